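ENZ <- restriction_enzymes()

test_that("the enzyme table carries IUPAC motifs and palindromy flags", {
  expect_true(all(c("EcoRI", "FokI", "TaqI") %in% ENZ$enzyme))
  expect_true(ENZ$palindromic[ENZ$enzyme == "EcoRI"])
  expect_false(ENZ$palindromic[ENZ$enzyme == "FokI"])
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("enzyme\tmotif", "X\tGGQ"), bad)
  expect_error(restriction_enzymes(bad), "IUPAC")
})

test_that("digestion finds motif occurrences on both strands, 0-based", {
  # GAATTC at 3 (forward; palindromic so one report);
  # FokI GGATG at 12 forward and CATCC (revcomp) at 20
  seq <- "AAAGAATTCAAAGGATGAAACATCCAAA"
  eco <- digest(seq, "GAATTC")
  expect_equal(eco$position, 3L)
  expect_equal(eco$strand, "+")
  fok <- digest(seq, "GGATG")
  expect_equal(fok$position, c(12L, 20L))
  expect_equal(fok$strand, c("+", "-"))
  # degenerate motif: GGWCC matches GGACC and GGTCC
  expect_equal(digest("TTGGACCTTGGTCCTT", "GGWCC")$position, c(2L, 9L))
})

test_that("a SNP completing GAATTC yields an EcoRI CAPS cutting the reference", {
  d <- find_caps("CCG", "A", "C", "ATTC", enzymes = ENZ)
  eco <- d[d$enzyme == "EcoRI", ]
  expect_equal(nrow(eco), 1)
  expect_equal(eco$type, "CAPS")
  expect_equal(eco$cut_allele, "reference")
  expect_equal(eco$n_mismatches, 0L)
  # ref amplicon CCGAATTC carries the site, alt amplicon CCGCATTC does not
  expect_equal(nrow(digest(eco$amplicon_ref_mod, "GAATTC")), 1)
  expect_equal(nrow(digest(eco$amplicon_alt_mod, "GAATTC")), 0)
})

test_that("a SNP covered by no motif placement yields no design", {
  d <- find_caps("TTTTTTTT", "A", "C", "TTTTTTTT", enzymes = ENZ)
  expect_equal(nrow(d), 0)
})

test_that("an alt allele creating GGATG on the reverse strand is a FokI CAPS", {
  # forward CATCC = reverse-strand GGATG; SNP G>C completes it
  d <- find_caps("TTTTTCA", "G", "T", "CCTTTTT", enzymes = ENZ)
  fok <- d[d$enzyme == "FokI", ]
  expect_gte(nrow(fok), 1)
  expect_true(all(fok$strand == "-"))
  expect_true(all(fok$cut_allele == "alternate"))
  amp_alt <- fok$amplicon_alt_mod[1]
  hits <- digest(amp_alt, "GGATG")
  expect_true(fok$motif_start[1] %in% hits$position[hits$strand == "-"])
})

test_that("one engineered base adjacent to the SNP rescues a near-site", {
  # ref: CCGGATTC -> GGATC? use BamHI GGATCC: seq GGATanything; SNP makes
  # the 5th base; one mismatch needed at the 6th.
  # amplicon: G G A T [C/A] G ... BamHI GGATCC needs C at offset 5.
  d <- find_dcaps("TTTGGAT", "C", "A", "GTTTTT", enzymes = ENZ,
                  max_mismatches = 1)
  bam <- d[d$enzyme == "BamHI", ]
  expect_equal(nrow(bam), 1)
  expect_equal(bam$type, "dCAPS")
  expect_equal(bam$n_mismatches, 1L)
  expect_equal(bam$cut_allele, "reference")
  # soundness: the placement is present in exactly one modified amplicon
  on_placement <- function(amp) {
    h <- digest(amp, "GGATCC")
    bam$motif_start %in% h$position
  }
  expect_true(on_placement(bam$amplicon_ref_mod))
  expect_false(on_placement(bam$amplicon_alt_mod))
})

test_that("dCAPS search with zero mismatches reduces to the CAPS search", {
  for (args in list(list("CCG", "A", "C", "ATTC"),
                    list("TTTTTCA", "G", "T", "CCTTTTT"),
                    list("ACGTACGTA", "G", "T", "TGCATGCAT"))) {
    caps <- do.call(find_caps, c(args, list(enzymes = ENZ)))
    dcaps0 <- do.call(find_dcaps, c(args, list(enzymes = ENZ, max_mismatches = 0)))
    expect_identical(caps, dcaps0)
  }
})

test_that("dCAPS designs are a superset of CAPS designs", {
  caps <- find_caps("CCG", "A", "C", "ATTC", enzymes = ENZ)
  dcaps <- find_dcaps("CCG", "A", "C", "ATTC", enzymes = ENZ, max_mismatches = 1)
  key <- function(x) paste(x$enzyme, x$strand, x$motif_start)
  expect_true(all(key(caps) %in% key(dcaps)))
  expect_true(all(dcaps$n_mismatches[match(key(caps), key(dcaps))] == 0))
})

test_that("every returned design passes the in-silico digestion soundness check", {
  withr::with_seed(101, {
    for (i in 1:25) {
      left <- random_bases(sample(6:12, 1))
      right <- random_bases(sample(6:12, 1))
      alleles <- sample(c("A", "C", "G", "T"), 2)
      d <- find_dcaps(left, alleles[1], alleles[2], right, enzymes = ENZ,
                      max_mismatches = 1)
      for (j in seq_len(nrow(d))) {
        hit <- function(amp) {
          h <- digest(amp, d$motif[j])
          any(h$position == d$motif_start[j] & h$strand == d$strand[j])
        }
        in_ref <- hit(d$amplicon_ref_mod[j])
        in_alt <- hit(d$amplicon_alt_mod[j])
        expect_true(xor(in_ref, in_alt))
        expect_equal(if (in_ref) "reference" else "alternate", d$cut_allele[j])
      }
    }
  })
})

test_that("the search finds exactly the placements brute-force enumeration finds", {
  withr::with_seed(102, {
    for (i in 1:15) {
      left <- random_bases(sample(5:10, 1))
      right <- random_bases(sample(5:10, 1))
      alleles <- sample(c("A", "C", "G", "T"), 2)
      got <- find_dcaps(left, alleles[1], alleles[2], right, enzymes = ENZ,
                        max_mismatches = 1)
      want <- brute_dcaps_placements(left, alleles[1], alleles[2], right,
                                     ENZ, max_mismatches = 1)
      key <- function(x) sort(paste(x$enzyme, x$strand, x$motif_start))
      expect_identical(key(got), key(want))
    }
  })
})

test_that("primers end one base 3' of the motif and report mismatch offsets", {
  d <- find_dcaps("TTTGGAT", "C", "A", "GTTTTT", enzymes = ENZ,
                  max_mismatches = 1, primer_length = 10)
  bam <- d[d$enzyme == "BamHI", ]
  # plus-strand placement: primer is the modified forward sequence ending
  # one base past the motif window
  amp <- bam$amplicon_ref_mod
  p_end <- bam$motif_start + nchar(bam$motif) + 1L  # 1-based end position
  expect_equal(bam$primer, substring(amp, max(1L, p_end - 9L), p_end))
  off <- as.integer(strsplit(bam$primer_mismatch_offsets, ",")[[1]])
  expect_true(all(substring(bam$primer, off + 1L, off + 1L) !=
                    substring(paste0("TTTGGAT", "C", "GTTTTT"),
                              max(1L, p_end - 9L) + off, max(1L, p_end - 9L) + off)))
  expect_error(find_dcaps("AG", "A", "C", "T", enzymes = ENZ), "at least")
})
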