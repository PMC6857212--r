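# A minimal gene whose protein is M-G-W-P-P-V-*: the degron-like GWPPV core
# sits right after the start codon.
CDS_GWPPV <- "ATGGGATGGCCTCCTGTGTAA"

plus_strand_case <- function() {
  left <- "GATTACAGAT"
  chrom_seq <- paste0(left, CDS_GWPPV, "CCGGAATTGG")
  models <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                           start = 11L, end = 31L, phase = 0L)
  class(models) <- c("gene_models", class(models))
  list(models = models, genome = c(chr1 = chrom_seq))
}

test_that("the degron G-to-A substitution is a Gly-to-Glu missense", {
  cs <- plus_strand_case()
  # codon 2 is GGA; its middle base is CDS position 5 = genomic 15
  call <- classify_snp(cs$models, cs$genome, "chr1", 15L, "G", "A")
  expect_equal(call$classification, "missense")
  expect_equal(call$codon_ref, "GGA")
  expect_equal(call$codon_alt, "GAA")
  expect_equal(call$aa_ref, "G")
  expect_equal(call$aa_alt, "E")
  expect_equal(call$residue, 2L)
  rep <- motif_report(call$protein_ref, call$protein_alt, "GWPPV")
  expect_equal(rep$before, "GWPPV")
  expect_equal(rep$after, "EWPPV")
})

test_that("a wobble substitution in the same codon is synonymous", {
  cs <- plus_strand_case()
  # third base of codon GGA: CDS position 6 = genomic 16, A -> G gives GGG
  call <- classify_snp(cs$models, cs$genome, "chr1", 16L, "A", "G")
  expect_equal(call$classification, "synonymous")
  expect_equal(call$codon_alt, "GGG")
})

test_that("minus-strand genes give the same call as the plus-strand case", {
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  chrom_seq <- paste0("GGAATTCCGG", rc(CDS_GWPPV), "ATCTGTAATC")
  models <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "-",
                           start = 11L, end = 31L, phase = 0L)
  class(models) <- c("gene_models", class(models))
  # CDS position 5 on a minus-strand gene is genomic end - 4 = 27;
  # coding G>A is genomic C>T
  call <- classify_snp(models, c(chr1 = chrom_seq), "chr1", 27L, "C", "T")
  expect_equal(call$classification, "missense")
  expect_equal(call$codon_ref, "GGA")
  expect_equal(call$codon_alt, "GAA")
  expect_equal(call$aa_ref, "G")
  expect_equal(call$aa_alt, "E")
})

test_that("multi-exon genes splice across introns before translation", {
  left <- "GATTACAGAT"
  intron <- "GTAAGTTTAG"
  exon1 <- substr(CDS_GWPPV, 1, 9)
  exon2 <- substr(CDS_GWPPV, 10, 21)
  chrom_seq <- paste0(left, exon1, intron, exon2, "CCGG")
  models <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                           start = c(11L, 30L), end = c(19L, 41L),
                           phase = c(0L, 0L))
  class(models) <- c("gene_models", class(models))
  call <- classify_snp(models, c(chr1 = chrom_seq), "chr1", 15L, "G", "A")
  expect_equal(call$classification, "missense")
  expect_equal(call$aa_alt, "E")
  # SNP inside the intron is non-coding
  call2 <- classify_snp(models, c(chr1 = chrom_seq), "chr1", 25L,
                        substr(intron, 6, 6), "C")
  expect_equal(call2$classification, "non_coding")
})

test_that("ref mismatches and broken CDS lengths are reported", {
  cs <- plus_strand_case()
  expect_error(classify_snp(cs$models, cs$genome, "chr1", 15L, "T", "A"),
               "mismatch")
  broken <- cs$models
  broken$end <- 30L   # 20 nt CDS
  expect_warning(classify_snp(broken, cs$genome, "chr1", 15L, "G", "A"),
                 "multiple of 3")
})

test_that("classification equals the full-translation diff on random genes", {
  withr::with_seed(71, {
    for (i in 1:40) {
      case <- random_gene_case()
      call <- classify_snp(case$models, case$genome, "chr1",
                           case$pos, case$ref, case$alt)
      expect_equal(call$classification, oracle_classify(case),
                   info = sprintf("case %d strand %s pos %d", i, case$strand, case$pos))
    }
  })
})

test_that("reverse-complementing the genome and flipping strands preserves calls", {
  withr::with_seed(72, {
    for (i in 1:15) {
      case <- random_gene_case()
      call <- classify_snp(case$models, case$genome, "chr1",
                           case$pos, case$ref, case$alt)
      # mirror the whole chromosome
      L <- nchar(case$genome[["chr1"]])
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(case$genome[["chr1"]])))
      flipped <- case$models
      flipped$start <- L - case$models$end + 1L
      flipped$end <- L - case$models$start + 1L
      flipped$strand <- ifelse(case$models$strand == "+", "-", "+")
      flipped <- flipped[order(flipped$start), ]
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      call2 <- classify_snp(flipped, c(chr1 = rc), "chr1",
                            L - case$pos + 1L, comp[[case$ref]], comp[[case$alt]])
      expect_equal(call2$classification, call$classification)
      expect_equal(call2$aa_ref, call$aa_ref)
      expect_equal(call2$aa_alt, call$aa_alt)
      expect_equal(call2$residue, call$residue)
    }
  })
})

test_that("motif_report handles absent motifs and motifs at the protein start", {
  expect_equal(nrow(motif_report("MAAAA", "MAAAT", "GWPPV")), 0)
  rep <- motif_report("GWPPVQQ", "EWPPVQQ", "GWPPV")
  expect_equal(rep$start, 1L)
  expect_equal(rep$after, "EWPPV")
})

test_that("candidate gene filtering keeps only non-synonymous genes in the region", {
  # three genes; SNPs: one missense (g1), one synonymous (g2), one non-coding
  make_gene <- function(id, offset, strand = "+") {
    tibble::tibble(gene_id = id, chrom = "chr1", strand = strand,
                   start = offset + 1L, end = offset + 21L, phase = 0L)
  }
  models <- dplyr::bind_rows(make_gene("g1", 10L), make_gene("g2", 60L),
                             make_gene("g3", 110L))
  class(models) <- c("gene_models", class(models))
  chrom_seq <- paste(rep("T", 200), collapse = "")
  for (off in c(10L, 60L, 110L)) {
    substring(chrom_seq, off + 1L, off + 21L) <- CDS_GWPPV
  }
  snps <- tibble::tibble(chrom = "chr1",
                         pos = c(15L, 66L, 95L),
                         ref = c("G", "A", "T"),
                         alt = c("A", "G", "C"))
  effects <- classify_variants(models, c(chr1 = chrom_seq), snps)
  expect_setequal(effects$classification, c("missense", "synonymous", "non_coding"))
  region <- tibble::tibble(chrom = "chr1", start = 1L, end = 150L)
  hits <- filter_candidate_genes(effects, models, region)
  expect_equal(hits$gene_id, "g1")
  # region covering no genes, and an empty region
  none <- filter_candidate_genes(effects, models,
                                 tibble::tibble(chrom = "chr1", start = 180L, end = 190L))
  expect_equal(nrow(none), 0)
  expect_equal(nrow(filter_candidate_genes(effects, models, region[0, ])), 0)
})

test_that("GFF3 and FASTA fixtures round-trip through the readers", {
  dir <- withr::local_tempdir()
  left <- "GATTACAGAT"
  chrom_seq <- paste0(left, CDS_GWPPV, "CCGGAATTGG")
  fx <- write_gene_fixture(dir, chrom_seq,
                           tibble::tibble(start = 11L, end = 31L,
                                          strand = "+", phase = 0L))
  models <- read_gene_models(fx$gff)
  expect_equal(models$start, 11L)
  expect_equal(models$end, 31L)
  expect_equal(models$strand, "+")
  genome <- read_genome(fx$fasta)
  expect_equal(unname(nchar(genome)), nchar(chrom_seq))
  call <- classify_snp(models, genome, "chr1", 15L, "G", "A")
  expect_equal(call$classification, "missense")
})
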