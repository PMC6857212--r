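# Shared fixtures and independent brute-force oracles.

# Build an f2_population by hand (bypassing the simulator) so depth sampling
# can be tested against known genotype codes.
manual_population <- function(geno, chrom = "chr1", pos = NULL, causal_idx = 1L,
                              dominant = TRUE) {
  pos <- pos %||% seq_len(ncol(geno)) * 1000L
  loci <- tibble::tibble(chrom = chrom, pos = pos,
                         is_causal = seq_len(ncol(geno)) == causal_idx)
  structure(list(geno = geno, loci = loci,
                 design = cross_design(population_size = max(2L, nrow(geno)),
                                       bulk_size = 1L),
                 dominant = dominant, phenotype = NULL),
            class = "f2_population")
}

`%||%` <- rlang::`%||%`

# A genome where every SNP sits alone on its own chromosome, so all loci are
# mutually unlinked; the causal SNP is the first.
unlinked_genome <- function(n_null, chrom_len = 1e6) {
  n <- n_null + 1L
  chroms <- paste0("c", seq_len(n))
  genome_spec(
    chromosomes = tibble::tibble(chrom = chroms, length = chrom_len),
    snp_positions = tibble::tibble(chrom = chroms, pos = rep(5e5L, n)),
    causal_chrom = "c1", causal_pos = 5e5L
  )
}

# Simulate an experiment, retrying with offset seeds for the rare draws in
# which one phenotype class is too small to fill its bulk.
sim_bulkable <- function(genome, design = cross_design(),
                         model = sequencing_model(), seed) {
  for (k in 0:9) {
    out <- tryCatch(
      simulate_bulk_experiment(genome, design, model,
                               seed = seed + k * 1000003L),
      error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("no replicate with fillable bulks found")
}

write_toy_vcf <- function(path, records,
                          samples = c("mut_bulk", "wt_bulk")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# Brute-force sliding-window means: literal double loop over windows/SNPs.
brute_windows <- function(track, window_size, step, chrom_lengths = NULL) {
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(tr$pos)
    for (s in seq(1, len, by = step)) {
      inside <- tr$pos >= s & tr$pos < s + window_size
      if (any(inside)) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = ch, start = as.integer(s),
          end = as.integer(min(s + window_size - 1, len)),
          n_snps = sum(inside), mean_delta = mean(tr$delta[inside]))
      }
    }
  }
  dplyr::bind_rows(out)
}

# Brute-force region scan: walk windows, accumulate exceeding runs, merge
# spans that overlap or touch.
brute_regions <- function(profile, hi_col) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    pf <- profile[profile$chrom == ch, ]
    open <- NULL
    flush <- function(open, out) {
      if (is.null(open)) return(out)
      c(out, list(tibble::tibble(chrom = ch, start = open$start, end = open$end)))
    }
    for (i in seq_len(nrow(pf))) {
      ex <- !is.na(pf$mean_delta[i]) && !is.na(pf[[hi_col]][i]) &&
        pf$mean_delta[i] >= pf[[hi_col]][i]
      if (ex) {
        if (is.null(open)) {
          open <- list(start = pf$start[i], end = pf$end[i])
        } else if (pf$start[i] <= open$end + 1) {
          open$end <- max(open$end, pf$end[i])
        } else {
          out <- flush(open, out)
          open <- list(start = pf$start[i], end = pf$end[i])
        }
      } else if (!is.null(open) && pf$start[i] > open$end + 1) {
        # runs separated by a non-exceeding gap beyond the open span end
        out <- flush(open, out)
        open <- NULL
      }
    }
    out <- flush(open, out)
  }
  dplyr::bind_rows(out)
}

# ---- gene-model fixtures ------------------------------------------------

write_gene_fixture <- function(dir, chrom_seq, cds, chrom = "chr1",
                               gene_id = "gene1") {
  fa <- file.path(dir, "genome.fa")
  writeLines(c(paste0(">", chrom), chrom_seq), fa)
  gff <- file.path(dir, "models.gff3")
  lines <- c("##gff-version 3",
             sprintf("%s\t.\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s",
                     chrom, min(cds$start), max(cds$end), cds$strand[1], gene_id),
             sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                     chrom, cds$start, cds$end, cds$strand, cds$phase,
                     gene_id, gene_id))
  writeLines(lines, gff)
  list(fasta = fa, gff = gff)
}

random_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                  collapse = "")

# Random single-gene model embedded in a random chromosome; returns the
# pieces needed both for classify_snp and for the translation oracle.
random_gene_case <- function() {
  n_exon <- sample(1:3, 1)
  exon_len <- 3 * sample(2:6, n_exon, replace = TRUE)
  gaps <- sample(5:20, n_exon + 1, replace = TRUE)
  starts <- integer(n_exon); ends <- integer(n_exon)
  cur <- gaps[1]
  for (i in seq_len(n_exon)) {
    starts[i] <- cur + 1L
    ends[i] <- cur + exon_len[i]
    cur <- ends[i] + gaps[i + 1]
  }
  strand <- sample(c("+", "-"), 1)
  chrom_seq <- random_bases(cur + 10L)
  models <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = strand,
                           start = starts, end = ends, phase = 0L)
  class(models) <- c("gene_models", class(models))
  # pick a SNP inside a random exon
  ex <- sample(n_exon, 1)
  pos <- sample(starts[ex]:ends[ex], 1)
  ref <- substring(chrom_seq, pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  list(models = models, genome = c(chr1 = chrom_seq),
       pos = pos, ref = ref, alt = alt, strand = strand)
}

# Independent oracle: classify by diffing full translations done with
# Biostrings::translate on the spliced CDS.
oracle_classify <- function(case) {
  m <- case$models
  seqs <- lapply(list(case$genome[["chr1"]],
                      {
                        s <- case$genome[["chr1"]]
                        substring(s, case$pos, case$pos) <- case$alt
                        s
                      }),
                 function(chrom_seq) {
                   pieces <- substring(chrom_seq, m$start, m$end)
                   cds <- paste(pieces, collapse = "")
                   d <- Biostrings::DNAString(cds)
                   if (case$strand == "-") d <- Biostrings::reverseComplement(d)
                   suppressWarnings(as.character(
                     Biostrings::translate(d, no.init.codon = TRUE)))
                 })
  p_ref <- seqs[[1]]; p_alt <- seqs[[2]]
  if (p_ref == p_alt) return("synonymous")
  i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  a <- substring(p_ref, i, i); b <- substring(p_alt, i, i)
  if (b == "*") "nonsense"
  else if (a == "*") "stop_loss"
  else if (i == 1 && a == "M") "start_loss"
  else "missense"
}

# ---- dCAPS brute-force oracle -------------------------------------------

# Enumerate every enzyme x strand x placement x (<= max_mismatches
# substitutions anywhere except the SNP, any base) and record the placements
# for which some substitution set makes the motif match exactly one allele.
brute_dcaps_placements <- function(flank_left, ref, alt, flank_right,
                                   enzymes, max_mismatches) {
  amp_ref <- toupper(paste0(flank_left, ref, flank_right))
  amp_alt <- toupper(paste0(flank_left, alt, flank_right))
  snp0 <- nchar(flank_left)
  total <- nchar(amp_ref)
  sets <- bsamapr:::IUPAC_SETS
  window_matches <- function(seq, s0, m) {
    chars <- strsplit(substring(seq, s0 + 1, s0 + length(m)), "")[[1]]
    all(mapply(function(b, code) b %in% sets[[code]], chars, m))
  }
  found <- list()
  for (i in seq_len(nrow(enzymes))) {
    strands <- if (enzymes$palindromic[i]) "+" else c("+", "-")
    for (strand in strands) {
      motif <- if (strand == "+") enzymes$motif[i] else
        bsamapr:::iupac_revcomp(enzymes$motif[i])
      m <- strsplit(motif, "")[[1]]
      L <- length(m)
      for (s0 in max(0, snp0 - L + 1):snp0) {
        if (s0 + L > total) next
        other <- setdiff(s0:(s0 + L - 1), snp0)
        subsets <- list(integer(0))
        if (max_mismatches >= 1) subsets <- c(subsets, as.list(other))
        ok <- FALSE
        for (ss in subsets) {
          base_opts <- if (length(ss) == 0) list(character(0)) else
            as.list(c("A", "C", "G", "T"))
          for (bb in base_opts) {
            r <- bsamapr:::apply_substitutions(amp_ref, ss, bb)
            a <- bsamapr:::apply_substitutions(amp_alt, ss, bb)
            if (xor(window_matches(r, s0, m), window_matches(a, s0, m))) {
              ok <- TRUE; break
            }
          }
          if (ok) break
        }
        if (ok) {
          found[[length(found) + 1]] <- tibble::tibble(
            enzyme = enzymes$enzyme[i], strand = strand, motif_start = s0)
        }
      }
    }
  }
  dplyr::bind_rows(c(list(tibble::tibble(enzyme = character(),
                                         strand = character(),
                                         motif_start = integer())),
                     found))
}
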