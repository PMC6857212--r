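#' Read two-bulk allele depths from a VCF
#'
#' Extracts per-sample AD (ref,alt allele depths) for the two bulk samples
#' and, optionally, the two parents' genotypes. Only biallelic SNP records
#' are kept; records with missing AD in either bulk are flagged and excluded
#' from downstream statistics. Output is sorted by (chrom, pos); a warning
#' is issued if the input was unsorted.
#'
#' @param path Path to a VCF (plain or bgzipped) with per-sample AD.
#' @param mutant_sample,wildtype_sample Sample names of the two bulks.
#' @param parent_samples Optional character vector of length 2
#'   (mutant-parent, wildtype-parent) whose GT columns are carried along.
#' @return A `bulk_counts` tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `mut_bulk_ref`, `mut_bulk_alt`, `wt_bulk_ref`, `wt_bulk_alt`, `missing`
#'   and, when parents are given, `parent_mut_gt`, `parent_wt_gt`.
#' @export
read_bulk_vcf <- function(path, mutant_sample, wildtype_sample,
                          parent_samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  wanted <- c(mutant_sample, wildtype_sample, parent_samples)
  missing_samples <- setdiff(wanted, samples)
  if (length(missing_samples) > 0) {
    abort(sprintf("sample(s) %s not found in VCF; available: %s",
                  paste(missing_samples, collapse = ", "),
                  paste(samples, collapse = ", ")))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  if (any(!biallelic)) {
    inform(sprintf("dropped %d multiallelic/non-SNP record(s)", sum(!biallelic)))
  }
  parse_ad <- function(x) {
    ok <- !is.na(x) & grepl("^\\d+,\\d+", x)
    ref <- alt <- rep(NA_integer_, length(x))
    parts <- strsplit(x[ok], ",", fixed = TRUE)
    ref[ok] <- as.integer(vapply(parts, `[`, "", 1L))
    alt[ok] <- as.integer(vapply(parts, `[`, "", 2L))
    list(ref = ref, alt = alt)
  }
  ad_mut <- parse_ad(ad[, mutant_sample])
  ad_wt <- parse_ad(ad[, wildtype_sample])
  out <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    mut_bulk_ref = ad_mut$ref, mut_bulk_alt = ad_mut$alt,
    wt_bulk_ref = ad_wt$ref, wt_bulk_alt = ad_wt$alt
  )
  if (!is.null(parent_samples)) {
    gt <- vcfR::extract.gt(v, element = "GT")
    out$parent_mut_gt <- unname(gt[, parent_samples[1]])
    out$parent_wt_gt <- unname(gt[, parent_samples[2]])
  }
  out <- out[biallelic, , drop = FALSE]
  out$missing <- is.na(out$mut_bulk_ref) | is.na(out$wt_bulk_ref)
  if (is.unsorted(order(out$chrom, out$pos)) ||
      !identical(order(out$chrom, out$pos), seq_len(nrow(out)))) {
    warn("VCF records were not sorted by (chrom, pos); output has been sorted")
    out <- arrange(out, .data$chrom, .data$pos)
  }
  class(out) <- c("bulk_counts", class(out))
  out
}

#' Read/write bulk allele counts as TSV
#'
#' The TSV layout is `chrom, pos, ref, alt, mut_bulk_ref, mut_bulk_alt,
#' wt_bulk_ref, wt_bulk_alt` with 1-based positions; it round-trips the
#' simulator output exactly.
#'
#' @param path File path.
#' @return `read_bulk_tsv()` returns a `bulk_counts` tibble.
#' @export
read_bulk_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = "c", pos = "i", ref = "c", alt = "c",
                           .default = "i"))
  out <- arrange(out, .data$chrom, .data$pos)
  class(out) <- c("bulk_counts", class(out))
  out
}

#' @rdname read_bulk_tsv
#' @param counts A `bulk_counts` tibble.
#' @export
write_bulk_tsv <- function(counts, path) {
  cols <- c("chrom", "pos", "ref", "alt",
            "mut_bulk_ref", "mut_bulk_alt", "wt_bulk_ref", "wt_bulk_alt")
  readr::write_tsv(as_tibble(counts)[, cols], path)
  invisible(path)
}

#' Write bulk allele counts as a minimal two-sample VCF 4.2
#'
#' Emits one record per SNP with `AD` (ref,alt) and `DP` FORMAT fields for
#' samples `mut_bulk` and `wt_bulk`. The companion ground truth (causal locus
#' of a simulated experiment) can be written as a sidecar JSON.
#'
#' @param counts A `bulk_counts` tibble.
#' @param path Output VCF path.
#' @param truth_path Optional path for the ground-truth sidecar JSON
#'   (written only when the counts carry a `truth` attribute).
#' @return `path`, invisibly.
#' @export
write_bulk_vcf <- function(counts, path, truth_path = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0("##contig=<ID=", unique(counts$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "mut_bulk", "wt_bulk"), collapse = "\t")
  )
  fmt <- function(r, a) sprintf("%d,%d:%d", r, a, r + a)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD:DP\t%s\t%s",
                  counts$chrom, counts$pos, counts$ref, counts$alt,
                  fmt(counts$mut_bulk_ref, counts$mut_bulk_alt),
                  fmt(counts$wt_bulk_ref, counts$wt_bulk_alt))
  writeLines(c(hdr, body), path)
  truth <- attr(counts, "truth")
  if (!is.null(truth_path) && !is.null(truth)) {
    jsonlite::write_json(list(causal = truth$causal), truth_path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Filter two-bulk variant records
#'
#' Applies, in order: removal of records flagged missing; a per-bulk minimum
#' depth; optionally a parent-homozygosity requirement (both parents
#' homozygous for different alleles, e.g. `0/0` vs `1/1`); optionally a
#' minimum SNP-index that must be reached in at least one bulk (records
#' whose index is below `min_index_both` in *both* bulks are dropped).
#'
#' @param counts A `bulk_counts` tibble.
#' @param min_depth Minimum total depth per bulk (default 7).
#' @param require_parent_homozygous_diff Keep only records whose parent GT
#'   columns are homozygous for different alleles. Requires parent columns.
#' @param min_index_both Optional threshold; `NULL` (default) disables it.
#' @return The filtered `bulk_counts`, with a `drop_tally` attribute naming
#'   how many records each rule removed.
#' @export
filter_variants <- function(counts, min_depth = 7,
                            require_parent_homozygous_diff = FALSE,
                            min_index_both = NULL) {
  tally <- c(missing = 0L, depth = 0L, parent = 0L, index = 0L)
  if ("missing" %in% names(counts)) {
    keep <- !counts$missing
    tally["missing"] <- sum(!keep)
    counts <- counts[keep, , drop = FALSE]
  }
  dm <- counts$mut_bulk_ref + counts$mut_bulk_alt
  dw <- counts$wt_bulk_ref + counts$wt_bulk_alt
  keep <- dm >= min_depth & dw >= min_depth
  tally["depth"] <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  if (require_parent_homozygous_diff) {
    if (!all(c("parent_mut_gt", "parent_wt_gt") %in% names(counts))) {
      abort("parent genotype columns are required for the parent-homozygosity filter")
    }
    homo <- function(gt) {
      a <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
      vapply(a, function(x) length(x) == 2L && !anyNA(x) &&
               x[1] == x[2] && x[1] %in% c("0", "1"), logical(1))
    }
    allele1 <- function(gt) sub("[/|].*$", "", gt)
    keep <- homo(counts$parent_mut_gt) & homo(counts$parent_wt_gt) &
      allele1(counts$parent_mut_gt) != allele1(counts$parent_wt_gt)
    tally["parent"] <- sum(!keep)
    counts <- counts[keep, , drop = FALSE]
  }
  if (!is.null(min_index_both)) {
    im <- counts$mut_bulk_alt / (counts$mut_bulk_ref + counts$mut_bulk_alt)
    iw <- counts$wt_bulk_alt / (counts$wt_bulk_ref + counts$wt_bulk_alt)
    keep <- !(im < min_index_both & iw < min_index_both)
    tally["index"] <- sum(!keep)
    counts <- counts[keep, , drop = FALSE]
  }
  attr(counts, "drop_tally") <- tally
  counts
}

#' Write candidate regions as BED
#'
#' Intervals are converted from 1-based inclusive to BED's 0-based half-open
#' convention; the name column carries the peak position and peak mean delta
#' as `peak=<pos>;delta=<value>`.
#'
#' @param regions A tibble of regions from [call_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\tpeak=%d;delta=%.4f",
                   regions$chrom, regions$start - 1L, regions$end,
                   regions$peak_pos, regions$peak_delta)
  writeLines(lines, path)
  invisible(path)
}
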