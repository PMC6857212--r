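#' SNP-index and delta SNP-index
#'
#' The SNP-index of a bulk at a variant is the fraction of reads carrying
#' the counted (mutant-parent) allele: `alt / (ref + alt)`. The delta
#' SNP-index is the mutant-bulk index minus the wild-type-bulk index; it has
#' expectation 0 at unlinked loci and, for a dominant causal allele with
#' phenotype-selected bulks, 2/3 - 0 = 2/3 at the causal SNP.
#'
#' @param ref_depth,alt_depth Non-negative read counts (vectorised).
#' @return `snp_index()` returns values in [0, 1]; `NA` where total depth
#'   is zero (undefined markers, excluded downstream).
#' @export
snp_index <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  ifelse(total > 0, alt_depth / total, NA_real_)
}

#' @rdname snp_index
#' @param index_mutant,index_wildtype SNP-index of each bulk.
#' @return `delta_snp_index()` returns values in [-1, 1].
#' @export
delta_snp_index <- function(index_mutant, index_wildtype) {
  index_mutant - index_wildtype
}

#' Per-SNP index track from bulk allele counts
#'
#' Computes both bulks' SNP-index and the delta SNP-index for every record.
#' Records where either bulk has zero depth are undefined and removed (the
#' number removed is reported via a `drop_tally` attribute).
#'
#' @param counts A `bulk_counts` tibble.
#' @return A `snp_index_track` tibble: `chrom`, `pos`, depths, `index_mut`,
#'   `index_wt`, `delta`.
#' @export
snp_index_track <- function(counts) {
  out <- mutate(as_tibble(counts),
                depth_mut = .data$mut_bulk_ref + .data$mut_bulk_alt,
                depth_wt = .data$wt_bulk_ref + .data$wt_bulk_alt,
                index_mut = snp_index(.data$mut_bulk_ref, .data$mut_bulk_alt),
                index_wt = snp_index(.data$wt_bulk_ref, .data$wt_bulk_alt),
                delta = delta_snp_index(.data$index_mut, .data$index_wt))
  undefined <- is.na(out$delta)
  out <- out[!undefined, , drop = FALSE]
  out <- arrange(out, .data$chrom, .data$pos)
  attr(out, "drop_tally") <- c(zero_depth = sum(undefined))
  attr(out, "truth") <- attr(counts, "truth")
  class(out) <- c("snp_index_track", class(out))
  out
}

#' Sliding-window means of the delta SNP-index
#'
#' Windows of `window_size` bp advance by `step` bp along each chromosome
#' starting at position 1; a SNP belongs to a window when
#' `start <= pos < start + window_size`. The window value is the unweighted
#' arithmetic mean of member deltas; empty windows are dropped. Window ends
#' are clipped at the chromosome end (taken from `chrom_lengths`, else the
#' last SNP position).
#'
#' @param track A `snp_index_track` tibble (sorted).
#' @param window_size,step Window width and step, in bp (defaults 1 Mb / 10 kb).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A `window_profile` tibble: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_snps`, `mean_delta`.
#' @export
sliding_windows <- function(track, window_size = 1e6, step = 1e4,
                            chrom_lengths = NULL) {
  if (window_size < step) {
    warn("window_size < step leaves gaps between windows")
  }
  per_chrom <- function(df) {
    pos <- df$pos
    chrom_len <- chrom_lengths[[df$chrom[1]]] %||% max(pos)
    starts <- seq(1, chrom_len, by = step)
    ends_excl <- starts + window_size
    cs <- c(0, cumsum(df$delta))
    # count of positions < x for sorted integer pos
    n_below <- function(x) findInterval(x - 0.5, pos)
    i_lo <- n_below(starts)          # SNPs strictly before window
    i_hi <- n_below(ends_excl)       # SNPs before window end (exclusive)
    n <- i_hi - i_lo
    keep <- n > 0
    tibble(chrom = df$chrom[1],
           start = as.integer(starts[keep]),
           end = as.integer(pmin(ends_excl[keep] - 1, chrom_len)),
           n_snps = n[keep],
           mean_delta = (cs[i_hi + 1][keep] - cs[i_lo + 1][keep]) / n[keep])
  }
  out <- dplyr::bind_rows(lapply(split(as_tibble(track), track$chrom), per_chrom))
  out <- arrange(out, .data$chrom, .data$start)
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  class(out) <- c("window_profile", class(out))
  out
}
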