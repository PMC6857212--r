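#' Monte-Carlo null distribution of the delta SNP-index
#'
#' The null model resamples the finite bulks before the reads: for each bulk
#' of `n` F2 plants the bulk allele count at an unlinked locus is
#' `k ~ Binomial(2n, 1/2)`, the bulk allele frequency is `p = k / 2n`, and
#' the observed alt read count is `Binomial(depth, p)`. The simulated delta
#' is the difference of the two bulks' read fractions. This reproduces the
#' extra variance a fixed-0.5 null would miss.
#'
#' @param depth_mut,depth_wt Integer depth vectors (recycled against each
#'   other), one entry per locus.
#' @param n Bulk size (plants per bulk).
#' @param replicates Number of null replicates per locus.
#' @return A `replicates x n_loci` matrix of null delta values.
#' @export
simulate_null_deltas <- function(depth_mut, depth_wt, n, replicates) {
  S <- max(length(depth_mut), length(depth_wt))
  depth_mut <- rep_len(as.integer(depth_mut), S)
  depth_wt <- rep_len(as.integer(depth_wt), S)
  N <- S * replicates
  draw <- function(depth) {
    p <- stats::rbinom(N, 2L * n, 0.5) / (2 * n)
    d <- rep(depth, each = replicates)
    k <- stats::rbinom(N, d, p)
    out <- k / d
    out[d == 0L] <- NA_real_
    out
  }
  matrix(draw(depth_mut) - draw(depth_wt), nrow = replicates)
}

#' Per-depth-pair confidence thresholds for the delta SNP-index
#'
#' For every distinct (mutant-bulk, wild-type-bulk) depth pair, simulates
#' `replicates` null deltas under the finite-bulk null of
#' [simulate_null_deltas()] and reports the two-sided empirical quantiles at
#' each confidence level. Depths can be binned (`depth_bin` > 1) to cap the
#' table size; each pair is then represented by its bin midpoint.
#'
#' @param depth_pairs A data frame with columns `depth_mut` and `depth_wt`
#'   (duplicates allowed; a `snp_index_track` works directly).
#' @param n Bulk size.
#' @param levels Confidence levels (default 0.95 and 0.99).
#' @param replicates Null replicates per distinct pair (default 10,000).
#' @param depth_bin Width of the depth bins (default 1 = exact depths).
#' @param seed Integer seed (optional).
#' @return A `threshold_table` tibble: `depth_mut`, `depth_wt`, `level`,
#'   `lo`, `hi`, with attributes `n`, `replicates`, `depth_bin`.
#' @export
null_thresholds <- function(depth_pairs, n, levels = c(0.95, 0.99),
                            replicates = 10000, depth_bin = 1, seed = NULL) {
  if (replicates < 1000) abort("use at least 1,000 replicates")
  bin <- function(d) as.integer(pmax(1, round(d / depth_bin)) * depth_bin)
  pairs <- distinct(tibble(depth_mut = bin(depth_pairs$depth_mut),
                           depth_wt = bin(depth_pairs$depth_wt)))
  pairs <- arrange(pairs, .data$depth_mut, .data$depth_wt)
  probs <- sort(c((1 - levels) / 2, 1 - (1 - levels) / 2))
  out <- with_seed_if(seed, {
    chunks <- split(seq_len(nrow(pairs)),
                    ceiling(seq_len(nrow(pairs)) / max(1L, 2e6 %/% replicates)))
    bind_rows(lapply(chunks, function(idx) {
      m <- simulate_null_deltas(pairs$depth_mut[idx], pairs$depth_wt[idx],
                                n, replicates)
      q <- apply(m, 2L, stats::quantile, probs = probs, names = FALSE)
      bind_rows(lapply(seq_along(levels), function(j) {
        a <- (1 - levels[j]) / 2
        tibble(depth_mut = pairs$depth_mut[idx], depth_wt = pairs$depth_wt[idx],
               level = levels[j],
               lo = q[match(a, probs), ], hi = q[match(1 - a, probs), ])
      }))
    }))
  })
  attr(out, "n") <- n
  attr(out, "replicates") <- replicates
  attr(out, "depth_bin") <- depth_bin
  class(out) <- c("threshold_table", class(out))
  out
}

#' Attach per-SNP null thresholds to an index track
#'
#' Joins a [null_thresholds()] table onto a track by (binned) depth pair,
#' spreading each confidence level into `lo_<level>` / `hi_<level>` columns
#' (e.g. `lo_95`, `hi_95`).
#'
#' @param track A `snp_index_track`.
#' @param table A `threshold_table`.
#' @return The track with threshold columns added.
#' @export
attach_snp_thresholds <- function(track, table) {
  depth_bin <- attr(table, "depth_bin") %||% 1
  bin <- function(d) as.integer(pmax(1, round(d / depth_bin)) * depth_bin)
  wide <- tidyr::pivot_wider(as_tibble(table),
                             names_from = "level", values_from = c("lo", "hi"),
                             names_glue = "{.value}_{round(level * 100)}")
  keyed <- mutate(as_tibble(track),
                  .dm = bin(.data$depth_mut), .dw = bin(.data$depth_wt))
  out <- left_join(keyed, wide, by = c(.dm = "depth_mut", .dw = "depth_wt"))
  out <- select(out, -dplyr::all_of(c(".dm", ".dw")))
  for (a in c("truth", "drop_tally")) attr(out, a) <- attr(track, a)
  class(out) <- unique(c("snp_index_track", class(out)))
  out
}

#' Flag SNPs whose delta lies outside its null thresholds
#'
#' A SNP is an outlier at a level when its delta reaches or passes either
#' two-sided threshold (`delta >= hi` or `delta <= lo`). The at-or-beyond
#' convention matches region calling, where a window is significant when its
#' mean delta reaches the threshold; on the discrete lattice of read
#' fractions it also keeps the empirical exceedance rate centred on the
#' nominal level.
#'
#' @param track A `snp_index_track` with threshold columns from
#'   [attach_snp_thresholds()].
#' @param level Confidence level whose thresholds to use.
#' @return A logical vector, one entry per SNP.
#' @export
snp_outliers <- function(track, level = 0.95) {
  hi <- track[[sprintf("hi_%d", round(level * 100))]]
  lo <- track[[sprintf("lo_%d", round(level * 100))]]
  if (is.null(hi)) {
    abort(sprintf("no thresholds at level %s; run attach_snp_thresholds() first", level))
  }
  track$delta >= hi | track$delta <= lo
}

#' Per-window confidence thresholds
#'
#' For each window, the threshold is the empirical quantile of the mean of
#' independently simulated null deltas drawn at each member SNP's observed
#' depth pair (member SNPs are treated as independent; linkage between them
#' is ignored, which makes the thresholds slightly conservative targets for
#' a smoothed statistic).
#'
#' @param profile A `window_profile` from [sliding_windows()].
#' @param track The `snp_index_track` the profile was computed from.
#' @param n Bulk size.
#' @param levels Confidence levels (default 0.95 and 0.99).
#' @param replicates Null replicates per window (default 1,000).
#' @param seed Integer seed (optional).
#' @return The profile with `lo_<level>` / `hi_<level>` columns.
#' @export
window_thresholds <- function(profile, track, n, levels = c(0.95, 0.99),
                              replicates = 1000, seed = NULL) {
  window_size <- attr(profile, "window_size")
  probs <- sort(c((1 - levels) / 2, 1 - (1 - levels) / 2))
  qcols <- matrix(NA_real_, nrow(profile), length(probs))
  with_seed_if(seed, {
    for (ch in unique(profile$chrom)) {
      tr <- track[track$chrom == ch, , drop = FALSE]
      rows <- which(profile$chrom == ch)
      m <- simulate_null_deltas(tr$depth_mut, tr$depth_wt, n, replicates)
      cs <- cbind(0, t(apply(m, 1L, cumsum)))   # replicates x (S+1)
      n_below <- function(x) findInterval(x - 0.5, tr$pos)
      i_lo <- n_below(profile$start[rows])
      i_hi <- n_below(profile$start[rows] + window_size)
      for (k in seq_along(rows)) {
        if (i_hi[k] > i_lo[k]) {
          means <- (cs[, i_hi[k] + 1L] - cs[, i_lo[k] + 1L]) / (i_hi[k] - i_lo[k])
          qcols[rows[k], ] <- stats::quantile(means, probs = probs, names = FALSE)
        }
      }
    }
  })
  for (j in seq_along(levels)) {
    a <- (1 - levels[j]) / 2
    profile[[sprintf("lo_%d", round(levels[j] * 100))]] <- qcols[, match(a, probs)]
    profile[[sprintf("hi_%d", round(levels[j] * 100))]] <- qcols[, match(1 - a, probs)]
  }
  profile
}
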