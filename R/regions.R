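#' Call candidate regions from a thresholded window profile
#'
#' Scans each chromosome for maximal runs of consecutive windows whose mean
#' delta reaches the upper threshold at the requested confidence level
#' (optionally `|delta|` against either threshold when `two_sided = TRUE`;
#' the default positive-side scan matches mutant-parent allele polarity,
#' under which the causal region's delta is positive by construction).
#' Runs whose window spans overlap or touch are merged; the peak is the
#' leftmost window of maximal mean delta and the region span is the union
#' of member windows. Regions on different chromosomes never merge.
#'
#' @param profile A `window_profile` with threshold columns from
#'   [window_thresholds()].
#' @param level Confidence level whose thresholds to use (default 0.99).
#' @param two_sided Call negative excursions too (default `FALSE`).
#' @return A tibble of regions: `chrom`, `start`, `end` (1-based inclusive),
#'   `peak_pos` (midpoint of the peak window), `peak_delta`, `n_windows`,
#'   `level`.
#' @export
call_regions <- function(profile, level = 0.99, two_sided = FALSE) {
  hi_col <- sprintf("hi_%d", round(level * 100))
  lo_col <- sprintf("lo_%d", round(level * 100))
  if (!hi_col %in% names(profile)) {
    abort(sprintf("profile has no `%s` column; run window_thresholds() first", hi_col))
  }
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  peak_pos = integer(), peak_delta = double(),
                  n_windows = integer(), level = double())
  exceed <- profile$mean_delta >= profile[[hi_col]]
  if (two_sided) exceed <- exceed | profile$mean_delta <= profile[[lo_col]]
  exceed[is.na(exceed)] <- FALSE
  if (!any(exceed)) return(empty)
  regions <- list()
  for (ch in unique(profile$chrom)) {
    rows <- which(profile$chrom == ch & exceed)
    if (length(rows) == 0) next
    # maximal runs of consecutive exceeding windows
    run_id <- cumsum(c(1L, diff(rows) != 1L))
    spans <- lapply(split(rows, run_id), function(idx) {
      list(start = min(profile$start[idx]), end = max(profile$end[idx]), idx = idx)
    })
    # merge runs whose spans overlap or touch (step < window_size)
    merged <- list(spans[[1]])
    for (s in spans[-1]) {
      last <- merged[[length(merged)]]
      if (s$start <= last$end + 1L) {
        merged[[length(merged)]] <- list(start = last$start,
                                         end = max(last$end, s$end),
                                         idx = c(last$idx, s$idx))
      } else {
        merged <- c(merged, list(s))
      }
    }
    regions <- c(regions, lapply(merged, function(s) {
      score <- if (two_sided) abs(profile$mean_delta[s$idx]) else profile$mean_delta[s$idx]
      pk <- s$idx[which.max(score)]   # which.max takes the leftmost tie
      tibble(chrom = ch, start = as.integer(s$start), end = as.integer(s$end),
             peak_pos = as.integer(round((profile$start[pk] + profile$end[pk]) / 2)),
             peak_delta = profile$mean_delta[pk],
             n_windows = length(s$idx), level = level)
    }))
  }
  bind_rows(regions)
}
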