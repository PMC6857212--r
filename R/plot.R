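#' Plot the delta SNP-index along chromosomes
#'
#' Per-SNP delta values are drawn as points, the sliding-window mean as a
#' line, and, when present, the window confidence thresholds as dashed
#' (95%) and dotted (99%) lines — the conventional display for two-bulk
#' mapping profiles.
#'
#' @param object A `window_profile` (with or without threshold columns).
#' @param track Optional `snp_index_track` to underlay per-SNP points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_profile
#' @export
autoplot.window_profile <- function(object, track = NULL, ...) {
  mid <- (object$start + object$end) / 2
  p <- ggplot2::ggplot()
  if (!is.null(track)) {
    p <- p + ggplot2::geom_point(
      data = as_tibble(track),
      ggplot2::aes(x = .data$pos / 1e6, y = .data$delta),
      colour = "steelblue", alpha = 0.25, size = 0.4)
  }
  df <- mutate(as_tibble(object), mid_mb = mid / 1e6)
  p <- p + ggplot2::geom_line(
    data = df, ggplot2::aes(x = .data$mid_mb, y = .data$mean_delta),
    colour = "firebrick")
  for (spec in list(c("hi_95", "dashed"), c("hi_99", "dotted"),
                    c("lo_95", "dashed"), c("lo_99", "dotted"))) {
    if (spec[1] %in% names(df)) {
      p <- p + ggplot2::geom_line(
        data = df,
        ggplot2::aes(x = .data$mid_mb, y = .data[[spec[1]]]),
        linetype = spec[2], colour = "darkgreen")
    }
  }
  p + ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(Delta ~ "SNP-index")) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.window_profile
#' @param profile A `window_profile`.
#' @export
plot_delta_profile <- function(profile, track = NULL) {
  autoplot.window_profile(profile, track = track)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
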