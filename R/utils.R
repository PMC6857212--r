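#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows distinct row_number n across
#' @importFrom tibble tibble as_tibble
NULL

# Run `expr` under a reproducible RNG state when `seed` is given; leave the
# global RNG untouched either way.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive a stream-specific child seed so that independent stages of a
# pipeline driven by one master seed do not share RNG streams.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483587L
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
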