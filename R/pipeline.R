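#' Run the full bulked-segregant mapping pipeline
#'
#' Orchestrates the stages simulate (or load) -> filter -> per-SNP index ->
#' sliding windows -> Monte-Carlo thresholds -> region calling, writing the
#' per-SNP track and window profile as TSV, the called regions as BED, and
#' a JSON run manifest with every parameter and the md5 checksum of every
#' output. All randomness derives from the single `seed`, so a rerun with
#' the same manifest is bit-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param counts A `bulk_counts` tibble; when `NULL` a synthetic experiment
#'   is simulated from `genome`, `design` and `model`.
#' @param genome,design,model Simulation settings used when `counts` is
#'   `NULL` (see [simulate_bulk_experiment()]).
#' @param bulk_size Plants per bulk for the null model; defaults to the
#'   design's bulk size.
#' @param window_size,step Sliding-window geometry in bp.
#' @param levels Confidence levels for thresholds.
#' @param call_level Level at which regions are called.
#' @param min_depth Per-bulk depth filter.
#' @param threshold_replicates Null replicates per window.
#' @param seed Master integer seed.
#' @return A list with the pipeline products (`counts`, `track`, `profile`,
#'   `regions`), the output `paths`, the `manifest`, and a `status` code:
#'   0 = regions called, 3 = no region reached the threshold, 2 = empty
#'   input.
#' @export
run_bsa_pipeline <- function(out_dir, counts = NULL,
                             genome = default_genome(),
                             design = cross_design(),
                             model = sequencing_model(),
                             bulk_size = NULL,
                             window_size = 1e6, step = 1e4,
                             levels = c(0.95, 0.99), call_level = 0.99,
                             min_depth = 7, threshold_replicates = 1000,
                             seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulated <- is.null(counts)
  if (simulated) {
    counts <- simulate_bulk_experiment(genome, design, model,
                                       seed = child_seed(seed, 10L))
    bulk_size <- bulk_size %||% design$bulk_size
  }
  if (is.null(bulk_size)) abort("bulk_size is required when counts are supplied")
  if (nrow(counts) == 0) {
    return(list(counts = counts, track = NULL, profile = NULL,
                regions = NULL, paths = list(), manifest = NULL, status = 2L))
  }
  counts <- filter_variants(counts, min_depth = min_depth)
  inform(sprintf("filter: %s dropped",
                 paste(names(attr(counts, "drop_tally")),
                       attr(counts, "drop_tally"), sep = "=", collapse = ", ")))
  track <- snp_index_track(counts)
  chrom_lengths <- if (simulated) {
    stats::setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  } else NULL
  profile <- sliding_windows(track, window_size, step, chrom_lengths)
  profile <- window_thresholds(profile, track, n = bulk_size, levels = levels,
                               replicates = threshold_replicates,
                               seed = child_seed(seed, 11L))
  regions <- call_regions(profile, level = call_level)
  paths <- list(track = file.path(out_dir, "track.tsv"),
                profile = file.path(out_dir, "windows.tsv"),
                regions = file.path(out_dir, "regions.bed"),
                manifest = file.path(out_dir, "manifest.json"))
  readr::write_tsv(as_tibble(track), paths$track)
  readr::write_tsv(as_tibble(profile), paths$profile)
  write_bed(regions, paths$regions)
  manifest <- list(
    parameters = list(window_size = window_size, step = step, levels = levels,
                      call_level = call_level, min_depth = min_depth,
                      threshold_replicates = threshold_replicates,
                      bulk_size = bulk_size, seed = seed,
                      simulated = simulated),
    n_snps = nrow(track), n_windows = nrow(profile), n_regions = nrow(regions),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(unlist(paths[c("track", "profile", "regions")]))),
      c("track.tsv", "windows.tsv", "regions.bed")))
  )
  if (simulated) manifest$truth <- attr(counts, "truth")$causal
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  list(counts = counts, track = track, profile = profile, regions = regions,
       paths = paths, manifest = manifest,
       status = if (nrow(regions) > 0) 0L else 3L)
}
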