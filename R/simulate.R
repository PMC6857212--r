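#' Describe a marker map for simulation
#'
#' A genome specification holds the chromosomes, the SNP marker positions
#' segregating between the two parents, and the designated causal locus.
#' Positions are 1-based and must be strictly increasing within a chromosome;
#' the causal locus must be one of the markers.
#'
#' @param chromosomes Tibble or data frame with columns `chrom` and
#'   `length` (bp).
#' @param snp_positions Tibble with columns `chrom` and `pos` (1-based).
#' @param causal_chrom,causal_pos Location of the causal SNP; must be a
#'   member of `snp_positions`.
#' @param dominant Logical; is the causal allele dominant? Default `TRUE`
#'   (a single copy produces the mutant phenotype).
#'
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes, snp_positions, causal_chrom, causal_pos,
                        dominant = TRUE) {
  chromosomes <- as_tibble(chromosomes)
  snp_positions <- as_tibble(snp_positions)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)),
            all(c("chrom", "pos") %in% names(snp_positions)))
  snp_positions <- arrange(snp_positions, .data$chrom, .data$pos)
  len <- chromosomes$length[match(snp_positions$chrom, chromosomes$chrom)]
  if (anyNA(len)) {
    abort(sprintf("chromosome(s) %s have SNPs but no declared length",
                  paste(unique(snp_positions$chrom[is.na(len)]), collapse = ", ")))
  }
  if (any(snp_positions$pos < 1 | snp_positions$pos > len)) {
    abort("SNP position(s) fall outside their chromosome's [1, length] range")
  }
  if (nrow(snp_positions) > 1) {
    same <- snp_positions$chrom[-1] == snp_positions$chrom[-nrow(snp_positions)]
    if (any(same & diff(snp_positions$pos) <= 0)) {
      abort("positions are not strictly increasing within a chromosome")
    }
  }
  hit <- snp_positions$chrom == causal_chrom & snp_positions$pos == causal_pos
  if (!any(hit)) abort("causal locus is not a member of the marker map")
  structure(
    list(chromosomes = chromosomes, snp_positions = snp_positions,
         causal = list(chrom = causal_chrom, pos = causal_pos, dominant = isTRUE(dominant))),
    class = "genome_spec"
  )
}

#' Default single-chromosome genome for desk-scale experiments
#'
#' One 60 Mb chromosome carrying `n_snps` evenly spaced markers with the
#' causal locus at the marker nearest `causal_pos` (28.3 Mb by default,
#' mimicking a causal gene in the middle third of a chromosome).
#'
#' @param chrom_length Chromosome length in bp.
#' @param n_snps Number of evenly spaced SNP markers.
#' @param causal_pos Approximate causal position (snapped to the nearest marker).
#' @param dominant Dominance of the causal allele.
#' @return A [genome_spec()].
#' @export
default_genome <- function(chrom_length = 60e6, n_snps = 3000,
                           causal_pos = 28.3e6, dominant = TRUE) {
  pos <- round(seq(chrom_length / n_snps, chrom_length, length.out = n_snps))
  causal <- pos[which.min(abs(pos - causal_pos))]
  genome_spec(
    chromosomes = tibble(chrom = "chr1", length = chrom_length),
    snp_positions = tibble(chrom = "chr1", pos = pos),
    causal_chrom = "chr1", causal_pos = causal, dominant = dominant
  )
}

#' Describe the cross and bulking design
#'
#' Defaults mirror a typical dominant-mutant mapping design: 277 F2 plants,
#' two phenotype-selected bulks of 50, no phenotyping error, Haldane map
#' function at 2 cM/Mb.
#'
#' @param population_size Number of F2 individuals.
#' @param bulk_size Plants per bulk; `2 * bulk_size <= population_size`.
#' @param phenotyping_error Probability a phenotype label is flipped; in [0, 0.5).
#' @param recombination_rate cM per Mb.
#' @param map_function Only `"haldane"` (no interference) is implemented.
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(population_size = 277, bulk_size = 50,
                         phenotyping_error = 0, recombination_rate = 2,
                         map_function = "haldane") {
  stopifnot_scalar_number(population_size, "population_size", lower = 1)
  stopifnot_scalar_number(bulk_size, "bulk_size", lower = 1)
  stopifnot_scalar_number(phenotyping_error, "phenotyping_error", lower = 0, upper = 0.5 - 1e-12)
  if (2 * bulk_size > population_size) abort("2 * bulk_size must be <= population_size")
  map_function <- match.arg(map_function, "haldane")
  structure(
    list(population_size = as.integer(population_size), bulk_size = as.integer(bulk_size),
         phenotyping_error = phenotyping_error, recombination_rate = recombination_rate,
         map_function = map_function),
    class = "cross_design"
  )
}

#' Describe the read-depth model
#'
#' @param mean_depth Mean reads per SNP per bulk.
#' @param depth_distribution `"poisson"` (default) or `"fixed"`.
#' @param error_rate Per-base symmetric miscall probability, in [0, 0.5).
#' @return An object of class `sequencing_model`.
#' @export
sequencing_model <- function(mean_depth = 30, depth_distribution = c("poisson", "fixed"),
                             error_rate = 0) {
  stopifnot_scalar_number(mean_depth, "mean_depth", lower = 1e-9)
  stopifnot_scalar_number(error_rate, "error_rate", lower = 0, upper = 0.5 - 1e-12)
  structure(
    list(mean_depth = mean_depth,
         depth_distribution = match.arg(depth_distribution),
         error_rate = error_rate),
    class = "sequencing_model"
  )
}

# Haldane map function: recombination fraction for a map distance in cM.
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

# Simulate one pool of gametes from a heterozygous F1. Returns a 0/1 matrix
# (gametes x loci) of mutant-parent alleles for one chromosome.
simulate_gametes <- function(pos, n_gametes, rate) {
  L <- length(pos)
  first <- stats::rbinom(n_gametes, 1L, 0.5)
  if (L == 1L) return(matrix(first, ncol = 1L))
  r <- haldane_r(diff(pos) / 1e6 * rate)
  sw <- matrix(stats::rbinom(n_gametes * (L - 1L), 1L, rep(r, each = n_gametes)),
               nrow = n_gametes)
  # allele_j = first XOR (parity of crossovers up to j)
  cum <- if (ncol(sw) == 1L) sw else t(apply(sw, 1L, cumsum))
  parity <- cum %% 2L
  cbind(first, (first + parity) %% 2L, deparse.level = 0)
}

#' Simulate an F2 population from a heterozygous F1
#'
#' Each F2 individual is the fusion of two independent gametes; gametes are
#' produced by sampling crossovers between adjacent markers under the Haldane
#' map function (no interference), so marginal genotype frequencies at every
#' locus approach 1:2:1.
#'
#' @param genome A [genome_spec()].
#' @param design A [cross_design()].
#' @param seed Integer seed (optional).
#' @return An object of class `f2_population`: integer genotype matrix
#'   (individuals x loci, codes 0/1/2 counting mutant-parent alleles), the
#'   locus table, and the design. Phenotypes are unset until
#'   [assign_phenotypes()].
#' @export
simulate_f2 <- function(genome, design = cross_design(), seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"), inherits(design, "cross_design"))
  loci <- mutate(genome$snp_positions,
                 is_causal = .data$chrom == genome$causal$chrom &
                   .data$pos == genome$causal$pos)
  n <- design$population_size
  geno <- with_seed_if(seed, {
    cols <- lapply(split(seq_len(nrow(loci)), loci$chrom), function(idx) {
      pos <- loci$pos[idx]
      g1 <- simulate_gametes(pos, n, design$recombination_rate)
      g2 <- simulate_gametes(pos, n, design$recombination_rate)
      g1 + g2
    })
    do.call(cbind, cols[unique(loci$chrom)])
  })
  # split() orders chromosomes alphabetically; restore locus order
  ord <- order(match(loci$chrom, unique(loci$chrom)), loci$pos)
  stopifnot(identical(ord, seq_len(nrow(loci))))
  structure(
    list(geno = geno, loci = loci, design = design,
         dominant = genome$causal$dominant, phenotype = NULL),
    class = "f2_population"
  )
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf("<f2_population> %d individuals x %d loci (causal: %s:%d, %s)\n",
              nrow(x$geno), nrow(x$loci),
              x$loci$chrom[x$loci$is_causal], x$loci$pos[x$loci$is_causal],
              if (x$dominant) "dominant" else "recessive"))
  if (!is.null(x$phenotype)) {
    cat(sprintf("  phenotypes: %d mutant, %d wildtype\n",
                sum(x$phenotype == "mutant"), sum(x$phenotype == "wildtype")))
  }
  invisible(x)
}

#' Long-format view of a simulated population
#'
#' @param x An `f2_population`.
#' @param ... Unused.
#' @return A tibble with one row per individual x locus.
#' @method tidy f2_population
#' @export
tidy.f2_population <- function(x, ...) {
  out <- tidyr::expand_grid(individual = seq_len(nrow(x$geno)),
                            locus = seq_len(nrow(x$loci)))
  out$chrom <- x$loci$chrom[out$locus]
  out$pos <- x$loci$pos[out$locus]
  out$code <- as.integer(x$geno[cbind(out$individual, out$locus)])
  if (!is.null(x$phenotype)) out$phenotype <- x$phenotype[out$individual]
  out
}

#' Assign phenotypes from the causal genotype
#'
#' An individual is labelled mutant iff its causal-locus code is >= 1 under a
#' dominant causal allele (== 2 under a recessive one); labels are then
#' flipped independently with probability `phenotyping_error`. With a
#' dominant allele and zero error the expected mutant fraction is 3/4.
#'
#' @param pop An `f2_population`.
#' @param dominant Overrides the dominance flag carried by the population.
#' @param phenotyping_error Flip probability; defaults to the design's value.
#' @param seed Integer seed (optional).
#' @return The population with a `phenotype` field (`"mutant"`/`"wildtype"`).
#' @export
assign_phenotypes <- function(pop, dominant = NULL, phenotyping_error = NULL,
                              seed = NULL) {
  stopifnot(inherits(pop, "f2_population"))
  dominant <- dominant %||% pop$dominant
  phenotyping_error <- phenotyping_error %||% pop$design$phenotyping_error
  code <- pop$geno[, which(pop$loci$is_causal)]
  mutant <- if (dominant) code >= 1L else code == 2L
  if (phenotyping_error > 0) {
    flip <- with_seed_if(seed, stats::rbinom(length(mutant), 1L, phenotyping_error) == 1L)
    mutant <- xor(mutant, flip)
  }
  pop$phenotype <- ifelse(mutant, "mutant", "wildtype")
  pop
}

#' Select two phenotype-contrasted bulks
#'
#' Bulks are disjoint and sampled uniformly without replacement within each
#' phenotype class.
#'
#' @param pop An `f2_population` with phenotypes assigned.
#' @param bulk_size Plants per bulk; defaults to the design's value.
#' @param seed Integer seed (optional).
#' @return A list with integer vectors `mutant` and `wildtype` of individual ids.
#' @export
select_bulks <- function(pop, bulk_size = NULL, seed = NULL) {
  stopifnot(inherits(pop, "f2_population"))
  if (is.null(pop$phenotype)) abort("assign phenotypes before selecting bulks")
  bulk_size <- bulk_size %||% pop$design$bulk_size
  ids_mut <- which(pop$phenotype == "mutant")
  ids_wt <- which(pop$phenotype == "wildtype")
  for (nm in c("mutant", "wildtype")) {
    avail <- if (nm == "mutant") length(ids_mut) else length(ids_wt)
    if (avail < bulk_size) {
      abort(sprintf("only %d %s individuals available for a bulk of %d", avail, nm, bulk_size))
    }
  }
  with_seed_if(seed, list(
    mutant = sort(sample(ids_mut, bulk_size)),
    wildtype = sort(sample(ids_wt, bulk_size))
  ))
}

#' Sample sequencing allele depths over the two bulks
#'
#' At each SNP the true bulk mutant-allele frequency is
#' `p = sum(codes) / (2 * bulk_size)`; a read depth is drawn per bulk from
#' the sequencing model and the mutant-allele read count from
#' `Binomial(depth, p(1-e) + (1-p)e)` with symmetric miscall rate `e`. Under
#' dominant selection the causal SNP has expected `p = 2/3` in the mutant
#' bulk (genotypes 1 AA : 2 Aa among mutants) and 0 in the wild-type bulk.
#'
#' @param pop An `f2_population`.
#' @param bulks Output of [select_bulks()].
#' @param model A [sequencing_model()].
#' @param seed Integer seed (optional).
#' @return A `bulk_counts` tibble: `chrom`, `pos`, `ref`, `alt`,
#'   `mut_bulk_ref`, `mut_bulk_alt`, `wt_bulk_ref`, `wt_bulk_alt`, plus a
#'   `truth` attribute recording the causal locus and the true bulk allele
#'   frequencies. The alt allele is the mutant-parent allele.
#' @export
sample_allele_depths <- function(pop, bulks, model = sequencing_model(), seed = NULL) {
  stopifnot(inherits(pop, "f2_population"), inherits(model, "sequencing_model"))
  L <- nrow(pop$loci)
  freq_of <- function(ids) colSums(pop$geno[ids, , drop = FALSE]) / (2 * length(ids))
  p_mut <- freq_of(bulks$mutant)
  p_wt <- freq_of(bulks$wildtype)
  e <- model$error_rate
  with_seed_if(seed, {
    draw_depth <- function() {
      if (model$depth_distribution == "fixed") rep(as.integer(round(model$mean_depth)), L)
      else stats::rpois(L, model$mean_depth)
    }
    d_mut <- draw_depth(); d_wt <- draw_depth()
    alt_mut <- stats::rbinom(L, d_mut, p_mut * (1 - e) + (1 - p_mut) * e)
    alt_wt <- stats::rbinom(L, d_wt, p_wt * (1 - e) + (1 - p_wt) * e)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    out <- tibble(
      chrom = pop$loci$chrom, pos = pop$loci$pos, ref = ref, alt = unname(alt),
      mut_bulk_ref = d_mut - alt_mut, mut_bulk_alt = alt_mut,
      wt_bulk_ref = d_wt - alt_wt, wt_bulk_alt = alt_wt
    )
    attr(out, "truth") <- list(
      causal = as.list(pop$loci[pop$loci$is_causal, c("chrom", "pos")]),
      p_mut = unname(p_mut), p_wt = unname(p_wt)
    )
    class(out) <- c("bulk_counts", class(out))
    out
  })
}

#' Simulate a complete two-bulk sequencing experiment
#'
#' Convenience wrapper chaining [simulate_f2()], [assign_phenotypes()],
#' [select_bulks()] and [sample_allele_depths()] under one master seed.
#'
#' @inheritParams simulate_f2
#' @param model A [sequencing_model()].
#' @param seed Master integer seed driving all four stages.
#' @return A `bulk_counts` tibble (see [sample_allele_depths()]).
#' @export
simulate_bulk_experiment <- function(genome = default_genome(),
                                     design = cross_design(),
                                     model = sequencing_model(),
                                     seed = NULL) {
  pop <- simulate_f2(genome, design, seed = child_seed(seed, 1L))
  pop <- assign_phenotypes(pop, seed = child_seed(seed, 2L))
  bulks <- select_bulks(pop, seed = child_seed(seed, 3L))
  sample_allele_depths(pop, bulks, model, seed = child_seed(seed, 4L))
}
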