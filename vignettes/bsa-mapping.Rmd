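---
title: "Mapping dominant mutations with two-bulk delta SNP-index profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dominant mutations with two-bulk delta SNP-index profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamapr)
```

## The mapping problem

A single dominant mutation segregating in an F2 population can be located
without genotyping every plant: pool the DNA of plants selected for the
mutant phenotype into one bulk, pool phenotypically wild-type plants into a
second bulk, sequence both, and compare allele frequencies along the
genome. Away from the causal locus the two bulks are random draws from the
same population and their allele frequencies agree; near it, phenotypic
selection drags the bulks apart. bsamapr implements this bulked-segregant
workflow — the MutMap / QTL-seq family of analyses — together with the
satellite analyses that normally accompany it: Mendelian segregation
testing, codon-level classification of candidate SNPs, and design of
CAPS/dCAPS genotyping markers for validating a candidate by restriction
digestion.

## The statistic

For a bulk with `ref` and `alt` read counts at a SNP, the SNP-index is the
fraction of reads carrying the counted allele,

    SNP-index = alt / (ref + alt),

and the delta SNP-index is the difference between the mutant-phenotype and
wild-type bulks,

    delta = SNP-index(mutant bulk) - SNP-index(wild-type bulk).

Allele polarity matters: the package counts the mutant-parent allele (the
VCF alt allele for simulated data, or the allele carried by the mutant
parent when parental genotypes are available), so the causal excursion is
positive by construction.

Under a *dominant* causal allele A, mutant-selected plants are 1 AA : 2 Aa,
so the causal-SNP allele frequency in the mutant bulk has expectation

    E[p] = (1/3)(1) + (2/3)(1/2) = 2/3,

while the wild-type bulk (all aa) has expectation 0. The causal delta
therefore peaks at 2/3 — not 1, as it would for a recessive mutation bulked
on homozygotes. At a locus with recombination fraction `r` to the causal
SNP the expectation decays as `2/3 - 4r/3`, reaching 0 only at `r = 1/2`.
On a single long chromosome nothing is fully unlinked, so significant
windows can legitimately span a large fraction of the chromosome; the
informative quantity is whether the called region contains the causal
position, and where the peak sits.

## Null model and confidence thresholds

Both bulks are finite: even an unlinked SNP shows delta fluctuations from
(a) sampling 2n chromosomes into each bulk of n plants and (b) sampling a
finite read depth from each bulk. `null_thresholds()` simulates exactly
this two-stage null: per bulk, an allele count `k ~ Binomial(2n, 1/2)`
gives a bulk frequency `p = k/2n`, and the observed alt reads are
`Binomial(depth, p)`. Two-sided empirical quantiles of the simulated delta
at 95% and 99% give per-depth-pair thresholds; a fixed-0.5 null would
understate the variance and anti-conservatively narrow them.

Window-level thresholds (`window_thresholds()`) simulate the mean of
independent null deltas at each member SNP's observed depth pair. Member
SNPs in a 1 Mb window are in reality linked within a bulk, so their null
deltas are positively correlated; treating them as independent understates
the null variance of the window mean and makes window thresholds somewhat
liberal for tightly linked markers. This independence approximation is the
standard one for this analysis family and is the package's main documented
approximation.

### Numerical conventions

* **At-or-beyond exceedance.** A window is significant when its mean delta
  *reaches* the threshold (`>=`), and `snp_outliers()` applies the same
  convention per SNP. Read fractions live on a discrete lattice
  (multiples of 1/depth); with a strict inequality the atom sitting at the
  quantile is never counted and the realised per-SNP exceedance rate runs
  systematically below nominal, while the inclusive convention keeps it
  centred.
* **Replicates.** `null_thresholds()` defaults to 10,000 replicates per
  distinct depth pair, which is ample for attaching thresholds to tracks.
  When the point of an experiment is the tail calibration itself we use
  40,000, because the 2.5% tail quantile of a lattice distribution is
  resolved in steps of one atom and benefits from the finer resolution.
  `window_thresholds()` defaults to 1,000 replicates per window: window
  means are much smoother than single-SNP deltas, and profiles contain
  thousands of windows.
* **Depth binning.** `null_thresholds(depth_bin = k)` rounds depths to
  multiples of `k` to cap the table size on deep data; the default (1) is
  exact.
* **Degenerate inputs.** Zero-depth markers have an undefined SNP-index
  and are dropped (tallied); empty windows carry no value and no
  threshold; ties for the peak window resolve to the leftmost; regions on
  different chromosomes never merge.

## Windows, regions, coordinates

`sliding_windows()` tiles each chromosome with windows of 1 Mb advanced by
10 kb (both configurable) and records the unweighted mean delta of the
SNPs with `start <= pos < start + window`. The 1 Mb / 10 kb defaults are
the conventional smoothing scale for rapeseed-sized chromosomes; a 4 Mb
window is sometimes preferred for display and is available by argument.
`call_regions()` finds maximal runs of consecutive significant windows at
the requested level, merges runs whose spans overlap or touch, and reports
the union span, the leftmost maximal-mean window as the peak, and its mean
delta. Internally all coordinates are 1-based inclusive (the VCF
convention); `write_bed()` converts to BED's 0-based half-open intervals.
By default only positive excursions are called, matching mutant-parent
polarity; `two_sided = TRUE` also calls negative ones.

Variant filtering defaults are deliberately mild: at least 7 reads per
bulk, with optional parent-homozygosity and minimum-SNP-index-in-either-bulk
filters switched off unless requested.

## The synthetic experiment generator

The simulator produces complete experiments with known ground truth. Its
defaults mirror a dominant dwarf-mutant mapping design:

| parameter | default | meaning |
|---|---|---|
| population_size | 277 | F2 plants grown |
| bulk_size | 50 | plants per phenotype-selected bulk |
| phenotyping_error | 0 | probability a phenotype label is flipped |
| recombination_rate | 2 cM/Mb | genome-wide average map density |
| map function | Haldane | crossovers without interference |
| mean_depth | 30 per bulk per SNP | Poisson-distributed by default |
| error_rate | 0 | symmetric per-base miscall probability |
| genome | 60 Mb, 3,000 SNPs | causal SNP at 28.3 Mb |

Each F2 individual fuses two gametes simulated from a heterozygous F1;
crossovers between adjacent markers occur with the Haldane recombination
fraction `r = (1 - exp(-2d/100))/2` for map distance `d` cM. Phenotypes
follow the causal genotype (dominant by default), bulks are drawn uniformly
within phenotype class, and read counts are Binomial given the true bulk
allele frequency, with an optional symmetric miscall rate. A 30x mean
depth per bulk is a conventional budget for bulked-segregant sequencing;
2 cM/Mb is a typical average for a *Brassica*-sized genome.

What the generator does **not** emulate: read-level artefacts (mapping
bias, duplicated regions, indel misalignment), variable SNP density,
segregation distortion, multiple causal loci, epistasis, and interference
in crossover placement. Tests that pass on simulated data therefore
validate the statistical machinery — calibration of thresholds, recovery
of a planted locus, correctness of the algebra — not robustness to
alignment artefacts, which an applied analysis must still assess with the
usual depth and parent-homozygosity filters.

One quirk of small dominant designs is worth knowing: with 277 plants
about 1 in 250 simulated populations has fewer than 50 wild-type plants,
and such a draw cannot fill the wild-type bulk. `select_bulks()` refuses
with a count rather than silently bulking fewer plants; replicated
experiments in the test-suite simply redraw in that case, which leaves the
within-class genotype composition (and hence all reported expectations)
unchanged.

## Segregation testing

`chi_square_gof()` tests observed phenotype counts against a Mendelian
ratio with the plain `sum((O - E)^2 / E)` statistic and an upper-tail
chi-square p-value at `classes - 1` degrees of freedom. No continuity
correction is applied by default — the conventional reporting for F2
segregation tables — and the Yates correction is available by flag for
two-class tables. `tidy()` and `glance()` expose the result in broom
shape.

```{r}
glance(chi_square_gof(c(190, 65), "3:1"))
```

## Variant effect classification

`classify_snp()` splices a gene's CDS segments (reverse-complementing
minus-strand genes and honouring the GFF3 phase of the first segment),
locates the affected codon, translates reference and mutant CDS under the
standard nuclear code, and labels the change synonymous, missense,
nonsense, stop_loss or start_loss; SNPs outside every CDS are non_coding.
Transcripts whose CDS length is not a multiple of three are flagged and
skipped rather than guessed. Only SNPs are handled — the package does not
annotate indels or splice-region effects. `motif_report()` returns the
aligned residue window around a motif (default the Aux/IAA domain II
degron core `GWPPV`), so a degron substitution prints as
`GWPPV -> EWPPV`; `filter_candidate_genes()` reduces an effect table to
genes in a called region with at least one protein-changing call.

## CAPS and dCAPS marker design

A candidate SNP is cheaply genotyped when it creates or destroys a
restriction site (CAPS), or when one or two bases engineered into a PCR
primer complete a site for exactly one allele (dCAPS). `find_dcaps()`
scans every enzyme, strand and motif placement covering the SNP; a
placement is reported when the SNP base matches the motif for exactly one
allele and at most `max_mismatches` other window positions need an
engineered base (never the SNP itself). The minimal substitution set is
reported, choosing the alphabetically first base compatible with the
motif's IUPAC class at each engineered position — any compatible base
works for digestion, so the choice is a tie-break, not a constraint.
Primers are reported on the placement strand ending one nucleotide 3' of
the recognition window (25 nt by default, clipped at the amplicon edge).
The built-in table ships EcoRI, BamHI, HindIII, TaqI, MseI and the
non-palindromic type IIS enzyme FokI (`GGATG`), for which only site
presence is modelled — its offset cut position, and gel band sizes in
general, are out of scope, as are primer thermodynamics. `digest()` is
the in-silico verification oracle: all IUPAC matches of a motif on both
strands, 0-based.

## Problem sizes used by the validation suite

The shipped tests and the acceptance script size their simulations for a
desk-class machine: 1,000 replicate bulk draws for the 2/3 expectation,
10,000 single-SNP chromosomes for threshold calibration, and 100 seeded
replicates of the default 3,000-SNP experiment for causal-region recovery
(a 99%-level region must contain the planted position in at least 90).
These sizes give Monte-Carlo error comfortably inside the asserted bands
while keeping the whole suite in the minutes range; they are package
choices, not statistical necessities, and all scale up by argument.

## Known limitations

* Window thresholds assume member SNPs are independent under the null;
  linkage within a bulk makes them slightly liberal at dense spacing.
* A single simulated chromosome leaves every marker partially linked to
  the causal locus, so called regions are wide; interpretation should rest
  on the peak and on containment of candidate positions.
* The effect classifier handles SNPs in CDS only; splice sites, indels,
  UTR and regulatory effects are not modelled.
* dCAPS designs are recognition-site designs; they do not predict band
  sizes for offset-cutting enzymes such as FokI and do not model primer
  melting behaviour.
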