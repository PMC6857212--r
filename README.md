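# bsamapr

Bulked-segregant mapping of monogenic mutations from two-pool sequencing
data, in R.

When a mutant segregates in an F2 population, pooling phenotype-selected
plants into a mutant bulk and a wild-type bulk and sequencing both pools
localises the causal locus without genotyping individuals. At each SNP the
**SNP-index** of a bulk is the fraction of reads carrying the counted
(mutant-parent) allele, `alt / (ref + alt)`, and the

    ΔSNP-index = SNP-index(mutant bulk) − SNP-index(wild-type bulk)

is ≈ 0 at unlinked loci but is dragged away from 0 by phenotypic selection
near the causal locus. For a **dominant** causal allele, mutant-selected
plants are 1 AA : 2 Aa, so the causal ΔSNP-index peaks at 2/3 (not 1).
ΔSNP-index values are smoothed in sliding windows (1 Mb window, 10 kb step
by default) and compared with Monte-Carlo confidence thresholds that
resample both the finite bulks (`k ~ Binomial(2n, ½)` plants' alleles) and
the finite read depth (`Binomial(depth, k/2n)`), at 95% and 99%
two-sided levels; maximal runs of significant windows become candidate
regions.

The package covers the full desk workflow around that statistic:

* **Simulator** — seeded F2 populations under the Haldane map function,
  phenotype-selected bulks, binomial read sampling; ground truth carried
  along for validation (`simulate_bulk_experiment()`).
* **I/O** — two-sample VCF 4.2 (AD/DP) and TSV allele-count tables in,
  depth/parent-homozygosity filters, BED region output
  (`read_bulk_vcf()`, `filter_variants()`, `write_bed()`).
* **Mapping statistics** — `snp_index_track()`, `sliding_windows()`,
  `null_thresholds()`, `window_thresholds()`, `call_regions()`,
  `autoplot()`.
* **Segregation tests** — `chi_square_gof()` against "3:1", "9:3:3:1", …
  with broom-style `tidy()`/`glance()`.
* **Variant effects** — codon-level classification of SNPs on GFF3 gene
  models (`classify_snp()`), including degron-motif reporting
  (`motif_report()`, default `GWPPV`).
* **Marker design** — CAPS and dCAPS restriction-digestion genotyping
  assays with in-silico digestion verification (`find_caps()`,
  `find_dcaps()`, `digest()`).

## Worked example

Segregation of 190 mutant : 65 wild-type F2 plants against the 3:1
dominant expectation:

```r
library(bsamapr)
chi_square_gof(c(190, 65), "3:1")
#> Chi-square goodness of fit vs 3:1 ratio
#>   observed: 190, 65   expected: 191.25, 63.75
#>   X-squared = 0.03268, df = 1, p-value = 0.8565
```

The fit is excellent (χ² = 0.033, P = 0.86): one dominant gene.

Map a simulated experiment end-to-end (60 Mb chromosome, 3,000 SNPs,
bulks of 50 from 277 F2 plants, 30× depth, dominant causal SNP planted at
28.3 Mb):

```r
counts  <- simulate_bulk_experiment(seed = 42)
track   <- snp_index_track(filter_variants(counts, min_depth = 7))
profile <- sliding_windows(track, window_size = 1e6, step = 1e4,
                           chrom_lengths = c(chr1 = 60e6))
profile <- window_thresholds(profile, track, n = 50, seed = 43)
call_regions(profile, level = 0.99)
#> # A tibble: 1 × 7
#>   chrom start      end peak_pos peak_delta n_windows level
#>   <chr> <int>    <int>    <int>      <dbl>     <int> <dbl>
#> 1 chr1      1 60000000 29020000    0.665    5996  0.99
```

The 99% region contains the planted locus; the peak window sits at
29.0 Mb with mean Δ = 0.665, right at the dominant expectation of 2/3.
(On a single 120 cM chromosome every marker is partially linked to the
causal SNP, so the significant span is wide; the peak is the signal.)
`autoplot(profile, track = track)` draws the classic Δ-vs-position panel
with 95%/99% threshold lines.

Classify the candidate SNP on a gene model and design a genotyping marker:

```r
call <- classify_snp(models, genome, "chr1", 15L, "G", "A")
#>   gene_id classification codon_ref codon_alt residue aa_ref aa_alt
#> 1    iaa7       missense       GGA       GAA       2      G      E
motif_report(call$protein_ref, call$protein_alt, "GWPPV")
#>   motif start before after
#> 1 GWPPV     2  GWPPV EWPPV

find_dcaps("CCTCTCGTTGGTTGG", "G", "A", "CCTCCTGTGAAGGAG")
#>    type enzyme strand cut_allele n_mismatches            primer
#> 1 dCAPS   TaqI      +  alternate            1 CCTCTCGTTGGTTCGGC
```

A Gly→Glu substitution in the second codon turns the degron core GWPPV
into EWPPV; a TaqI dCAPS assay with one engineered primer base digests
only the mutant allele.

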