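# scarsig

Downstream analysis of multiregion tumor whole-exome sequencing, built
around the questions a renal-cell-carcinoma study with venous tumor
thrombus (VTT) raises: does a tumor show "BRCAness" — the mutational
footprint of defective homologous-recombination repair — and how much of
its mutational landscape is private to the primary tumor versus the
intravascular thrombus?

The package implements, as tested R code:

* **Mutational catalogues** — somatic SNVs classified into the 96
  trinucleotide channels (`A[C>A]A` …), with a per-channel strand-bias
  filter, a functional-SNV filter, correction for the triplet composition
  of the exome capture versus the whole genome, and 2–10 bp indel counts.
* **Supervised signature refitting** — two-pass non-negative least
  squares (NNLS) against a predefined signature matrix
  (argmin<sub>h≥0</sub> ‖v − W h‖₂): signatures whose relative exposure
  falls below a signature-specific cutoff after pass 1 are removed and
  the reduced set is refitted. Cutoffs are calibrated by ROC analysis
  (Youden's J) on any labeled training cohort.
* **Purity and ploidy** — a grid search over tumor cell content
  (0.15–1.0) and ploidy (1–6.5) scoring the length-weighted distance of
  model-implied copy numbers to allowed integer states, using segment
  coverage ratios r(c) = (ρc + 2(1−ρ)) / (ρψ + 2(1−ρ)) and folded
  B-allele frequencies of germline-het SNPs; allele-specific copy
  numbers, decrease of heterozygosity (DH = |A−B|/(A+B)), infeasibility
  exclusions, ranked local minima, and a MAF-based purity cross-check
  (ρ ≈ 2·mode(MAF)).
* **Genomic scars** — profile smoothing, HRD-LOH (LOH segments > 15 Mb,
  shorter than a chromosome) and LST (state switches between > 10 Mb
  segments not explained by whole arms) scores.
* **Heterogeneity** — gene-level tumor-only / thrombus-only / shared
  classification per patient and a Wilcoxon rank-sum test for the
  association between AC3 (HR-deficiency signature) exposure and
  small-indel burden.
* **Synthetic data** — generators for every input above with known
  ground truth (multinomial catalogues, noisy segmented genomes with
  known purity/ploidy/karyotype, multiregion cohorts with planted
  sharing), so the whole pipeline is testable without access-controlled
  patient data. The packaged 30-signature matrix is a clearly labelled
  synthetic stand-in, not the published COSMIC profiles.

## Worked example

```r
library(scarsig)

## signature refitting on simulated catalogues
W   <- synthetic_signature_set(cutoffs = 0.02)      # 96 x 30, AC1..AC30
sim <- simulate_catalogue(sim_config(seed = 42, n_samples = 4), W)
exp <- cohort_exposures(sim$catalogue, W)
round(exp$H[rowSums(exp$H) > 0, ], 1)
#>        S01   S02   S03   S04
#> AC1  355.7   0.0   0.0   0.0
#> AC5  331.6   0.0   0.0   0.0
#> AC9    0.0   0.0 258.5   0.0
#> AC17   0.0 512.7 214.3   0.0
#> AC25 350.5   0.0   0.0   0.0
#> ...
```

Each column is one sample; entries are exposures in mutation counts
(column sums equal the 1,000 simulated SNVs per sample), and exact zeros
are signatures removed by the two-pass cutoff.

```r
## purity / ploidy from a simulated genome (true tcc 0.7, ploidy 3.5)
g    <- simulate_genome(sim_config(seed = 42, tcc = 0.7, ploidy = 3.5))
ann  <- annotate_segments(g$segments, g$snps)   # het SNPs -> allelic state
head(fit_tcc_ploidy(ann), 3)
#>    tcc ploidy  objective
#> 1 0.71   3.50 0.02430291
#> 2 1.00   5.45 0.24770428
#> 3 0.59   6.10 0.25668953
```

The ranked candidates are local minima of the grid objective; the best
one sits one TCC grid step (0.01) from the simulated truth. Competing
minima (the usual purity/ploidy ambiguity) are reported, not hidden.

```r
## genomic scars: a 30 Mb one-copy LOH on chr1
profile <- data.frame(chrom = "chr1",
                      start = c(1, 3e7 + 1), end = c(3e7, 121535434),
                      total_cn = c(1L, 2L), a_cn = c(1L, 1L),
                      b_cn = c(0L, 1L), real_cn = c(1.02, 1.98))
sm <- smooth_profile(profile)
count_hrd_loh(sm)$hrd_loh   #> 1   (LOH > 15 Mb, < whole chromosome)
count_lst(sm)$lst           #> 1   (mid-arm switch, both flanks > 10 Mb)

## tumor vs thrombus sharing and the AC3/indel association
mr <- simulate_multiregion(sim_config(seed = 42))
classify_sharing(mr$variants)$cohort
#>      n_genes_total           n_shared       n_tumor_only    n_thrombus_only
#>        483.0000000        377.0000000         63.0000000         43.0000000
#>    n_heterogeneous frac_heterogeneous
#>        106.0000000          0.2194617
a <- ac3_indel_association(mr$indels$n_indels,
                           as.numeric(mr$indels$ac3_positive))
c(U = a$statistic, p = signif(a$p_value, 3))
#>        U        p
#> 2.15e+02 6.24e-06
```

22% of mutated genes are compartment-private in this simulated cohort
(the planted fractions), and AC3-positive samples carry significantly
more 2–10 bp indels — the "BRCAness" association the pipeline is built
to detect.

A command-line interface (`inst/cli/scarsig`, or `run_cli()` from R)
wraps the same steps as subcommands: `simulate`, `signatures`, `purity`,
`scars`, `heterogeneity`, `assoc`.

## Documentation

The methods vignette (`vignettes/scarsig-methods.Rmd`) describes the
models and assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
the package's numerical choices and known limitations.
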