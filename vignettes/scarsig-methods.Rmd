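---
title: "Methods: signature refitting, purity/ploidy and genomic scars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature refitting, purity/ploidy and genomic scars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarsig)
```

scarsig implements the downstream computational stages of a multiregion
tumor whole-exome study: mutational catalogues and supervised signature
refitting, purity/ploidy and allele-specific copy-number estimation,
HRD-LOH and LST genomic-scar scores, and tumor-versus-thrombus mutation
sharing. This vignette explains the models, their assumptions, the
tunable parameters, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Mutational catalogues

Somatic single-base substitutions are classified into the 96 canonical
trinucleotide channels: the substitution with a pyrimidine reference
(purine-reference calls are reverse-complemented, flanks swapped), ordered
substitution-major (C>A, C>G, C>T, T>A, T>C, T>G) and then by 5' and 3'
flank. This is the COSMIC v2 row convention, so published signature
matrices align with catalogues both by label and by row position.

**Strand-bias filter.** Sequencing artifacts often manifest as
channel-specific strand asymmetry of alt-supporting reads. The detection
test is not fixed by the convention we follow, so we declare one: per
channel, a two-sided exact binomial test of the pooled forward/reverse alt
counts against 0.5, with a channel flagged when p < 0.05 (configurable)
and the pooled count is at least 10 (sparsely populated channels cannot be
assessed). In a flagged channel the *opposite strand* is the strand with
the smaller pooled count, and variants with fewer than 2 alt reads on it
are removed. The filter is idempotent in practice; a pathological channel
whose majority strand flips after removal could in principle require a
second pass, which we accept rather than iterate.

**Functional filter.** "Functional" means nonsynonymous, splice-site,
stop-gain or stop-loss; missing annotation is an error rather than a
silent keep.

**Triplet correction.** Exome capture covers trinucleotides in different
proportions than the whole genome against which signatures were derived.
Each channel count is multiplied by
$f(t) = \frac{g_t / \sum g}{c_t / \sum c}$
with $g$ and $c$ the genome and capture occurrence counts of the
channel's central triplet $t$; columns are then rescaled to their original
totals so that downstream exposures stay in mutation-count units (matching
per-sample mutation-count reporting). The correction is thus a
within-sample reweighting, not a rescaling of the load.

## Supervised signature decomposition

Given a catalogue column $v \in \mathbb{R}^{96}_{\ge 0}$ and a
column-stochastic signature matrix $W \in \mathbb{R}^{96 \times k}$,
exposures solve the non-negative least-squares problem
$\hat h = \arg\min_{h \ge 0} \lVert v - W h \rVert_2$,
computed with a Lawson–Hanson active-set solver implemented in the
package and cross-checked in the tests against exhaustive enumeration of
all active sets.

Specificity is increased by a second pass: signatures whose *relative*
pass-1 exposure $h_i / \sum_j h_j$ does not exceed a signature-specific
cutoff are discarded (exposure exactly 0) and the reduced set is refitted.
Cutoffs are compared on the relative scale — the open question was
absolute versus relative; relative makes a single per-signature constant
meaningful across samples with very different mutational loads, and gives
exact scale equivariance of the whole procedure. Default cutoffs are 0
(pure NNLS refitting); `calibrate_cutoffs()` regenerates them from any
labeled training cohort by sweeping the observed relative exposures and
maximizing Youden's J (sensitivity + specificity − 1), ties broken toward
the larger (more specific) cutoff. Youden's J is our declared
operating-point rule; the original ROC rule behind the published analyses
is not documented, and the original numeric cutoffs are not published,
which is why they are configuration, not constants.

Samples with at most 25 SNVs (configurable) are removed before cohort
analysis (`min_load_filter()`): below that load the NNLS fit is dominated
by multinomial noise.

### The packaged signature set is synthetic

The published 30-signature matrix is third-party data that this package
does not redistribute. `synthetic_signature_set()` generates a
deterministic stand-in — 30 column-stochastic 96-channel profiles from a
sparse Dirichlet (gamma shape 0.3), named AC1..AC30 — with comparable
sparsity and mutual distinguishability, and the file
`inst/extdata/signatures_ac30_synthetic.tsv` is exactly its output. Every
green signature test therefore establishes properties of the *method*
(recovery, specificity, calibration) on signatures of realistic geometry,
not agreement with the published profiles. Analyses of real data should
load the published matrix with `read_signature_matrix()`, which accepts
the standard COSMIC TSV layout.

## Purity, ploidy and allele-specific copy number

**Inputs.** Coverage-ratio segments (from any segmentation tool) and
germline-heterozygous SNP allele counts. Heterozygous means a normal-
sample alternate-allele fraction in [0.3, 0.7]; segments with fewer than
20 such SNPs are not informative for allelic state.

**Allelic state.** The tumor allele-fraction distribution of each segment
is inspected by kernel density (Silverman's rule bandwidth; peaks must
reach 5% of the density maximum — both configurable, since peak-calling
details are an open design point). A global maximum inside [0.45, 0.55]
calls the segment *balanced*; otherwise one peak calls it *ambiguous*
(excluded downstream) and two or more *imbalanced*. Imbalanced segments
get a folded B-allele frequency: the per-SNP mean of $\max(f, 1-f)$,
i.e. the allele with the higher read count acts as B-allele. Folding
biases the mean upward when the two peaks are within roughly one binomial
standard deviation of 0.5 — the reason automated allelic-state calling
degrades at low purity, and the motivation for the CLI overrides
(`--force-tcc`, `--force-ploidy`) that stand in for the manual rescues
such cases need.

**Mixture model.** A segment at total copy number $c$ in a tumor of
purity $\rho$ (tumor cell content, TCC) and tumor ploidy $\psi$ has
expected normalized coverage ratio
$$r(c) = \frac{\rho c + 2(1-\rho)}{\rho \psi + 2(1-\rho)},$$
inverted to map observed ratios to real-valued copy numbers. For an
imbalanced segment with folded BAF $\beta$ the major allele is
$A = (\beta\,(\rho c + 2(1-\rho)) - (1-\rho)) / \rho$, the minor is
$B = c - A$, and the decrease of heterozygosity is
$DH = |A - B| / c$, which is 0 for balanced segments and 1 at LOH. The
model and the DH formula are this package's declared reconstruction —
the upstream method they emulate is unpublished.

**Grid search.** TCC is scanned over 0.15–1.0 (step 0.01) and ploidy over
1–6.5 (step 0.05); steps are configurable and not externally prescribed.
Each grid point is scored by the segment-length-weighted mean distance to
the nearest *allowed* integer state: the nearest even total for balanced
segments (an undetected 50/50 allele split is only consistent with even
totals), and for imbalanced segments the mean of the distances of total,
major and minor copy to the nearest non-negative integer (the sources
list the three distances without an aggregation rule; the unweighted mean
treats them symmetrically). Grid points *requiring* negative copy states
or DH > 1 are excluded with a machine-readable reason. "Requiring" is
implemented with a slack of 0.5 copies: a fitted value below −0.5 would
round to a negative state; with zero slack, binomial BAF noise on a true
$B = 0$ allele would exclude the true grid point about half the time.

**Reported solutions.** All local minima of the objective are returned
ranked, not just the global one: the likelihood surface of this model is
multimodal by construction (doubling ploidy while adjusting purity
produces competing integer fits), and on a fully balanced genome purity
is not identifiable at all — there the objective is constant along whole
ridges in the TCC direction. We therefore collapse equal-objective
plateau runs along the *ploidy* axis only and keep each TCC column's
representative, so the true point is always among the reported minima in
the degenerate case; collapsing whole plateaus to a single member would
silently hide it. Candidates are ranked by objective with ties broken
toward higher purity and lower ploidy.

**MAF cross-check.** Under the clonal-heterozygous-diploid approximation
a clonal somatic SNV has expected mutant allele fraction $\rho/2$, so
$\hat\rho = \min(1, 2\,\mathrm{mode}(\mathrm{MAF}))$ with the mode from a
kernel density estimate. This is a coarse but segmentation-independent
estimate used to sanity-check the grid solution; below 10 SNVs it is
flagged unreliable.

## Genomic scar scores

Profiles are smoothed before scoring to undo oversegmentation: (1)
adjacent segments with identical rounded (total, A, B) state whose
real-valued copy numbers differ by at most 0.3 are merged; (2) segments
under 3 Mb are absorbed into the neighbor with the closer real-valued
copy number (the neighbor keeps its integer state). The two rules are
iterated to a joint fixpoint, which makes smoothing idempotent; merged
real values are length-weighted means. All thresholds follow the strict
("larger than") reading.

*HRD-LOH* counts segments longer than 15 Mb but shorter than their
chromosome with minor-allele copy number 0 and total at least 1 —
copy-neutral LOH counts, homozygous deletions do not. A fallback
`single_copy_mode` replaces the LOH criterion by total copy number 1 for
samples without allele-specific calls. *LST* counts copy-state switches
where both flanking segments exceed 10 Mb (the two-sided reading of the
segment-size condition; one-sided is configurable), excluding breakpoints
at centromeres and switches whose flanking segment coincides with a full
chromosome arm within a 3 Mb tolerance (the exact window used originally
is unstated, hence configurable). A built-in hg19 arm map derived from
the standard UCSC centromere annotation ships with the package and can be
overridden by file.

## Mutation sharing and the indel association

Per patient, a gene with at least one functional variant is *tumor-only*
if mutated in one or more primary-tumor samples and no thrombus sample,
*thrombus-only* symmetrically, and *shared* otherwise. "Mutated" means
any functional variant in the gene (the identical-variant alternative is
stricter but was not the declared rule); there is no VAF threshold, only
an optional minimum alt-read support (default 1). Cohort totals sum
gene-per-patient events, so one gene mutated in two patients counts
twice. Patients lacking one compartment are excluded with a warning.

The burden association splits samples into AC3-positive (exposure > 0)
and AC3-negative groups and compares 2–10 bp indel counts with a
two-sided Wilcoxon rank-sum test: exact null for combined n ≤ 25 without
ties, normal approximation with tie and continuity correction otherwise.

## The synthetic-data generator

`simulate_catalogue()`, `simulate_genome()` and `simulate_multiregion()`
generate every input the pipeline consumes, with ground truth, under
these stated conditions (all in `sim_config()`):

* **Catalogues**: 20 samples, 1,000 SNVs each, 3–5 active signatures per
  sample with relative exposures ≥ 0.1; channel counts are multinomial in
  the mixture profile. This is the exact noise model of counting
  mutations.
* **Genomes**: a toy karyotype of ten 20 Mb segments whose integer totals
  average the target ploidy exactly, with at least three distinct
  imbalanced allele splits (one majority copy-number pair (t,t) is
  widened to (t−1, t+1) at integer ploidies so the purity/ploidy problem
  stays identifiable). Coverage ratios get lognormal noise with
  σ = 0.01: a segment-level ratio averages thousands of exome baits, so
  per-bait noise of ~20% at 60× leaves well under 1% on the segment mean;
  σ = 0.01 is deliberately conservative. Het SNPs at 10/Mb (the typical
  exome het-SNP yield over a 20 Mb window) with Poisson(60) depths and
  binomial allele counts, each SNP's alternate allele on a random
  parental haplotype; somatic MAFs are binomial at ρ/2. Setting
  `coverage_sigma = 0` switches the generator to a noise-free
  idealization in which read counts take their exact expectations, so the
  closed-loop identity (every downstream estimate exact) holds — with
  stochastic reads a "zero-noise" run would still carry binomial BAF
  noise.
* **Cohorts**: 5 patients × (3 tumor + 3 thrombus) samples; 483
  gene-per-patient events planted as 377 shared / 63 tumor-only / 43
  thrombus-only by default; indel counts Poisson with mean 5
  (AC3-negative) versus 15 (AC3-positive), the 3× ratio used in the
  calibration/power checks; AC3 status is assigned at patient level to
  3 of 5 patients.

What the generator does **not** emulate: subclonality (all events are
clonal), segmentation error (segment boundaries are known), mapping and
GC artifacts in coverage, contamination of the matched normal, sequencing
error in allele counts, and correlated signature activity. A green test
therefore establishes correctness of the estimators under their own
model assumptions — not robustness to everything real exomes do.

## Numerical choices and degenerate inputs

* NNLS: active-set iterations capped at 30k per problem; rank-deficient
  passive sets fall back to minimum-norm coefficients with zeros.
* Relative-exposure cutoffs are applied as strict "greater than"; an
  all-discarded pass 1 yields an all-zero exposure column.
* KDE bandwidth: Silverman's rule everywhere; constant inputs (possible
  only in noise-free simulations) bypass the KDE with a point-mass rule.
* Distance-to-state ties (x.5) follow `round()`'s banker's rounding; grid
  rankings break objective ties toward higher TCC, then lower ploidy.
* Empty inputs: empty variant tables, profiles and catalogues pass
  through as empty results; an all-excluded purity grid and a patientless
  sharing cohort raise errors rather than returning silently.

## Known limitations

* Automated allelic-state classification degrades below roughly 30%
  purity (folded-BAF bias); this mirrors the behaviour of the original
  analysis, which required manual intervention there, and is why forcing
  options exist in the CLI.
* The LST arm-correspondence tolerance and the strand-bias test are
  declared substitutes for unstated originals; both are configurable.
* Exposures are refit per sample independently; no information is shared
  across samples of a patient.
* The purity grid reports candidate solutions; choosing among competing
  local minima on real data may still need the MAF cross-check or
  external knowledge.
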