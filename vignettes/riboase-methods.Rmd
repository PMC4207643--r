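---
title: "Detecting genetic influences on translation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genetic influences on translation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboase)
```

## Overview

riboase asks how genetic variation between two yeast strains (BY and RM)
affects translation, using paired mRNA and ribosome-footprint counts from
the two parents and from the two alleles of their diploid hybrid. Three
quantities are distinguished per gene: mRNA abundance, footprint abundance
(a proxy for protein synthesis), and their ratio, the translational
efficiency (TE). On the log scale used throughout,
log TE = log footprint fraction − log mRNA fraction, so a TE difference is a
footprint difference not explained by the mRNA difference. This vignette
explains the statistical machinery, the choices behind it, and what the
bundled simulator does and does not establish.

## Power-equalizing resampling

Exact count tests gain power with depth, and depth differs both between
libraries (footprint libraries are typically sequenced deeper than mRNA
libraries) and, within a gene, between the mRNA and footprint side. Left
uncorrected, this converts depth differences into apparent biology — e.g. a
highly transcribed but weakly translated gene would be tested with more
power on the mRNA side. Two resampling stages remove this:

1. **Library downsampling** (`downsample_libraries()`). The library with
   the smallest total stays as observed; every other library is drawn down
   to exactly that total *without replacement* (multivariate
   hypergeometric, sequential conditional sampling). Reads are physical
   objects, so sampling without replacement is the faithful model;
   multinomial sampling with replacement is available behind
   `method = "multinomial"` for sensitivity checks. For the hybrid, the two
   allele columns of a replicate come from one sequencing library and are
   downsampled jointly.
2. **Per-gene pair equalization** (`hypergeometric_equalize()`). Per gene,
   the compared samples form an mRNA pair and a footprint pair (two
   strains, or two alleles). The pair with the smaller sum stays; the other
   pair is replaced by one hypergeometric draw of that sum from its pooled
   counts. Afterwards both pairs of every gene carry identical totals, so
   the mRNA and footprint tests run at identical power.

Both stages preserve totals exactly (library totals equal the minimum;
pair sums match per gene) and never increase any count — properties the
test suite asserts as exact identities, alongside Monte-Carlo checks of the
closed-form hypergeometric means.

**Gene filter.** After equalization, genes with any pair sum below 20 or
with any single zero count are removed (the two rules are not redundant:
one pair member can exceed 20 while the other is 0). The thresholds are
inclusive — a pair sum of exactly 20 passes. Exclusions decided on the
equalized data are propagated to the downsampled data, so all derived
statistics and the multiple-testing denominator refer to one gene universe.

## Tests

* **Binomial tests** (`binom_two_sided()`) for differential mRNA and
  footprint expression run on the *equalized* counts with null
  p₀ = 0.5 — the only consistent null once library totals have been made
  equal. Two-sided p-values use the minimum-likelihood convention (sum of
  all outcome probabilities no larger than the observed one), as
  implemented by `stats::binom.test`; an exhaustive-enumeration oracle
  verifies exact agreement for all n ≤ 25.
* **G-tests** (`g_test_2x2()`) for differential TE run on the *downsampled*
  2×2 table (molecule × source): G = 2·Σ O·ln(O/E) with margin-based
  expectations, 1 df, no Williams or Yates correction. The equalized data
  cannot be used here — equalization forces mRNA and footprint counts to
  the same level and would erase the TE signal. Tables with a zero margin
  are degenerate and return p = 1 with a warning; after the gene filter
  such tables cannot arise in the pipeline.
* **Correction.** Bonferroni is the default (threshold α/m on the raw
  scale; at α = 0.05 this gives 9.4 × 10⁻⁶ for m = 5316 and
  1.5 × 10⁻⁵ for m = 3342). Storey q-values (`storey_qvalues()`) are the
  FDR alternative: π₀ is estimated by a df = 3 smoothing spline through
  π₀(λ) = #{p > λ}/(m(1−λ)) over λ = 0, 0.05, …, 0.90, evaluated at
  λ = 0.90; q-values are made monotone by a step-down pass with
  largest-rank tie handling. Below 100 p-values the spline is unreliable
  and π₀ is fixed at 1 with a warning. Note that under a global null the
  q-values all sit near π₀ ≈ 1 — they estimate the FDR incurred at each
  threshold, and rejecting everything down to any p incurs FDR ≈ 1 when
  nothing is real.

## cis/trans decomposition

For a gene regulated purely in *cis*, the parental difference reappears
between the hybrid alleles; for pure *trans*, the hybrid alleles are equal.
The regression of hybrid allelic log₂ fold changes on parental log₂ fold
changes therefore has slope 1 under pure cis and 0 under pure trans. Both
axes carry comparable measurement error, so ordinary least squares (which
attenuates under error in x) is inappropriate; the package fits the
**major axis** (MA) — the first principal axis of the 2×2 covariance
matrix, computed from the closed form
(Syy − Sxx + √((Syy − Sxx)² + 4·Sxy²)) / (2·Sxy) — and the **standardized
major axis** (SMA), sign(Sxy)·√(Syy/Sxx). Uncertainty comes from
resampling genes with replacement (default B = 1000) with percentile 95%
intervals; BCa intervals are available behind `ci_type = "bca"`. The CI is
annotated with whether it excludes 0 and 1. Non-finite fold-change pairs
(zero counts) are dropped pairwise and counted. For comparability, parental
fold changes fed into the slope should come from the same SNP-based
quantification as the hybrid ones.

A caution on interpretation: MA estimation is consistent only when the
error variances on the two axes are comparable. In the parent-versus-hybrid
design they need not be — parents are measured in single libraries while
hybrid alleles sum two replicate libraries, which halves the overdispersion
component of their noise — and under excess dispersion the estimated slope
attenuates even for a purely cis architecture. The package's recovery
experiments therefore validate the estimator where it is identified
(depth-matched libraries, counting noise only, recovering slopes of 1 and
0 for pure-cis and pure-trans architectures), and real-data slopes should
be read the way noisy slopes always are: through their bootstrap intervals
rather than as point estimates of the cis fraction.

`stratified_slopes()` repeats the fit within eQTL annotation classes
(local-only, distant-only, both) and reports pairwise CI overlap: genes
with local (likely cis-acting) eQTL should show steeper slopes than genes
with distant (likely trans-acting) eQTL. `replicate_error_by_bin()`
estimates the measurement-error variance of fold changes as
var(rep₁ − rep₂)/2 within equal-size abundance bins — under counting noise
it decreases with abundance.

## Directional classification of TE genes

Among genes with a significant TE difference, the mRNA and footprint calls
and fold-change signs define six mutually exclusive categories: footprint
difference only (`fp_only`); both significant and same direction with the
footprint difference larger (`reinforced`) or smaller (`buffered`); mRNA
only (`completely_buffered`); both significant with opposite signs
(`inverted`); neither (`neither`). Two measure-zero edge cases are resolved
deterministically and logged when they fire: an exact magnitude tie goes to
`buffered`, and a zero fold change with a significant flag counts as
sign-agreeing.

Whether translation preferentially amplifies expression differences is
then a ratio question. Because the answer can depend on which genes count
as "amplifying" and "opposing", all four comparisons are reported:
reinforced (optionally + fp_only) versus buffered + completely buffered
(optionally + inverted), each tested against an equal-frequency null with
the χ² statistic (a − b)²/(a + b), 1 df, no continuity correction. The
"buffered" side pools partial and complete buffering — the pooling that
reproduces the published ratios (2.0, 1.6, 1.1) from the published
category counts. External datasets (e.g. interspecies comparisons
distributed as fold-change/p-value tables) enter through
`harmonize_external()` with a column mapping and one of three significance
rules (Bonferroni, q < α, pre-corrected p < α) applied uniformly to all
three tests.

## SNP-site filtering for unbiased ASE

Allele-specific quantification is only as good as its SNP sites. The
package vets sites on hybrid *DNA* counts, where any allelic imbalance is
necessarily technical: an unbiased reference distribution is simulated as
Binomial(depth, 0.5) at the observed depths
(`generate_unbiased_hybrid_dna()`, `calibrate_against_null()`), and sites
are excluded for coverage > 100× or < 30× (bounds exclusive: exactly 30 or
100 is kept), BY-allele frequency < 0.3 or > 0.7, or location in a
segmental-duplication region. Duplications present in RM but not BY
produce a characteristic ~2:1 RM bias (allelic ratio ≈ 1/3);
`detect_duplication_regions()` finds them as runs of at least 10
consecutive sites with RM/BY parental coverage ratio ≥ 1.7, absorbing up
to 2 sub-threshold sites into a run so that Poisson noise in per-site
coverage does not fragment genuine regions. Window, threshold and gap are
configurable; the defaults are a deliberately simple algorithmic stand-in
for what is ultimately a judgment call about structural variation, and are
not calibrated to reproduce any particular published region list.
Upstream mappability filtering (alignment to both parental references) is
assumed already done; this module starts from count tables.

## pQTL comparison

Protein-QTL mapped by bulk segregant analysis come with allele-frequency
differences at the QTL location rather than direct effect sizes; summing
them per gene (`sum_pqtl_effects()`, opposite signs cancelling) gives a
rough aggregate expectation of trans-acting protein-level effects. These
sums are compared to mRNA and footprint fold changes by Spearman
correlation (average ranks, t-approximation for p). Whether footprints
track the pQTL effects better than mRNA does is assessed by a gene-level
bootstrap (B = 1000): the contrast p is the fraction of replicates where
the mRNA correlation *strictly* exceeds the footprint correlation — ties
count against, taken literally from the definition.

## The simulator: what it emulates, and what it does not

`generate_expression_dataset()` draws, per gene, a baseline log₁₀ mRNA
abundance (Normal, SD 0.9 → the central 95% of genes span ≈ 3.5 orders of
magnitude) and a log₁₀ TE (SD 0.5 → ≈ 100-fold TE variation). Effects are
multiplicative on rates, i.e. additive in log₂, drawn Normal(0, 0.5 log₂
units) for configured fractions of genes: *cis* and *TE* effects apply to
the BY parent and the BY allele of the hybrid; *trans* effects apply only
in the parents, because trans-acting factors act on both hybrid alleles
equally. Footprint rates are mRNA rate × TE × 2^(TE effect). Counts are
gamma-Poisson (negative binomial) with one dispersion parameter, scaled so
column totals match configured library sizes in expectation; footprint
libraries default to 1.5× the mRNA depth, mirroring typical practice. An
optional orientation parameter (`te_reinforce_prob`) couples TE-effect
signs to the gene's mRNA difference, for studying directional
classification; at its default 0.5 the effects are independent. All
randomness flows from one integer seed; the same seed reproduces the
dataset bit for bit.

Deliberate simplifications: no positional footprint structure along ORFs,
no UTRs, no alignment or mappability artifacts, no correlation between
abundance and TE, replicates as independent draws from identical rates. A
green test suite on this generator therefore demonstrates *statistical*
correctness (calibration, parameter recovery, invariances) — not
robustness to alignment bias or batch structure in real libraries.

Two sizing choices matter for interpretation. The default dispersion 0.05
is a conventional magnitude for well-controlled sequencing experiments,
not an estimate from any particular dataset. And calibration checks of
type-I error run at dispersion 0: the binomial and G tests model counting
noise only (conditionally binomial under the null), so any extra-Poisson
dispersion makes them anticonservative by construction — a property of
exact count tests generally, not of this implementation. With
overdispersed replicates, the tests answer "is the imbalance larger than
counting noise allows", which is exactly how their results should be read.

## Numerical and design notes

* **TE sign convention.** TE is footprint over mRNA; the TE log₂ fold
  change equals footprint fold change minus mRNA fold change, an identity
  the suite asserts exactly. Positive fold changes mean higher in BY (or
  the BY allele).
* **Zero counts.** log₂(a/b) with a zero is flagged non-finite and the
  gene excluded from tests requiring finite values; in the standard
  pipeline the zero-count filter removes such genes up front.
* **Determinism.** Every stochastic step takes an explicit seed;
  `te_analysis(seed = s)` derives its stage seeds (s, s + 1), and repeated
  runs produce byte-identical result tables (the run manifest differs only
  in its timestamp).
* **Problem sizes.** The test suite and the acceptance script use 2000 to
  5000 simulated genes and library totals of 0.4–3 million reads — the
  scale at which slope recovery, type-I calibration within 3 binomial SEs,
  and ≥ 90% site-filter sensitivity are comfortably identifiable while a
  full run stays under a minute on one core.
* **Degenerate inputs.** Zero-margin G-tables return p = 1 with a warning;
  MA orientation is undefined at Sxy = 0 with Sxx = Syy (error); SMA
  requires nonzero x-variance and covariance; bootstrap with B < 100
  warns; fewer than 100 p-values pin π₀ to 1.

## Known limitations

The slope heuristic summarizes cis/trans contributions in aggregate; it is
not a per-gene variance decomposition. The duplication-region detector is
a windowed heuristic whose parameters trade sensitivity against boundary
precision. The q-value implementation follows the spline-smoothed π₀
recipe and will differ in the third decimal from implementations using
other λ grids. Analyses start from counts: alignment, de-duplication and
SNP mappability are upstream concerns the package trusts its input to have
handled.
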