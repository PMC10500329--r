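---
title: "Methods: thermal tolerance and heat-stress transcriptomics in ants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal tolerance and heat-stress transcriptomics in ants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antherm)
```

`antherm` packages the statistical machinery of a comparative heat-stress
study: survival dose–response estimation, consensus differential
expression, cross-species annotation overlap against a resampling null,
and orthogroup-based classification of conserved versus taxonomically
restricted genes. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Survival dose–response

Each observation is one tube: `n_dead` of `n_total` workers moribund
after a 3-hour exposure at temperature `T` (°C). Death is modelled as the
event (the LT50 is identical either way):

$$\mathrm{logit}\,P(\text{death}) = \beta_0 + \beta_1 T, \qquad
\mathrm{LT50} = -\beta_0/\beta_1 .$$

`fit_dose_response()` maximizes the binomial likelihood by IRLS
(deviance tolerance 1e-8, ≤ 100 iterations). Assays at 2 °C spacing
routinely produce *separated* data — every tube fully alive below some
temperature and fully dead above — where the ML slope diverges. Rather
than refuse to fit, the function detects separation (non-convergence,
|slope| > 20 per °C, or slope SE > 5) and refits with Jeffreys-prior
(Firth) penalization, flagging `method = "firth"`. The penalized estimate
places the LT50 at the midpoint of the kill gap with a finite standard
error, which is the scientifically sensible summary of such an assay.

Confidence intervals use the delta method with gradient
$(-1/\beta_1, -\mathrm{LT50}/\beta_1)$; this was chosen over Fieller
intervals because it matches the construction used by the standard
ecotoxicology ratio test the package also implements, and it is a
swappable policy (the full coefficient covariance is returned).
`ratio_test()` compares two species by
$z = \log(\mathrm{LT50}_A/\mathrm{LT50}_B)\big/\sqrt{(se_A/\mathrm{LT50}_A)^2+(se_B/\mathrm{LT50}_B)^2}$
with a two-sided normal reference. Simulation at the default assay design
(7 temperatures × 6 tubes × 10 workers, slope 1.5/°C) gives LT50 bias
below 0.01 °C, CI coverage ≈ 0.94–0.95, and ratio-test type-I error
≈ 0.05–0.06 — these are recomputed by `scripts/acceptance.R` and the
test suite rather than asserted here.

### Upper thermal limit

The UTL is operationalized as the highest assayed temperature whose
per-tube survival proportions do not differ from the reference group
under Tukey HSD (α = 0.05) after a one-way ANOVA across temperature
groups. Two interpretation choices deserve note:

* The reference is the *highest-mean-survival* group (ties broken to the
  lowest temperature), not a nominal "100%" constant — a contrast against
  an exact constant has zero variance and is undefined.
* Proportions enter raw (no arcsine transform), at tube level, because
  nothing in the study design calls for more.

When every group is at 100% survival with zero variance the ANOVA is
undefined and the UTL is reported as the highest tested temperature with
a `degenerate` flag. With zero residual variance but differing means,
groups identical to the reference count as indistinguishable.

A caveat the test suite makes explicit: under the package's own pure
logistic-binomial generator, low-temperature groups have exactly zero
variance, which shrinks the pooled ANOVA mean square so far that one or
two chance deaths just below the LT50 become Tukey-significant. For a
steep species with LT50 at 49.8 °C the recovered UTL therefore alternates
between 47 and 49 °C (49 modal) instead of being 49 °C almost always;
real assays, with their nonzero handling mortality in every group, are
more forgiving. The tests assert the distributional fact, not an
idealized recovery rate.

### Decline width

`decline_width()` reports `t_zero − t_high`, where `t_high` is the
highest tested temperature with mean survival ≥ 0.90 and `t_zero` the
lowest with mean survival ≤ 0.05. The thresholds operationalize "from
around 100% to 0%" and are configuration parameters; at the default 2 °C
assay grid the width resolves to even numbers, so steep (slope ≥ 4/°C)
species report 2–4 °C and shallow species (slope 0.8/°C) 6–10 °C.

## Expression response

### TMM normalization

`tmm_factors()` implements the standard trimmed-mean-of-M-values recipe,
since the method is referred to only by name in this field: reference
sample by 75th-percentile count fraction closest to the mean; genes zero
in sample or reference excluded; 30% two-sided trim on M-values, 5% on
A-values; inverse asymptotic-binomial-variance weights; factors rescaled
to geometric mean 1. All four constants are exposed as arguments. The
implementation agrees with an independently coded naive recomputation to
1e-10 and with `edgeR::calcNormFactors` to the same tolerance (both are
cross-checks in the test suite, not the implementation). Normalized
values are CPM on effective library sizes.

### Differential expression and the consensus filter

The package's built-in caller (`de_test()`) is deliberately lightweight:
log2 fold changes from TMM-normalized condition means with a 0.5
pseudo-value; a single common dispersion estimated by the method of
moments on library-size-equalized counts (floored at 1e-4, so the test
never assumes sub-Poisson noise); p-values from a double-tail exact-style
test on the two condition sums, each negative binomial with size
`n_reps/φ`, conditioning on their total and summing partition
probabilities no larger than the observed one (full enumeration up to
totals of 1e5, a ±40 SD window above). Under a true NB null with 4+4
replicates its p-values are uniform to within KS-test resolution at 2000
genes. It is *not* a replacement for edgeR/DESeq2 dispersion machinery
(no trended or tagwise dispersions, no shrinkage) — it exists so that
fully self-contained synthetic runs have two independent callers:
`run_de()` dispatches either the built-in test or edgeR's classic
exact-test pipeline, and `run_study()` intersects the two.

`consensus_det()` applies the stringent selection rule: FDR ≤ 1e-3 in
*both* callers and mean |log2FC| ≥ 2. One point the rule's plain reading
leaves open is whether opposite-sign fold changes could jointly qualify;
the package additionally requires sign concordance, because a "DET" that
one caller sees up- and the other down-regulated is uninterpretable. DET
percentages are computed against the full reference transcriptome (the
published per-species fractions reproduce exactly on that basis, not on
the nonzero-expressed subset).

### HSP panels, profiles and strategies

`find_hsp_transcripts()` treats the six canonical search strings
(`Hsp70`, `Hsp 70`, `Heat shock protein 70`, and the 90-family
equivalents) as case-insensitive literal substrings — no regular
expressions, no fuzzy matching — and selects per family the isoform with
the highest mean normalized expression. `classify_profile()` cuts the DET
percentage at 0.3% and 5%: the published per-species fractions cluster as
{0.12, 0.14} ≪ 0.3 < {0.60, 1.53} < 5 < {8, 12.71}, so the defaults
separate the three observed response tiers with an order of magnitude of
slack on either side. `call_strategy()` is a transparent rule:
desert + weak + no HSP induction → constitutive; desert + medium/strong +
HSP induction → reactive; temperate → temperate-like; anything else is
left `unclassified` with its evidence attached rather than forced into a
category.

## Cross-species overlap

Annotation names are reduced by trimming, case-folding, dropping empty
entries and anything containing "uncharacterized protein", then
deduplicated (`unique_meaningful_names()`). The Monte-Carlo null
(`resampling_null()`) resamples *transcripts* — not names — from each
full transcriptome and reduces each draw to names, mirroring how a DET
list arises; with isoform redundancy these two sampling units genuinely
differ, and the transcript-level choice is asserted by a closed-form
check: on redundancy-free catalogs the null mean must equal
$s\,n_A n_B/(|A||B|)$. Sampling is without replacement; the empirical
p-value uses the $(1+k)/(N+1)$ estimator so it is never zero; the null
mean and SD (denominator $N-1$) populate "expected (SD)" table cells. The
subsequent manual curation of partial annotation matches that a human
analyst might perform is explicitly out of scope — significance is
defined on the uncurated comparison.

## Orthology

`classify_orthogroups()` maps species-presence patterns to categories
with precedence V → IV → II/III → I, which resolves the containment of
the two-species *Cataglyphis* pattern (IV) within "Formicinae only"
(III). Patterns spanning both subfamilies while missing some species fall
in none of the five categories; they are labelled `mixed_partial` and
treated as *conserved*, since cross-subfamily presence implies an
ancestral gene. Unassigned genes (in the catalog but in no orthogroup)
are excluded from enrichment by default — restricted status is defined
through lineage-specific *orthogroups*, not assembly singletons — with a
flag to count them as restricted for sensitivity analysis.

`restricted_enrichment()` uses the conventional two-sided Fisher exact
test (summing hypergeometric point probabilities ≤ the observed table's,
with the standard 1 + 1e-7 tie tolerance); the odds ratio is the sample
odds ratio, Haldane-corrected only when a cell is zero and flagged when
so. Published study-wide summary counts need not equal per-species table
sums (orthology tools deduplicate differently at the two levels), so
`orthology_summary_from_counts()` accepts the study-wide species-specific
orthogroup count as an independent input.

## The synthetic-data generator

`simulate_study()` emulates the structure of a six-species
desert/temperate comparison with known ground truth:

* **Survival**: per tube, `Binomial(10, plogis(slope · (T − LT50)))` at
  39–51 °C in 2 °C steps, 6 tubes per temperature. True LT50s are the six
  published estimates (39.91–49.83 °C); slopes are 0.8/°C for the two
  wide-decline species and 4–5/°C for the four narrow-decline species,
  values implied by the reported 6 °C versus 2 °C survival decline
  windows.
* **Transcriptomes**: catalogs at 1/20 of the published sizes
  (~1.9k–4.2k transcripts) for desk-scale runtime, with 25%
  "uncharacterized protein" rows, a shared conserved-name pool (HSP70 and
  HSP90 names always present in every species), species-private names,
  and isoform redundancy (multiple transcripts per name).
* **Counts**: negative binomial with gene-wise log-normal means
  (meanlog 4, sdlog 1.5), common dispersion 0.1, library sizes ±30% —
  standard bulk RNA-seq emulation values. Stress genes number the
  published DET counts / 20 for induced species (log2FC 3 under heat) and
  ~50 for constitutive species (8× elevated in *both* conditions, no
  differential signal).
* **Orthogroups**: category mixture proportional to the published
  category counts (I 25.6%, II 3.1%, III 1.0%, IV 2.6%, V 26.9%, mixed
  40.8%), genes drawn from the catalogs without reuse.

One master seed derives per-stage seeds through a fixed linear map
(`stage_seed()`), so any stage can be regenerated independently and all
output is bit-reproducible. An audit pass (`audit_study()`) re-derives
shared-name counts, orthogroup categories and truth consistency from the
emitted objects on every run.

What the generator does **not** emulate: read-level noise and mapping
ambiguity, GC/length biases, gene-wise dispersion trends, correlated
expression modules, batch effects, partial or fuzzy annotation matches,
and background assay mortality. Passing tests therefore demonstrate that
the statistics recover the planted structure under clean NB/logistic
assumptions — they do not certify performance on real libraries, where
caller disagreement and dispersion misspecification are larger.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the default-scale study
(1/20 transcriptomes, 10,000 overlap iterations, 1000-replicate
LT50/ratio simulations), sizes chosen so a complete desk run finishes in
a few minutes while keeping every Monte-Carlo band at least three
standard errors wide. Other numerical policies, gathered in one place:
IRLS deviance tolerance 1e-8; Firth step damping at 5 units; dispersion
floor 1e-4; fold-change pseudo-value 0.5; exact-test enumeration window
1e5 with ±40 SD tails; Fisher/exact-test tie tolerance 1 + 1e-7 relative;
TMM trim constants 30%/5%; empirical p estimator (1+k)/(N+1); all
reported percentages carried unrounded with rounded companions (2
decimals for DET fractions, 1 for orthology).

## Known limitations

* The built-in DE caller's single common dispersion will be
  anticonservative on data with strong dispersion trends; use the edgeR
  caller (or externally produced tables) for real libraries.
* Delta-method LT50 intervals undercover slightly on very steep curves
  where the penalized fit dominates; coverage is verified only at the
  default design.
* The UTL operationalization is one reading of "not significantly
  different from full survival"; alternatives (e.g. Dunnett contrasts
  against a fixed control) would shift results on borderline assays.
* Orthogroup categories depend only on presence/absence; copy number and
  tree-aware refinement are out of scope.
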