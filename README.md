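# antherm

Comparative analysis of heat tolerance and the transcriptomic heat-shock
response in ants.

Thermophilic desert ants (*Cataglyphis*, *Melophorus*, *Ocymyrmex*) forage
at ground temperatures close to their own lethal limits, while related
temperate species (*Formica*, *Myrmica*) never face such extremes. A
recurring observation in six-species comparisons of these genera is that
desert ants respond to near-lethal heat with *fewer* gene-expression
changes than temperate ants, and that desert lineages split into two
strategies: a **constitutive** one (chaperones such as HSP70/HSP90 already
highly expressed in unstressed workers, very few differentially expressed
transcripts, and a survival curve that collapses within ~2 °C) and a
**reactive** one (chaperones induced by heat, a broader expression
response, and survival declining gradually over ~6 °C). `antherm`
implements the full analysis chain behind such a comparison as a tested,
reusable R package, together with a synthetic-study generator so every
stage can be validated against known ground truth without any external
data.

## What it computes

**Thermal tolerance.** Worker survival assays (tubes of workers held 3 h
at fixed temperatures) are modelled by a binomial logistic regression of
death probability on temperature,

logit P(death) = β₀ + β₁·T,   LT50 = −β₀/β₁,

fit by maximum likelihood with a Jeffreys-prior (Firth) fallback for
separated data (complete kill/no-kill series are common in these assays).
The LT50 standard error follows from the delta method with gradient
(−1/β₁, −LT50/β₁). Two species are compared with a ratio test on
log(LT50_A/LT50_B); the upper thermal limit (UTL) is the highest assayed
temperature whose per-tube survival does not differ from the best-surviving
group (one-way ANOVA + Tukey HSD); the decline width is the temperature
interval over which mean survival falls from ≥ 90% to ≤ 5%.

**Expression response.** Count matrices are normalized by the trimmed mean
of M-values (TMM; 30% M-trim, 5% A-trim, inverse-variance weights) and
expressed as CPM on effective library sizes. Differential expression
between heat-stressed (HS) and control (NHS) workers uses two callers — a
built-in negative-binomial exact-style test with a method-of-moments
common dispersion, and edgeR's classic exact-test pipeline — and keeps a
transcript only if **both** callers give FDR ≤ 1e-3, the fold changes
agree in sign, and the mean |log2FC| ≥ 2. HSP70/HSP90 panels are extracted
by literal substring search on annotations; each species' response is
classified weak/medium/strong from its DET percentage (cut points 0.3% and
5%) and combined with habitat and HSP evidence into a
constitutive/reactive/temperate-like strategy call.

**Cross-species overlap.** DET lists are reduced to unique, meaningful
annotation names (case-folded, trimmed, "uncharacterized protein" dropped)
and pairwise overlaps are referred to a Monte-Carlo null: resample each
species' DET count from its full transcriptome, reduce to names, count the
overlap, repeat (default 10,000 iterations); the empirical p-value is
(1 + #{null ≥ observed}) / (N + 1).

**Orthology.** Orthogroup tables (OrthoFinder dialect) are classified into
taxonomic categories — I (all species), II (Myrmicinae only), III
(Formicinae only), IV (both *Cataglyphis* species), V (species-specific) —
with IV/V defining taxonomically restricted ("new") genes. Restricted-gene
enrichment among DETs uses a two-sided Fisher exact test (hypergeometric
point-probability summation), and summary tables report per-species and
study-wide assignment percentages.

## Worked example

```r
library(antherm)

study <- simulate_study(seed = 1)     # six-species synthetic study
obs   <- study$survival[study$survival$species == "Mbag", ]

fit_dose_response(obs)
#> Dose-response fit (firth, Mbag): LT50 = 49.87 C (95% CI 49.51-50.23), slope = 4.238/C
determine_utl(obs)
#> UTL = 49 C (reference 39 C, alpha 0.05)
decline_width(obs)
#> Survival decline: 49 -> 51 C, width 2 C

res <- run_study(study, study_config(seed = 1))
res
#> Comparative heat-stress study results
#>   species   habitat  lt50 se_lt50 utl decline_width det_count
#> 1    Cbom    desert 45.10  0.2008  41            10        13
#> 2    Chol    desert 46.13  0.1841  45             2         0
#> 3    Mbag    desert 49.87  0.1841  49             2         0
#> 4    Orob    desert 47.05  0.2055  43             8        36
#> 5    Ffus temperate 42.21  0.1737  41             2       250
#> 6    Msab temperate 39.87  0.1841  39             2       533
#>   transcriptome_size det_fraction profile       strategy
#> 1               2096       0.6202  medium       reactive
#> 2               2226       0.0000    weak   constitutive
#> 3               1936       0.0000    weak   constitutive
#> 4               2285       1.5755  medium       reactive
#> 5               3121       8.0103  strong temperate_like
#> 6               4239      12.5737  strong temperate_like
#>
#> Size~DET correlation: r = 0.994 (p = 5.59e-05)
```

The synthetic study plants two constitutive desert species, two reactive
desert species and two temperate species; the pipeline recovers every
strategy from the data alone — the constitutive species show zero
consensus DETs (their chaperones are high in both conditions), the
reactive species show medium responses with induced HSPs, and DET counts
track transcriptome size across all six species.

A thin CLI wraps the same functions:

```sh
antherm simulate --out study/ --seed 1
antherm lt50 --survival study/survival.csv
antherm run-all --out report/ --seed 1
```

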