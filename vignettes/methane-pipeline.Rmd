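---
title: "Methods: from chamber closures to community assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chamber closures to community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricemethane)
```

`ricemethane` chains together the quantitative stages of a paddy-field
methane study: chamber flux and cumulative emission, qPCR gene abundances,
ASV community summaries, Sloan's neutral community model, SPEC-OCCU
specialist classification, co-occurrence networks, and Mantel association
tests. This vignette documents the models, the defaults and why they were
chosen, what the synthetic-data generators do and do not emulate, and the
numerical decisions a user should know about.

## Chamber fluxes

A closure records headspace CH₄ mixing ratios (ppmv) at fixed minutes after
sealing (conventionally 0/15/30). `fit_slope()` estimates Δc/Δt by ordinary
least squares over all points (an endpoint-difference option exists for
two-point protocols); with exactly two points the slope is the endpoint
difference and r² is recorded as 1, as it is for a zero-variance series —
both conventions keep the QC column well defined without inventing
information. `compute_flux()` applies

$$F = \rho \, H \, \frac{\Delta c}{\Delta t} \, \frac{273}{273 + T},$$

with $\rho$ = 0.717 mg cm⁻³ (CH₄ density at 0 °C, 101 kPa), $H$ the chamber
height above the water layer in m, and $T$ the mean in-chamber temperature
in °C. A note on units: with $\rho$ in mg cm⁻³ (numerically kg m⁻³) the
equation returns mg m⁻² h⁻¹ only when Δc/Δt is a ppmv (volume-fraction)
rate, because $\rho$ itself performs the volume-to-mass conversion. The
package therefore ingests concentrations in ppmv; `conc_unit = "mg_m3"`
accepts mass concentrations and divides the density back out. Negative
slopes (net CH₄ uptake by the soil) are retained and produce negative
fluxes.

`cumulative_emission()` integrates plot-level fluxes by the trapezoid rule
over calendar dates, times 24 to convert day intervals to hours — exact for
piecewise-linear flux, and no gap-filling is attempted for missed dates.
Two seasonal averages are reported because the field convention is
ambiguous: the arithmetic mean of fluxes (mg m⁻² h⁻¹, the unit in which
average fluxes are typically quoted) and the literal
cumulative-divided-by-number-of-samplings quantity (units mg m⁻²). Both are
emitted; neither is silently preferred.

Treatment effects use `stats::aov`: one-way across all treatments plus a
two-way N rate × Fe analysis restricted to the crossed cells (a lone
conventional-N control without an Fe companion stays in the one-way
analysis only). Tukey HSD contrasts carry the conventional star codes at
0.05/0.01/0.001. QC on slope r² is available but off by default — flagged
closures are marked, never dropped.

## qPCR calibration

Standard curves regress Cq on log₁₀(copies) (instrument convention;
slope ≈ −3.32 at perfect doubling). Efficiency $E = 10^{-1/\text{slope}}-1$
depends only on the slope, so intercept shifts between plates do not affect
it; curves at or below 90 % are flagged, the usual acceptance practice for
soil assays. Technical replicates are averaged on the Cq scale (Cq is the
approximately normal scale), non-detects stay missing rather than becoming
zeros, and `gene_ratio()` aggregates treatment-level *mcrA*/*pmoA* as the
mean of per-sample ratios — not the ratio of means, which differs whenever
denominators vary.

## Community summaries

Count tables are samples × ASVs with a `sample_id` column. Singleton ASVs
(total count one across all samples) are droppable at ingest via
`filter_singletons()`, matching standard denoising practice. Relative
abundance, taxonomy aggregation (unmapped lineages pool into
"unclassified"), richness/Shannon/Simpson (vegan, natural log), and
Bray–Curtis distances (vegan) follow the field's standard definitions.
No rarefaction is applied by default; `rarefy_counts()` provides seeded
even-depth subsampling when diversity comparisons require it. Core-ASV
counts enumerate every Venn region with presence defined as ≥ 1 read in
≥ 1 sample of a group (an "all replicates" rule is available).

## The neutral community model

For a taxon with regional mean relative abundance $p$, the Sloan model
takes local relative abundances as Beta$(Nm\,p,\ Nm(1-p))$, where $N$ is
the community size and $m$ the immigration rate. The classical fit predicts
occurrence frequency as the probability of exceeding a detection limit $d$
(one read at mean depth, $d = 1/N$, by default):
$1 - \mathrm{BetaCDF}(d;\ Nm\,p,\ Nm(1-p))$ — this is `ncm_predict()`.

Sequencing data add a layer the threshold approximation ignores: reads are
a finite sample of the local community, so a taxon whose latent proportion
exceeds $d$ can still yield zero reads and vice versa. Under the beta model
the exact detection probability among $N$ reads has closed form

$$P(\text{detected}) = 1 - \frac{B(a,\ b + N)}{B(a,\ b)},
\qquad a = Nm\,p,\ b = Nm(1-p),$$

the zero-truncation probability of the beta-binomial. `ncm_fit()` uses this
curve by default (`detection_model = "beta_binomial"`) because in recovery
experiments against communities simulated with beta-distributed weights and
multinomial read sampling the threshold fit overestimates $Nm$
substantially when dispersal is strong (relative errors on $m$ of roughly
20–35 % across $m$ = 0.05–0.3), while the beta-binomial fit is essentially
unbiased (median error ≈ 3 %). The classical curve remains available via
`detection_model = "beta_cdf"` for comparability with published fits.

Numerics: the single free parameter is optimised as log₁₀(Nm) ∈ [0, 7] by
bounded quasi-Newton descent from three log-spaced starts (1, 3, 5) — the
objective is smooth and unimodal in practice, but the multi-start guards
against flat shoulders at extreme $Nm$. $R^2 = 1 - SSE/SST$ on
untransformed frequencies may be negative for non-neutral data; a table in
which every ASV occurs everywhere has no frequency variance and raises an
explicit fit-failure error. Bootstrap CIs resample ASVs (the fitting unit)
with replacement, refit from the base-fit optimum, and take percentile
2.5/97.5 bounds; replicate failures above 20 % trigger a recorded warning.
Partition labels (above/neutral/below) compare each observed frequency to
a Wilson binomial band around the fitted prediction with $n$ = number of
samples — the Wilson interval behaves correctly at frequencies near 0 or 1
where the Wald interval degenerates.

## SPEC-OCCU

Specificity of ASV $S$ for habitat $H$ is its mean relative abundance in
$H$ divided by the sum of those habitat means over all habitats (so each
ASV's specificities sum to 1); occupancy is the fraction of $H$'s samples
containing it. "Mean abundance" is taken as the mean of per-sample
proportions (default) because it weights replicates equally regardless of
depth; a pooled-counts alternative is selectable. Specialists require both
scores ≥ 0.7, inclusive at the boundary. Since specificities sum to one, a
threshold above 0.5 makes specialist habitats unique per ASV. Both scores
are scale-invariant per sample, so raw counts and relative abundances give
identical classifications.

## Co-occurrence networks

Edges connect ASV pairs with |Spearman r| ≥ 0.6 and Benjamini–Hochberg
adjusted two-sided p ≤ 0.05 after a ≥ 50 %-prevalence filter — common
practice values, all configurable, since correlation networks have no
canonical thresholds. Spearman p-values use the t approximation on ranks;
constant profiles are masked as undefined rather than given r = 0. Isolated
nodes are dropped so the node count means "connected ASVs". Community
detection runs both deterministic greedy agglomeration and Louvain on
|r|-weighted edges and keeps the higher-modularity partition; on small
graphs this tracks the exhaustive-search optimum closely (within 0.05 in
the test suite's enumeration oracle). Module ids are assigned by decreasing
size, because modularity optimisers do not produce stable labels. Module
abundance is the summed relative abundance of member ASVs, averaged per
plot, and correlated (Spearman) against cumulative emissions; a module
spanning the whole community has constant abundance 1 and is flagged
undefined.

## Mantel tests

The Mantel statistic correlates the upper triangles of two sample-matched
distance matrices; significance comes from jointly permuting the rows and
columns of one matrix, $p = (1 + \#\{r_\pi \ge r\})/(1 + n_{perm})$,
one-sided for positive association by default with 999 permutations. A
joint label permutation rearranges the same multiset of distances, so for
the Spearman variant the matrices are rank-transformed once and every
permuted statistic is a plain Pearson correlation of ranks — this keeps
999-permutation runs fast and exactly equivalent to re-ranking each time.
The smallest attainable p is $1/(n_{perm}+1)$, and under the null the
p-value is uniform on its discrete support, so the test is exactly
calibrated. Soil-property distances are Euclidean on z-scored variables;
zero-variance variables are dropped with a warning, and missing values are
handled pairwise with rescaling to the number of shared variables.

## Synthetic data: what it does and does not emulate

The generators exist to give every stage inputs with known truth:

- `gen_chamber_series()` inverts the flux equation to a ppmv slope and adds
  Gaussian vial noise — so slope fitting plus flux computation must
  round-trip exactly at zero noise and unbiasedly under noise.
- `gen_neutral_community()` draws metacommunity abundances from a
  long-tailed stick-breaking distribution (mean breaking proportion 0.01,
  giving realistically many rare taxa per 1,000-taxon pool), then
  per-sample beta weights and multinomial reads. Only the neutral sampling
  layer matters for recovery experiments; the metacommunity shape is not a
  claim about real paddy soils.
- `gen_habitat_community()` plants specialists that concentrate a chosen
  fraction of their abundance in one habitat and are guaranteed present in
  all of its replicates, over a Poisson-uniform background — at
  concentration 1.0 every planted taxon must be called and nothing else; at
  0.5 the specificity threshold must exclude them.
- `gen_field_season()` fixes the study design at 7 treatments
  (100/80/60/0 % conventional N, with Fe-amended companions at 80/60/0 %) ×
  4 replicates, a lognormal-shaped emission pulse peaking near day 30
  (the tillering flood), N-rate scaling from 0.7 to 1.0 of the peak,
  multiplicative Fe effect, ~15 % plot-level lognormal variability and
  0.05 ppm vial noise. Ten sampling dates span a 100-day season.
- `gen_qpcr_run()` emits the 10²–10⁶ standard gradient and unknowns at a
  planted efficiency.

These emulate the statistical structure of the measurements, not their
mechanisms: no methane biogeochemistry, no primer or sequencing error
model, no compositional coupling between the flux and community layers
beyond what a test plants deliberately. Passing recovery tests therefore
demonstrates the correctness of the estimators under the stated sampling
models, not the realism of any particular field dataset.

## Validation problem sizes

The test suite validates each stage against independent oracles (hand
algebra, brute-force loops, exhaustive partition enumeration, Monte-Carlo
sampling, vegan's Mantel statistic) and runs the recovery experiments at
sizes chosen to finish comfortably on a laptop: 100 random closures and
seasons for the flux oracles; 20 neutral simulations (1,000-taxon pool,
28 samples, 20,000 reads) with 200-replicate bootstraps for immigration-
rate recovery and CI coverage; 20 trials for the shuffled-frequency
discrimination check; 200 null simulations × 999 permutations for Mantel
type-I calibration; and 40 seeded seasons each for the Fe-effect power and
null-calibration experiments. The bootstrap default in analysis use remains
1,000 replicates.

## Known limitations

- Correlation networks on compositions can show spurious negative
  correlations; SparCC-style compositional inference is out of scope, so
  thresholds should be read as descriptive, not inferential.
- The neutral fit treats ASVs as independent observations; the bootstrap
  quantifies sampling variability of the fit, not phylogenetic or
  ecological non-independence.
- Day-resolution trapezoid integration ignores sub-daily sampling times and
  does not model diel flux cycles.
- The two-way ANOVA requires crossed N × Fe cells; unbalanced field losses
  beyond a missing companion treatment are not specially handled.
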