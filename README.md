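# ricemethane

Rice paddies are a major anthropogenic source of atmospheric methane. Field
trials that pair fertiliser management with soil amendments (for example
zero-valent iron, which supplies Fe³⁺/Fe²⁺ redox couples that compete with
methanogenesis for electrons) quantify their effect through a standard chain
of measurements: closed-chamber CH₄ fluxes through the season, qPCR
abundances of the methanogen (*mcrA*) and methanotroph (*pmoA*) marker
genes, and amplicon (ASV) profiles of both communities. `ricemethane`
implements that quantitative chain end to end as a tidyverse-style R
package, with seeded synthetic-data generators so every stage can be
validated against planted ground truth.

## What it computes

**Chamber fluxes and seasonal emissions.** Each chamber closure yields
headspace CH₄ mixing ratios at 0/15/30 min; the flux is

&nbsp;&nbsp;&nbsp;&nbsp;*F* = ρ · *H* · (Δc/Δt) · 273 / (273 + *T*)  (mg CH₄ m⁻² h⁻¹)

with ρ = 0.717 mg cm⁻³ the CH₄ density at 0 °C, *H* the chamber height above
the water layer (m), Δc/Δt the OLS concentration slope (ppmv h⁻¹) and *T*
the mean in-chamber temperature (°C). Seasonal cumulative emission is the
trapezoid integral over sampling dates,
*S* = Σ (*F*ᵢ + *F*ᵢ₊₁)/2 · (*t*ᵢ₊₁ − *t*ᵢ) · 24 (mg m⁻²). Treatment
contrasts use one- and two-way ANOVA (N rate × Fe) with Tukey HSD.

**qPCR quantification.** Standard curves are OLS fits of Cq on
log₁₀(copies) over a 10²–10⁶ plasmid gradient; amplification efficiency is
*E* = 10^(−1/slope) − 1 with a >90 % acceptance flag; absolute copies per g
dry soil invert the curve, and the *mcrA*/*pmoA* ratio (a
production-vs-oxidation potential proxy) is aggregated as the mean of
per-sample ratios.

**Community stages.** Relative abundance, taxonomy aggregation, α-diversity
(richness, Shannon, Simpson), Bray–Curtis distances, and core-ASV Venn
counts across treatments; Sloan's neutral community model fitted to
occurrence frequency vs mean relative abundance (estimating *Nm*, the
immigration rate *m* = *Nm*/*N*, and *R*², with ASV-bootstrap confidence
intervals); SPEC-OCCU specialist calling (specificity and occupancy both
≥ 0.7); thresholded Spearman co-occurrence networks with node/edge/degree/
modularity summaries and module-abundance-vs-emission correlations; and
Mantel permutation tests linking soil-property distances to community
distances.

## Worked example

Simulate a 7-treatment × 4-replicate season with a planted 50 % Fe
suppression of flux, then run the flux chain:

```r
library(ricemethane)
library(dplyr)

field  <- gen_field_season(fe_effect = -0.5, seed = 2023)
fluxes <- chamber_fluxes(field)
season <- cumulative_emission(fluxes)

season |> group_by(treatment) |> summarise(mean_S = mean(cumulative_S))
#>   treatment mean_S
#> 1 0N+Fe      4975.
#> 2 60N+Fe     7411.
#> 3 80N+Fe     8397.
#> 4 0N        12012.
#> 5 60N       13814.
#> 6 100N      14579.
#> 7 80N       15795.

info <- distinct(field, plot_id, n_rate, fe)
an <- compare_treatments(left_join(season, info, by = "plot_id"),
                         "cumulative_S", n_rate = "n_rate", fe = "fe")
glance(an)
#>   term         df f_statistic  p_value analysis
#> 1 treatment     6      39.5   2.25e-10 one-way
#> 2 N_rate        2      18.0   5.11e- 5 two-way
#> 3 Fe            1     198.    3.66e-11 two-way
#> 4 N_rate:Fe     2       0.348 7.11e- 1 two-way
```

The Fe main effect dominates cumulative emissions (F = 198, p ≈ 4 × 10⁻¹¹)
while the N rate × Fe interaction is flat — exactly the planted structure:
every Fe-amended treatment emits about half of its non-amended counterpart.

Fitting the neutral model to a community simulated at immigration rate
m = 0.1:

```r
tab <- gen_neutral_community(m = 0.1, seed = 11)
fit <- ncm_bootstrap(ncm_fit(tab), reps = 200, seed = 12)
fit
#> Sloan neutral community model fit
#>   N = 20000.0 reads/sample, d = 5e-05
#>   Nm = 2020.4, m = 0.101, R2 = 0.975
#>   95% bootstrap CI (m): 0.09508 - 0.1085 (200 reps)
#>   partition: above 161, below 22, neutral 550
autoplot(fit)   # occurrence-frequency scatter with the fitted curve
```

The planted immigration rate (0.1) is recovered to about 1 % and sits inside
the bootstrap interval.

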