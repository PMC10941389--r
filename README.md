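# resilink

Linking feed-intake resilience to the gut microbiota in group-housed
pigs.

Electronic feeders record every visit a pig makes; the day-to-day
variability of its daily feed consumption (FCD, kg/day), once growth is
removed, is a practical inverse proxy of resilience — animals that
struggle to maintain a stable physiological state eat erratically.
resilink turns visit-level feeder records into four per-animal
resilience indicators and quantifies their association with 16S gut
microbial composition. It is aimed at quantitative geneticists and
microbiome researchers working with livestock phenomics data.

## What it computes

For each animal, daily FCD is smoothed with a centred 5-day moving
median and detrended by OLS on age; the residuals e_t yield

* **Lag1** — lag-1 autocorrelation r₁ = Σ(e_t−ē)(e_{t+1}−ē)/Σ(e_t−ē)²,
* **LnVar** — ln of the residual variance,
* **MaxArea** — ln of the largest trapezoidal integral of −e over a run
  of >2 consecutive negative days,
* **SumMin** — the sum of residuals at strict interior local minima,

plus within-breed L/M/H classes (≥95th, 47.5–52.5, ≤5th percentile).

On the microbiome side: depth (≥700) and prevalence (≥5%) filters,
centred log-ratio transform with "const" zero imputation, Aitchison
distances, Shannon / inverse-Simpson α-diversity, and the microbial
similarity kernel K = XXᵀ/p on standardised CLR values. Associations
are quantified by distance-based PERMANOVA with room and breed
covariates (via vegan), α-diversity regressions, Kolmogorov–Smirnov
class comparisons, a Bayesian kernel variance-component model for
microbiability m² = σ²_M/(σ²_M+σ²_E+σ²_S+σ²_e) with HPD intervals and
Geweke diagnostics, and PLS-DA with VIP-driven recursive feature
elimination for classifying resilience classes from composition. A
synthetic cohort generator with known ground truth (growth curves,
intake-depression events, variance components, informative ASVs) makes
every stage testable without animal data; `run_pipeline()` chains all
stages from one config with a reproducibility manifest.

See `vignettes/resilink-methods.Rmd` for the models, assumptions and
design choices.

## Worked example

```r
library(resilink)

cfg  <- sim_config(n_animals = 240, n_asv = 300, n_informative = 30)
meta <- simulate_cohort(cfg, seed = 1)
feed <- simulate_feed_intake(cfg, meta, seed = 2)

daily <- clean_visits(feed$visits) |>
  aggregate_visits_to_daily() |>
  restrict_period(99, 140) |>
  filter_animals(min_days = 10, max_gap = 3)

ind <- resilience_indicators(daily, window = 5)
head(ind, 3)
#>   animal_id breed pen_id room_id sire_id n_obs  lag1 lnvar maxarea summin
#> 1 an0001    DR    pen01  room1   DR_s03     40 0.778 -4.23  -0.186 -0.654
#> 2 an0002    DR    pen02  room1   DR_s17     40 0.788 -5.17  -0.131 -0.404
#> 3 an0003    DR    pen03  room1   DR_s18     42 0.629 -1.62   1.11  -0.958
```

Each row is one animal: `lnvar` near −5 means day-to-day residual SD of
about 0.08 kg/day (a steady eater), −1.6 about 0.45 kg/day (an erratic
one); `maxarea` is the log-integrated depth of its worst multi-day
intake dip.

```r
micro <- simulate_microbiome(cfg, meta, seed = 3,
                             indicator_values = ind$lnvar)
clr <- micro$counts |>
  filter_samples_by_depth(700) |>
  filter_asvs_by_prevalence(0.05) |>
  clr_transform()

pm_meta <- ind[match(rownames(clr), ind$animal_id), ]
permanova(aitchison_distance(clr), pm_meta,
          terms = c("room_id", "breed", "lnvar"), n_perm = 999, seed = 4)
#>   term        df  sum_sq pseudo_f p_value var_exp
#> 1 room_id      7   6157.    0.961   0.621   2.97
#> 2 breed        2   1500.    0.820   0.853   0.723
#> 3 lnvar        1   1194.    1.30    0.147   0.576
#> 4 Residual   217 198513.   NA      NA      95.7
#> 5 Total      227 207363.   NA      NA     100
```

The indicator enters last, so its 0.58% VarExp is conditional on room
and breed — the same order of magnitude seen in real herds, where
composition shifts along resilience are real but small against
between-animal variation.

```r
fit <- fit_microbiability(pm_meta, "lnvar", build_kernel(clr),
                          pen = "pen_id", sire = "sire_id",
                          iters = 6000, burnin = 1000, thin = 10, seed = 5)
summarize_m2(fit)
#> m2: median 0.030, HPD95 [0.004, 0.103] (500 draws)
#>   component  fraction_median
#> 1 microbiome          0.0302
#> 2 pen                 0.0139
#> 3 sire                0.0161
#> 4 residual            0.928
```

At this cohort size a planted microbial share of 0.10 yields a
posterior median of 0.03 with an HPD reaching 0.10 — small shares are
genuinely hard to pin down at n ≈ 240, and the interval, not the
median, is the honest summary.

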