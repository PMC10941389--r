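---
title: "Methods: feed-intake resilience indicators and their microbiota associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feed-intake resilience indicators and their microbiota associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

resilink quantifies the link between a pig's day-to-day feed-intake
variability — read as an inverse proxy of resilience — and its gut
microbial composition. This vignette documents the models and procedures
the package implements, the choices made where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate.

## From feeder visits to resilience indicators

Electronic feeders record one row per visit. `clean_visits()` applies
plausibility rules (non-negative intake, a per-visit maximum of 5 kg, a
per-animal-day maximum of 10 kg/day); all three thresholds are
arguments, because visit-level cleaning rules are inherently
site-specific. A day whose summed intake is implausible is dropped
whole, so it reappears downstream as a missing day rather than as an
absurd total. `aggregate_visits_to_daily()` then sums visits within each
integer age-day into daily feed consumption (FCD, kg/day); a day with no
visit is an explicit missing value, never a zero. The analysis window is
ages 99–140 days inclusive (`restrict_period()`), and
`filter_animals()` removes animals with fewer than 10 observed days or
any run of more than 3 consecutive missing days. We read both filters
literally: "fewer than 10" keeps an animal with exactly 10, and a 3-day
gap is tolerated while a 4-day gap is not. An animal's series spans its
first to last observed day inside the window; days before the first or
after the last observation are treated as not-yet-enrolled rather than
missing, so they do not count toward the gap rule. Missing days inside
the span stay as gaps — nothing is imputed anywhere in the pipeline.

Each series is smoothed with a centred 5-day moving median
(`moving_median()`), which suppresses single-day white noise while
preserving multi-day excursions. Windows are truncated at the series
edges and skip missing days; a position whose window holds fewer than 3
observed values is left undefined. The smoothed series is detrended by
per-animal ordinary least squares on age (`fit_linear_trend()`), since
growing pigs increase consumption roughly linearly over this window;
residuals are smoothed minus predicted. Four scalar indicators summarise
the residuals:

* **Lag1** — the sample lag-1 autocorrelation. The mean and the
  denominator use all observed residuals; numerator pairs that straddle
  a missing day are dropped rather than imputed.
* **LnVar** — the natural log of the sample residual variance (n−1
  denominator). The log stabilises the right-skewed sampling
  distribution of a variance.
* **MaxArea** — maximal runs of strictly negative residuals lasting
  more than two consecutive days are integrated by the trapezoidal rule
  at unit day spacing (so a constant depression of c kg/day over L days
  has area c·(L−1) kg·day); MaxArea is the log of the largest such
  area. Animals with no qualifying run get a missing value and are
  excluded from MaxArea analyses; a log of zero area is undefined and
  we prefer an explicit missing value over an arbitrary floor.
* **SumMin** — the sum of residual values at interior local minima,
  where a local minimum is strictly lower than both neighbours.
  Plateaus are not minima; endpoints and positions adjacent to a
  missing day are ineligible. We scan the residuals rather than the
  smoothed curve: the indicator is meant to capture deviation depth,
  not the growth trend it sits on.

Two invariances matter for interpretation. Adding a constant to all of
an animal's intakes changes no indicator (the intercept absorbs it
exactly — the test suite asserts this to 1e−9). Adding a linear-in-age
term is absorbed by the trend fit *almost* exactly: a moving median is
not perfectly trend-equivariant, because a superimposed trend can switch
which window element is the median, so indicators move slightly. The
tests bound this drift rather than pretending it is zero.

Lag1 uses the standard sample autocorrelation estimator; a
regression-based estimator would differ only at O(1/n) and the choice is
not material at 42-day series length.

## Resilience classes

`assign_classes()` bins each indicator within breed by equal-frequency
percentile ranks: at or below the 5th percentile → class H (low
variability, high resilience), at or above the 95th → class L, inside
the 47.5–52.5 band → class M (the control group), everything else
unassigned. Ties are resolved by first occurrence, making labels
deterministic. Binning within breed balances the class design across
breeds. The implementation uses an explicit rank-to-bin formula
(`floor(bins·(rank−1)/n)+1`) rather than a library n-tile helper, which
leaves upper bins empty when a breed has fewer animals than bins; at
large n the two agree. Class sizes per breed are ⌈0.05·n⌉ within ±1.

SumMin's sign convention is inverted relative to the other indicators
(deep minima are *negative*, so the ≥95th percentile holds the
*shallowest* minima). The same percentile rule is applied to all four
indicators anyway, reproducing the upstream behaviour; an
`invert` reading can be obtained by negating the column before calling
`assign_classes()`. This directionality caveat should be kept in mind
when interpreting SumMin classes.

## Compositional microbiome operations

ASV count tables are samples × ASVs. Samples with a total count strictly
below 700 are removed, then ASVs present in strictly fewer than 5% of
the retained samples; both boundaries are read strictly, so a sample at
exactly 700 and an ASV at exactly 5% prevalence stay. α-diversity
(Shannon entropy in nats, inverse Simpson) is computed on the
*unfiltered* table, since richness estimates should not depend on
analysis-convenience filters; Tukey-fence outliers (beyond 1.5 IQR, a
single pass, strict "beyond") are removed before diversity regressions.

`clr_transform()` replaces zeros by a constant pseudo-value — by default
0.65 times the smallest non-zero count of the table, a common "const"
replacement convention; the multiplier is an argument because the
convention, not the exact constant, is what upstream work specifies —
and maps each row x to ln x − mean(ln x). CLR rows sum to zero by
construction and are invariant to sequencing depth on zero-free rows, so
Euclidean distance between CLR rows (the Aitchison distance) compares
compositions, not library sizes.

`build_kernel()` column-standardises the CLR matrix (zero-variance
columns are dropped with a warning) and forms K = XXᵀ/p. Dividing by the
number of ASVs p puts the mean diagonal near 1, the same scaling used
for genomic relationship matrices, which makes the kernel variance
component directly comparable to the other variance components.

## Association analyses

`permanova()` performs distance-based PERMANOVA with sequential (Type-I)
partitioning, delegating to `vegan::adonis2(by = "terms")` — the same
engine the upstream analyses used. The default term order is room,
breed, indicator, so the indicator's sum of squares is conditional on
housing and breed; VarExp is 100·SS/SS_total. Permutations are free
(unrestricted) over samples; `exact = TRUE` enumerates all orderings for
very small n, and the test suite checks the permutation p against an
independent brute-force enumeration built from Gower centring and
hat-matrix traces.

`diversity_regression()` fits OLS with diversity as the outcome and one
indicator as the predictor, optionally adding room and breed. The
sources disagree internally about which variable is the outcome; the
simple two-variable model's slope *test* is direction-symmetric (it
equals the correlation test), so the conclusion does not depend on the
choice, and we follow the methods-section reading. `ks_class_test()`
compares indicator classes (L vs M, M vs H, L vs H) with two-sample
Kolmogorov–Smirnov tests.

## Microbiability

`fit_microbiability()` estimates how much indicator variance the
microbial kernel captures, with the mixed model

y = 1μ + Z_E u_E + Z_S u_S + m + e,

u_E the pen effects (environment), u_S sire-within-breed effects
(genetics; sire codes are composed as breed:sire so breed means are
absorbed into sire levels), m ~ N(0, Kσ²_M) the microbial effect, e the
residual. The components are modelled as mutually independent — an
approximation forced by the design, in which full- and half-sibs are
spread across pens — and no sire×pen interaction is fitted.
Microbiability is m² = σ²_M/(σ²_M+σ²_E+σ²_S+σ²_e) per posterior draw,
summarised by the posterior median and the shortest 95% HPD interval.

The sampler works in the eigenbasis of K (m = Uα with prior
α ~ N(0, Λσ²_M)): because U is orthonormal, every full conditional of α
is diagonal and one sweep costs two n×n matrix-vector products. Two
numerical choices deserve comment:

* **Collapsed variance updates.** With hundreds of near-null
  eigendirections, the textbook conditional draw of σ²_M given α mixes
  pathologically slowly (each weak direction contributes ≈σ²_M to the
  sufficient statistic, making the update self-confirming). The sampler
  instead updates (σ²_M, σ²_e) by random-walk Metropolis on their
  *marginal* posterior with α integrated out — the marginal likelihood
  of the rotated data is a product of n univariate normals with
  variances λᵢσ²_M + σ²_e, an O(n) evaluation — and then draws α from
  its exact conditional. This partially collapsed blocked update is a
  valid Gibbs variant and mixes orders of magnitude faster.
* **Weakly informative priors.** All variances carry scaled-inverse-χ²
  priors with df = 2 and prior mode 0.01·var(y). A heavier prior whose
  mode splits var(y) equally across components behaves like
  exp(−c/σ²) near zero and *forbids* a variance from concentrating at
  zero, which would make the no-signal case unestimable; the light
  prior lets a null component collapse while barely influencing a real
  one. The flip side is conservatism: posterior medians of genuinely
  small shares (≲0.1) are shrunk somewhat toward zero. Doubling the
  prior df moves the posterior median m² by well under 0.03 on the
  standard synthetic fixture.

Convergence is monitored with Geweke's Z (`geweke_z()`), comparing the
first 10% and last 50% of each variance chain with
spectral-density-at-zero variance estimates from an AR fit (batch means
as a fallback for short chains). The default run profile is 70,000
iterations, 10,000 burn-in, thinning 50; a reduced profile (6,000 /
1,000 / 10) is adequate for the package's simulation checks at n ≤ 500
and is what the tests use.

## PLS-DA classification

`stratified_split()` allocates 50% of samples to training within every
breed × class cell (odd units by a seeded coin flip). `fit_plsda()`
one-hot encodes the classes and fits PLS2 on column-centred-and-scaled
features: each component's weight vector is the leading singular vector
of the current XᵀY cross-product (the NIPALS fixed point, computed
directly), with X and Y deflated by the component scores; class scores
for new data come from the indicator regression coefficients and the
predicted label is the argmax. `select_components()` picks the number
of components by repeated stratified 4-fold cross-validation (50
repeats by default), maximising the mean held-out macro AUC with ties
toward fewer components.

`vip_scores()` implements variable importance in projection,
VIPⱼ = √(p·Σₐ SSYₐ wⱼₐ²/Σₐ SSYₐ), normalised so ΣVIP² = p.
`recursive_vip_elimination()` repeatedly drops the ⌊0.2·p⌋ (at least 1)
lowest-VIP features — a quantile-of-features reading of "the lowest 20%
of the variable importance"; a cumulative-share reading is possible but
removes erratically many features per step — refits, and records the
cross-validated AUC; it stops at the first failure to improve (or below
5 features) and returns the best recorded iteration. The component
count is fixed after the initial selection and reused during
elimination; re-selecting per iteration is possible but multiplies cost
for little observed benefit.

`evaluate_plsda()` reports one-vs-rest AUC per class computed by the
rank-sum (Mann–Whitney) identity with half credit for ties, the overall
AUC as the unweighted macro mean across classes, ROC coordinates, the
3×3 confusion matrix, and a one-sided Wilcoxon p-value per class
(scores of class members greater than non-members) — the standard test
of ROC area. In a 3-class setting, one-vs-rest AUCs of the *other*
classes are inflated whenever one class is strongly separable (it
contaminates the "rest"); the H-vs-M contrast should therefore be read
from the pairwise AUC, which the acceptance checks do.

## The synthetic cohort generator

`sim_config()` defaults describe the study conditions the package
targets: 528 animals of three breeds (153/193/182), eight rooms of
eight breed-homogeneous pens (~11 animals per pen), 28 sires per breed
nested in breed with paternal half-sibs interleaved across pens, and
ages 99–140 days. Daily intake is a per-animal linear trend (2.0 ±
0.3 kg/day at age 99, slope 0.02 ± 0.005 kg/day per day — a growing pig
roughly adds 0.8 kg/day of consumption over the window) plus a pen
effect (SD 0.1 kg/day), AR(1) daily noise (marginal SD 0.15 kg/day,
φ = 0.3, so Lag1 has recoverable signal), and, for 30% of animals, one
depression event of 3–7 days and ~1.0 kg/day depth — the signature that
MaxArea is designed to integrate. Days are split into 1–8 visits that
sum exactly to the daily value; 2% of days go missing at random.

The microbiome side generates a latent log-composition with genuine
community structure: a rank-25 factor model (loading SD 0.35,
idiosyncratic SD 0.4, ASV baseline SD 1.0). The factor structure is not
cosmetic — independent ASVs would give the kernel a Marchenko–Pastur
spectrum nearly indistinguishable from the residual identity, and no
variance-component method could then separate σ²_M from σ²_e at
realistic n. Counts are multinomial draws at log-normal depths (median
50,000 reads, as in deeper modern 16S runs; a configurable fraction of
samples is planted below 700 reads to exercise the depth filter).

Three signal modes serve different tests. In the default mode a latent
indicator is built as microbial + pen + sire + residual components, each
rescaled so its realised variance share matches the configured targets
(m² = 0.10, pen 0.25, sire 0.06 by default, echoing the magnitudes the
method reports on real data) exactly; the microbial component is a
linear combination of the latent CLR values of the informative ASVs, so
the analysis-side kernel is correctly specified under the generator. In
`indicator_values` mode an externally computed indicator (e.g. the
pipeline's own LnVar) is mixed into the first community factor with a
calibrated variance share, which keeps the recoverable microbiability
near the configured target rather than saturating. In `class_labels`
mode, named classes receive a latent shift in the informative ASVs,
planting the asymmetric situation in which only low-resilience animals
carry a compositional signature.

What the generator does *not* emulate: taxonomic correlation beyond the
factor structure, overdispersion beyond multinomial sampling,
zero-inflation mechanisms, time-varying composition, true pedigree
relationships (sires are iid effects), or any feedback from composition
to intake. Passing the simulation checks therefore demonstrates that
the estimators recover what they claim under a compositionally
realistic but idealised data-generating process — not that the
biological effect sizes of any particular herd will be reproduced.

## Problem sizes and tolerances used by the checks

The test suite runs reduced but representative scales, chosen as the
smallest sizes at which each property is statistically crisp: indicator
oracles on 1,000 random series of up to 50 days; PERMANOVA calibration
with 500 null data sets of 30 samples at 199 permutations (exact
enumeration at n = 6); microbiability recovery at n = 500 animals / 600
ASVs with the reduced MCMC profile, 20 replicates for HPD coverage;
PLS-DA on 360 animals / 300 ASVs; and a 192-animal end-to-end pipeline
run executed twice to verify byte-identical outputs. Exact identities
(CLR centring, VIP normalisation, AUC/U-statistic equality, SS
additivity) are asserted at 1e−8 to 1e−12; stochastic recoveries use
the bands stated alongside each check.

## Known limitations

* The Casey-style visit cleaning is a configurable placeholder; real
  deployments should calibrate the thresholds to their feeder hardware.
* m² posterior medians are conservative for small true shares under the
  weak prior; the HPD interval is the more faithful summary there.
* PERMANOVA permutations are unrestricted; no strata/repeated-measures
  designs are supported.
* The PLS-DA significance tests are per-class and unadjusted for the
  three-class multiplicity.
* MaxArea is undefined (missing) for animals without a ≥3-day negative
  run, which couples its missingness to resilience itself; analyses of
  MaxArea are implicitly conditional on having at least one such run.
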