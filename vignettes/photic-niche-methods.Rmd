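---
title: "Methods: modelling the photic niche of depth-segregated corals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the photic niche of depth-segregated corals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoniche)
```

# The scientific problem

Reef-building corals host photosynthetic dinoflagellates, so light is the
primary axis of their vertical zonation. Sibling coral species often
segregate by depth, and a central question is whether that segregation
reflects genuine physiological divergence — different photoacclimation
capacity of each species' symbionts — or mere habitat preference. The
classic way to test this is a reciprocal transplant between shallow and
deep sites combined with chlorophyll-fluorescence measurements of
photosystem II (PSII) performance. `photoniche` implements the full
quantitative chain of such a study: water-column optics, PSII excitation
pressure, per-species depth-response regressions with an extrapolated depth
limit, and survivorship/selection statistics, plus a synthetic-data
generator so the whole chain is testable end to end.

# Water-column optics

Downwelling irradiance decays exponentially with depth,

$$E(z) = E_0\, e^{-K_d z},$$

where $K_d$ (m$^{-1}$) is the diffuse attenuation coefficient and $z$ is
depth in metres, positive downward with the surface at $z = 0$ (a
convention enforced by all validators). `fit_kd()` estimates $K_d$ by
ordinary least squares of $\log E$ on $z$ — the log transform linearises
the model exactly and corresponds to a multiplicative (log-normal) sensor
error, the standard assumption in optical oceanography. We deliberately do
not use nonlinear least squares: on the natural scale the brightest
(shallowest) readings would dominate the fit. $R^2$ is reported from the
log-linear regression.

Two small derived tools matter in practice. `depth_for_irradiance()`
inverts the law to express habitat ranges as irradiance bands, and
`equivalent_depth_increase()` translates a depth response across waters of
different clarity using conservation of optical thickness,
$K_d^{(1)} \Delta z_1 = K_d^{(2)} \Delta z_2$: the light reduction over 6 m
of turbid water ($K_d = 0.40$) requires roughly 40 m in very clear water
($K_d = 0.06$). This is the quantity restoration planners need when
matching donor and outplant light environments.

Logger series are summarised by `summarize_loggers()`. Sub-daily readings
are first aggregated to calendar-day means (in the logger's local
timestamps; days without readings simply drop out), because the diel cycle
would otherwise dominate both the temperature comparison and the light
variability. The shallow-vs-deep temperature contrast is a pooled-variance
Student *t* on daily means by default (Welch available via
`var.equal = FALSE`), and light variability is the coefficient of variation
of daily mean relative light, reported as the shallow/deep CV ratio.

# Excitation pressure over PSII

PAM fluorometry yields two quantum-yield measurements per colony: the
effective yield at noon, $\Delta F/F_m'$, and the maximum yield at dusk on
dark-acclimated tissue, $F_v/F_m$. Their ratio defines the maximum
excitation pressure over PSII,

$$Q_m = 1 - \frac{\Delta F/F_m'}{F_v/F_m},$$

which approaches 1 under chronic light stress and 0 under light
limitation. `compute_qm()` applies the formula without clamping: negative
values arise from measurement noise when noon and dusk yields are nearly
equal, and retaining them keeps treatment means unbiased (reported
treatment means near zero with s.d. ~0.08 are only possible if individual
negatives exist). $Q_m$ is scale-invariant in the two yields, which is why
a constant relative underestimation of the noon yield (e.g. brief dark
acclimatisation during transport) biases $Q_m$ by a near-constant additive
amount rather than distorting the depth trend.

Dusk measurements are expensive, so surveys measure $F_v/F_m$ on a
calibration subsample only. `calibrate_fvfm_depth()` regresses $F_v/F_m$
on depth (it increases with depth as symbionts photoacclimate), and
`predict_fvfm()` evaluates the line for the remaining colonies, truncating
predictions into $(0, 1]$ — the physical range of a quantum yield — with a
warning. Because $(0,1]$ has no minimum, the lower truncation uses a floor
of 0.001; in practice only the upper truncation ever triggers for sensible
calibrations. Predictions outside the calibration depth range warn about
extrapolation rather than failing. `estimate_survey_qm()` then uses the
measured $F_v/F_m$ where available and the prediction otherwise, recording
the route in a `source` column so a measured-only sensitivity analysis is
a one-line filter.

# Niche limits

Across a species' depth range, $Q_m$ declines roughly linearly with depth.
`fit_qm_depth()` fits the per-species OLS line; `depth_limit()`
extrapolates it to $Q_m = 0$,

$$z^* = -\,b/m \qquad (m < 0),$$

interpreted as the depth at which the symbiosis can no longer be powered by
light — the theoretical lower boundary of the species' photic niche. A
positive or zero slope has no finite limit and is an error.

The x-intercept of a regression has no exact finite-sample distribution
(it is a ratio of correlated estimates), so uncertainty comes from a
case-resampling bootstrap of the underlying records with percentile
intervals, 2000 replicates by default and a mandatory seed. Bootstrap
replicates whose resampled slope is non-negative have no finite limit;
they are discarded and counted, with a warning when more than 10% are lost
(a sign the slope is too weak to support extrapolation at all). Summaries
print $z^*$ to 0.1 m; full precision is retained in the objects and JSON.
Negative fitted $Q_m$ beyond $z^*$ is reported as-is — it means light
limitation, not an error.

`ancova_interaction()` asks whether two species' slopes differ: it
compares the full model `qm ~ depth * species` with the additive model by
the extra-sum-of-squares *F* test (numerator df 1, denominator df
$N - 4$). The ANCOVA pools measured- and predicted-$F_v/F_m$ records by
default, mirroring how such surveys are analysed. `slope_ratio()` reports
how much more pronounced one species' decline is ($|m_a|/|m_b|$).

# Transplant fitness

Survivorship is a single census (alive/dead six months after
transplantation), so the analysis is exact contingency statistics rather
than survival curves. Colonies that detached or were otherwise discarded
are excluded before tallying — never counted as dead.
`fisher_one_tailed()` computes the exact one-tailed Fisher *p*: the
hypergeometric probability, conditioning on table margins, of at least as
many deaths in the first-listed group as observed. The direction is fixed
as "mortality in the first-listed (non-native) group exceeds the second",
matching the transplant-disadvantage hypothesis; callers therefore order
groups explicitly, and no silent tail-flipping occurs. Terms are
accumulated from log-factorials and normalised over the full support,
which is overflow-safe and makes the tail sum exactly 1 when it spans the
support. An independent full-enumeration oracle (binomial coefficients,
test-only) and `stats::fisher.test` cross-check the implementation in the
suite.

The standardized selection differential between two species in a habitat is

$$s = \frac{w_1 - w_2}{(w_1 + w_2)/2},$$

with $w$ the survival proportions: a dimensionless fitness advantage,
antisymmetric under swapping the species and bounded by $|s| \le 2$.
`survivorship_report()` assembles per-treatment mortalities (displayed as
whole percents; raw proportions kept in the objects and JSON), the four
natural pairwise Fisher contrasts of a shallow/deep reciprocal design
(S-D vs S-S, S-D vs D-D, D-S vs D-D, D-S vs S-S), and the per-habitat
selection differentials (deep: D-D vs S-D; shallow: S-S vs D-S).

# The synthetic-data generator

`sim_config()` fixes the study conditions the generators emulate: a turbid
reef with $K_d = 0.40$ m$^{-1}$ profiled at 21 depths over 0–10 m with
log-normal sensor noise (sd 0.05); 176 days of 30-min logger readings with
daily temperatures N(28.85, 0.96) shallow vs N(28.46, 0.88) deep and a
5:1 shallow:deep day-to-day light CV ratio (0.50 vs 0.10, with mean
relative light levels of 420 and 38 chosen as realistic for ~3.5 m vs
~9.5 m under that $K_d$); surveys of 38 and 67 colonies uniform over
2.5–6 m and 3–8 m with $Q_m$ lines $0.735 - 0.133z$ and $0.422 - 0.054z$;
and transplant groups of 27/29/44/28 with death probabilities
0/0.27/0.02/0.04. The $Q_m$ residual standard deviations (0.090, 0.078)
are back-computed from the lines' $R^2$ (0.71, 0.50) under uniform depth
sampling, so simulated fits reproduce the observed goodness of fit. The
$F_v/F_m$ calibration lines (0.50 + 0.02 z and 0.48 + 0.02 z, noise sd
0.01) produce dusk yields of ~0.54 at 2–3 m rising to ~0.64 at 7–8 m,
matching the magnitudes such surveys report.

Noise models are the simplest forms consistent with field summaries:
log-normal for irradiance (multiplicative sensor error), truncated Normal
for yields, Bernoulli for survival. One deliberate design choice: the noon
yield is *derived* from the simulated $Q_m$,
$\Delta F/F_m' = F_v/F_m\,(1 - Q_m)$, rather than simulated directly, so
the $Q_m$ formula is exercised as an inverse problem and a zero-noise
configuration reproduces the generating line exactly.

All generators are pure functions of the config: each stage draws from a
sub-seed equal to the config seed plus a fixed per-stage offset, so
enabling or disabling one stage never perturbs another's draws, and
`write_simulated_data()` emits byte-identical CSVs for identical configs.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: within-colony repeated-measures
correlation (records are independent), non-linear or saturating
$Q_m$–depth responses, temporal autocorrelation in logger series beyond
the diel cycle, non-photochemical-quenching relaxation during dark
transport, and any microbial/symbiont community structure.

# Numerical choices and degenerate inputs

* Light profiles require ≥ 3 readings at ≥ 3 distinct depths and strictly
  positive irradiance (the log is otherwise undefined); regressions require
  ≥ 3 distinct depths; ANCOVA requires two species with ≥ 3 records and
  ≥ 2 distinct depths each.
* The hypergeometric tail is computed in log space and normalised over the
  support (numerically exact at the boundaries); the enumeration oracle is
  kept test-only and independent.
* The bootstrap refits each resample by closed-form OLS sums (vectorised),
  not repeated `lm()` calls; with 2000 replicates on n ≈ 40 this runs in
  milliseconds.
* Exactly collinear inputs make residual variance equal to machine noise;
  fits succeed, but F statistics are then "numerically huge" rather than
  meaningfully comparable, and the tests treat them that way.
* Reports round for display only (mortality to whole percent, depth limits
  to 0.1 m, yields to 3 decimals); JSON serialisation keeps full precision.

# Problem sizes used in the test suite

The suite's stochastic checks use replication scales chosen to keep
sampling error well below the asserted tolerances while remaining quick on
a single CPU: 500 replicate experiments for bootstrap-coverage and
unbiasedness checks (binomial s.e. on a 95% coverage estimate ≈ 1%), 200
seeds for CI-recovery rates, 1000 simulated experiments for the mean
temperature-contrast t statistic, and bootstrap sizes of 500 within
coverage loops (2000, the analysis default, elsewhere). The full suite
runs in well under five minutes.

# Known limitations

* The depth limit is a linear extrapolation beyond the deepest occupied
  sites; it is a bioenergetic boundary estimate, not a prediction that
  colonies occur at $z^*$.
* Percentile bootstrap intervals for a ratio estimate can undercover
  slightly at small n with weak slopes; the discard-rate warning flags the
  regime where this matters.
* Calibration-based $F_v/F_m$ prediction shares one fitted line across all
  survey colonies of a species, so its error is correlated across records;
  with calibration noise far smaller than $Q_m$ residual noise this is
  negligible, but a poorly sampled calibration would understate survey
  uncertainty.
* Fitness is survival only, over a single census; growth and reproduction
  are not modelled.
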