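# photoniche

Photic-niche analysis for depth-segregated reef corals.

Symbiotic corals partition reef habitat along the underwater light
gradient. `photoniche` is for ecophysiologists analysing that partitioning
with reciprocal-transplant experiments and PAM chlorophyll fluorometry. It
implements the quantitative chain from raw field measurements to a
species' theoretical photic depth limit and its fitness consequences:

* **Optics** — fit the diffuse attenuation coefficient K<sub>d</sub> from a
  light profile via the log-linear form of E(z) = E₀·e^(−K_d·z); express
  depths as percent surface irradiance; translate depth responses across
  waters of different clarity (conservation of K_d·Δz); summarise
  temperature/light logger series by calendar-day means.
* **Fluorometry** — the maximum excitation pressure over PSII,
  Q_m = 1 − (ΔF/F_m′)/(F_v/F_m), from noon effective and dusk maximum
  quantum yields; depth calibration of F_v/F_m for survey colonies lacking
  dusk measurements.
* **Niche limits** — per-species OLS lines of Q_m vs depth; the x-intercept
  z\* = −b/m where Q_m reaches 0, read as the bioenergetic lower boundary
  of the species' photic niche, with case-resampling bootstrap confidence
  intervals; ANCOVA (extra-sum-of-squares F) for species × depth
  interaction.
* **Fitness** — one-tailed Fisher exact tests on 2×2 dead/alive transplant
  tables (exact hypergeometric tail, log-factorial implementation) and
  standardized selection differentials s = (w₁ − w₂)/mean(w₁, w₂).
* **Synthetic data** — seeded generators for all four input types with
  defaults emulating a turbid-water reciprocal transplant, so the entire
  pipeline is testable without field data.

## Worked example

Simulate a full field campaign and run the pipeline:

```r
library(photoniche)

cfg <- sim_config(seed = 42)
dat <- list(profile  = gen_light_profile(cfg),
            loggers  = gen_logger_series(cfg),
            pam      = rbind(gen_fluorometry_survey(cfg, "annularis"),
                             gen_fluorometry_survey(cfg, "franksi")),
            outcomes = gen_transplant_experiment(cfg))
report <- run_pipeline(dat, bootstrap_reps = 2000, seed = 1)
report
```

```
== Photic-niche analysis report ==

Optics
Optical model: E(z) = E0 * exp(-Kd * z)
  Kd = 0.4032 m^-1, E0 = 102.9, R^2 = 0.998 (n = 21)
  3.5m: 24% of surface irradiance
  9.5m: 2% of surface irradiance

Environment summary (daily aggregates)
  shallow: 28.90 +/- 1.06 C over 176 days
  deep:    28.47 +/- 0.86 C over 176 days
  Student two-sample t: t = 4.11, df = 350.0, p = 5.01e-05
  light variability ratio (shallow CV / deep CV) = 5.41

Niche limits
Qm-depth model (O. annularis): Qm = 0.804 -0.150 * depth  (R^2 = 0.71, n = 38)
Theoretical depth limit (O. annularis): 5.4 m  [95% bootstrap CI 5.1-5.7 m, 2000 replicates]
Qm-depth model (O. franksi): Qm = 0.440 -0.056 * depth  (R^2 = 0.59, n = 67)
Theoretical depth limit (O. franksi): 7.8 m  [95% bootstrap CI 7.3-8.5 m, 2000 replicates]
Species x depth interaction: F(1,101) = 36.19, p = 2.89e-08
  slopes: O. annularis -0.150, O. franksi -0.056 (Qm per m)
  slope magnitude ratio = 2.66

Survivorship after transplantation
  S-S (O. annularis): n = 27, 0% mortality
  S-D (O. annularis): n = 29, 28% mortality
  D-S (O. franksi): n = 44, 0% mortality
  D-D (O. franksi): n = 28, 4% mortality
Contrasts (one-tailed):
  S-D vs S-S: 28% vs 0% mortality (Fisher exact test: p = 0.00302)
  S-D vs D-D: 28% vs 4% mortality (Fisher exact test: p = 0.0145)
  D-S vs D-D: 0% vs 4% mortality (Fisher exact test: p = 1)
  D-S vs S-S: 0% vs 0% mortality (Fisher exact test: p = 1)
Selection in deep habitat: O. franksi favored, survival 0.96 vs 0.72, advantage s = 28%
Selection in shallow habitat: O. annularis favored, survival 1.00 vs 1.00, advantage s = 0%
```

Reading it: the shallow species' excitation pressure collapses about 2.7×
faster with depth than the deep species' (a significant species × depth
interaction), putting its bioenergetic depth limit at ~5.4 m versus
~7.8 m; consistently, transplanting it below that limit produced 28%
mortality (Fisher p = 0.003) and a ~28% standardized survival advantage
for the deep specialist in deep habitat. `report_json(report, "report.json")`
serialises every block at full precision. The same analyses run on CSV
inputs via `read_light_profile()`, `read_logger_series()`,
`read_pam_records()` and `read_transplant_outcomes()` (schemas in the
function docs), and `write_simulated_data(cfg, dir)` emits matching CSVs.

Individual stages are plain functions, e.g.:

```r
compute_qm(0.31, 0.62)                          # 0.5
percent_surface_irradiance(0.40, c(3.5, 9.5))   # 24.66  2.24
equivalent_depth_increase(0.40, 6, 0.06)        # 40 m of clear water
depth_limit(niche_limit_model(0.735, -0.133), bootstrap_reps = 0)  # 5.5 m
```

## Documentation

See the methods vignette (`vignettes/photic-niche-methods.Rmd`) for the
models, assumptions, numerical choices and known limitations, and the
roxygen help pages for per-function contracts.
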