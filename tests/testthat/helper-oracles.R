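# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Closed-form OLS slope/intercept from sums.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# One-tailed Fisher p by full enumeration of all tables with the observed
# margins, using choose() directly: P(deaths in group A >= observed).
fisher_enum_oracle <- function(dead_a, n_a, dead_b, n_b) {
  d <- dead_a + dead_b
  N <- n_a + n_b
  total <- choose(N, d)
  p <- 0
  for (k in 0:d) {
    if (k <= n_a && (d - k) <= n_b && k >= dead_a) {
      p <- p + choose(n_a, k) * choose(n_b, d - k) / total
    }
  }
  p
}

# Extra-sum-of-squares F for the depth x species interaction, from raw RSS
# of both nested models fitted by the closed-form OLS above.
ancova_rss_oracle <- function(depth, qm, species) {
  species <- as.character(species)
  lev <- sort(unique(species))
  stopifnot(length(lev) == 2L)
  rss <- function(res) sum(res^2)
  # full model: separate line per species
  res_full <- unlist(lapply(lev, function(s) {
    i <- species == s
    f <- ols_oracle(depth[i], qm[i])
    qm[i] - (f$intercept + f$slope * depth[i])
  }))
  # reduced model: common slope, species-specific intercepts -> OLS of
  # (qm centred by species mean) on (depth centred by species mean)
  dc <- depth
  qc <- qm
  for (s in lev) {
    i <- species == s
    dc[i] <- depth[i] - mean(depth[i])
    qc[i] <- qm[i] - mean(qm[i])
  }
  slope0 <- sum(dc * qc) / sum(dc^2)
  res_red <- qc - slope0 * dc
  N <- length(qm)
  ((rss(res_red) - rss(res_full)) / 1) / (rss(res_full) / (N - 4))
}

# Convenience: default synthetic inputs for pipeline-level tests.
default_pipeline_data <- function(seed) {
  cfg <- sim_config(seed = seed)
  list(profile = gen_light_profile(cfg),
       loggers = gen_logger_series(cfg),
       pam = rbind(gen_fluorometry_survey(cfg, "annularis"),
                   gen_fluorometry_survey(cfg, "franksi")),
       outcomes = gen_transplant_experiment(cfg))
}
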