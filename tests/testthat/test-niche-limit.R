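test_that("fit_qm_depth recovers an exact line", {
  z <- c(1, 2, 3, 4, 6)
  m <- fit_qm_depth(data.frame(depth_m = z, qm = 0.6 - 0.1 * z))
  expect_equal(m$slope, -0.1, tolerance = 1e-12)
  expect_equal(m$intercept, 0.6, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_qm_depth(data.frame(depth_m = c(2, 2, 2), qm = 1:3)),
               "distinct")
})

test_that("fitted slope covers the generating value on a synthetic survey", {
  set.seed(14)
  z <- runif(38, 2.5, 6)
  qm <- 0.735 - 0.133 * z + rnorm(38, 0, 0.09)
  m <- fit_qm_depth(data.frame(depth_m = z, qm = qm))
  ci <- confint(m$fit)["depth_m", ]
  expect_gt(-0.133, ci[1])
  expect_lt(-0.133, ci[2])
  oracle <- ols_oracle(z, qm)
  expect_equal(m$slope, oracle$slope, tolerance = 1e-12)
  band <- confidence_band(m, c(3, 4, 5))
  expect_true(all(band$lwr < band$fit & band$fit < band$upr))
})

test_that("depth limits from regression coefficients match the field estimates", {
  dl_ann <- depth_limit(niche_limit_model(0.735, -0.133), bootstrap_reps = 0)
  expect_equal(round(dl_ann$z_star, 1), 5.5)
  dl_fra <- depth_limit(niche_limit_model(0.422, -0.054), bootstrap_reps = 0)
  expect_equal(round(dl_fra$z_star, 1), 7.8)
  expect_equal(depth_limit(niche_limit_model(0.6, -0.1), bootstrap_reps = 0)$z_star, 6)
  expect_error(depth_limit(niche_limit_model(0.6, 0.1)), "slope < 0")
})

test_that("the fitted line crosses zero exactly at z_star", {
  set.seed(4)
  for (i in 1:20) {
    b <- runif(1, 0.2, 1)
    m <- -runif(1, 0.02, 0.3)
    z <- depth_limit(niche_limit_model(b, m), bootstrap_reps = 0)$z_star
    expect_lt(abs(b + m * z), 1e-12)
  }
})

test_that("z_star is invariant to measurement order and bootstrap needs a seed", {
  set.seed(9)
  z <- runif(20, 2, 8)
  qm <- 0.7 - 0.1 * z + rnorm(20, 0, 0.05)
  d <- data.frame(depth_m = z, qm = qm)
  m1 <- fit_qm_depth(d)
  m2 <- fit_qm_depth(d[sample(nrow(d)), ])
  e1 <- depth_limit(m1, bootstrap_reps = 200, seed = 1)
  e2 <- depth_limit(m2, bootstrap_reps = 200, seed = 1)
  expect_equal(e1$z_star, e2$z_star, tolerance = 1e-12)
  expect_error(depth_limit(m1, bootstrap_reps = 100), "seed")
  expect_true(e1$ci_low <= e1$z_star && e1$z_star <= e1$ci_high)
})

test_that("bootstrap interval coverage of the true depth limit is near nominal", {
  z_true <- 0.735 / 0.133
  covered <- 0L
  n_exp <- 500L
  set.seed(2024)
  for (i in seq_len(n_exp)) {
    z <- runif(38, 2.5, 6)
    qm <- 0.735 - 0.133 * z + rnorm(38, 0, 0.09)
    m <- fit_qm_depth(data.frame(depth_m = z, qm = qm))
    e <- suppressWarnings(depth_limit(m, bootstrap_reps = 500, seed = i))
    if (e$ci_low <= z_true && z_true <= e$ci_high) covered <- covered + 1L
  }
  expect_gte(covered / n_exp, 0.90)
  expect_lte(covered / n_exp, 0.99)
})

test_that("ANCOVA interaction F equals the brute-force nested-RSS oracle", {
  # one point nudged off each line so residual variance is far above
  # machine epsilon and the F comparison is numerically meaningful
  d <- data.frame(
    species = rep(c("A", "B"), each = 4),
    depth_m = rep(1:4, 2),
    qm = c(0.5, 0.41, 0.3, 0.2, 0.45, 0.42, 0.38, 0.36))
  res <- ancova_interaction(d)
  expect_equal(res$f_statistic,
               ancova_rss_oracle(d$depth_m, d$qm, d$species),
               tolerance = 1e-10)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, nrow(d) - 4L)

  set.seed(55)
  for (i in 1:10) {
    n <- sample(6:30, 2)
    d <- data.frame(
      species = rep(c("ann", "fra"), n),
      depth_m = c(runif(n[1], 2, 6), runif(n[2], 3, 8)),
      qm = rnorm(sum(n), 0.4, 0.15))
    res <- ancova_interaction(d)
    expect_equal(res$f_statistic,
                 ancova_rss_oracle(d$depth_m, d$qm, d$species),
                 tolerance = 1e-9)
  }
})

test_that("ANCOVA is calibrated under the null and decisive under separation", {
  false_pos <- 0L
  n_seeds <- 200L
  set.seed(400)
  for (i in seq_len(n_seeds)) {
    d <- data.frame(
      species = rep(c("A", "B"), each = 20),
      depth_m = runif(40, 2, 8))
    d$qm <- 0.7 - 0.1 * d$depth_m + rnorm(40, 0, 0.08)
    if (ancova_interaction(d)$p_value < 0.05) false_pos <- false_pos + 1L
  }
  expect_lte(false_pos, 0.10 * n_seeds)

  # two exact lines with different slopes: essentially zero residual variance
  d <- data.frame(species = rep(c("A", "B"), each = 5), depth_m = rep(1:5, 2))
  d$qm <- ifelse(d$species == "A", 0.8 - 0.1 * d$depth_m, 0.5 - 0.02 * d$depth_m)
  res <- ancova_interaction(d)
  expect_gt(res$f_statistic, 1e10)
  expect_lt(res$p_value, 1e-10)
})

test_that("slope_ratio compares slope magnitudes symmetrically", {
  a <- niche_limit_model(0.735, -0.133)
  b <- niche_limit_model(0.422, -0.054)
  expect_equal(slope_ratio(a, b), 0.133 / 0.054, tolerance = 1e-12)
  expect_equal(round(slope_ratio(a, b), 2), 2.46)
  expect_equal(slope_ratio(a, a), 1)
  expect_equal(slope_ratio(-0.1, -0.2), 0.5)
  expect_equal(slope_ratio(a, b) * slope_ratio(b, a), 1, tolerance = 1e-12)
  expect_error(slope_ratio(a, 0), "zero")
})
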