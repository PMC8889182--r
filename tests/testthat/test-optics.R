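test_that("fit_kd recovers the attenuation law exactly on noiseless profiles", {
  for (kd in c(0.06, 0.40, 0.5)) {
    z <- seq(0, 10, by = 0.5)
    m <- fit_kd(light_profile(z, 100 * exp(-kd * z)))
    expect_lt(abs(m$kd - kd) / kd, 1e-10)
    expect_lt(abs(m$e0 - 100) / 100, 1e-10)
    expect_equal(m$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("fit_kd matches the closed-form OLS slope on a noisy profile", {
  set.seed(11)
  z <- seq(0, 10, by = 0.5)
  irr <- 100 * exp(-0.40 * z) * exp(rnorm(length(z), 0, 0.05))
  m <- fit_kd(light_profile(z, irr))
  oracle <- ols_oracle(z, log(irr))
  expect_equal(m$kd, -oracle$slope, tolerance = 1e-12)
  expect_equal(m$e0, exp(oracle$intercept), tolerance = 1e-12)
  expect_lt(abs(m$kd - 0.40), 0.03)
})

test_that("fit_kd is unbiased over noise realisations", {
  z <- seq(0, 10, by = 0.5)
  set.seed(99)
  est <- replicate(500, {
    fit_kd(light_profile(z, 100 * exp(-0.40 * z + rnorm(length(z), 0, 0.05))))$kd
  })
  expect_lt(abs(mean(est) - 0.40) / 0.40, 0.01)
})

test_that("light profiles reject degenerate or non-positive inputs", {
  expect_error(light_profile(c(0, 1), c(100, 50)), "at least 3")
  expect_error(light_profile(c(0, 0, 0), c(3, 2, 1)), "distinct")
  expect_error(light_profile(0:3, c(100, 50, 0, 10)), "strictly positive")
  expect_error(light_profile(c(-1, 0, 1), c(3, 2, 1)), "non-negative")
})

test_that("percent_surface_irradiance matches the turbid-reef field values", {
  m <- optical_model(kd = 0.40)
  expect_equal(round(percent_surface_irradiance(m, 3.5), 1), 24.7)
  expect_equal(round(percent_surface_irradiance(m, 9.5), 1), 2.2)
  expect_equal(percent_surface_irradiance(m, 0), 100)
  expect_error(percent_surface_irradiance(m, -1), "non-negative")
})

test_that("percent irradiance decreases strictly in depth and in kd", {
  depths <- seq(0, 30, by = 0.5)
  for (kd in c(0.06, 0.2, 0.8)) {
    p <- percent_surface_irradiance(kd, depths)
    expect_true(all(diff(p) < 0))
  }
  p_by_kd <- sapply(c(0.05, 0.1, 0.4, 1), percent_surface_irradiance,
                    depth_m = 5)
  expect_true(all(diff(p_by_kd) < 0))
})

test_that("depth_for_irradiance inverts the attenuation law", {
  m <- optical_model(kd = 0.40)
  expect_equal(depth_for_irradiance(m, 100), 0)
  expect_equal(depth_for_irradiance(m, 2.237), 9.5, tolerance = 1e-3)
  z <- 1:10
  expect_equal(depth_for_irradiance(m, percent_surface_irradiance(m, z)), z,
               tolerance = 1e-10)
  expect_error(depth_for_irradiance(m, 0), "\\(0, 100]")
  expect_error(depth_for_irradiance(m, 101), "\\(0, 100]")
  expect_error(depth_for_irradiance(optical_model(kd = -0.1), 50), "kd > 0")
})

test_that("equivalent_depth_increase conserves the optical thickness kd * dz", {
  expect_equal(equivalent_depth_increase(0.40, 6, 0.06), 40)
  expect_equal(equivalent_depth_increase(0.40, 6, 0.08), 30)
  for (k in c(0.05, 0.3, 1.2)) {
    expect_equal(equivalent_depth_increase(k, 7.5, k), 7.5)
  }
  set.seed(3)
  for (i in 1:20) {
    k1 <- runif(1, 0.01, 1); k2 <- runif(1, 0.01, 1); dz <- runif(1, 0.1, 50)
    expect_equal(k2 * equivalent_depth_increase(k1, dz, k2), k1 * dz)
  }
  expect_error(equivalent_depth_increase(0, 6, 0.06), "positive")
  expect_error(equivalent_depth_increase(0.4, 6, -0.1), "positive")
})

test_that("identical logger series give t = 0 and variability ratio 1", {
  cfg <- sim_config(seed = 5)
  lg <- gen_logger_series(cfg)
  s <- summarize_loggers(lg$shallow, lg$shallow)
  expect_equal(s$t_statistic, 0)
  expect_equal(s$variability_ratio, 1)
  expect_equal(s$p_value, 1)
})

test_that("summarize_loggers aggregates to calendar days before testing", {
  # two days whose 30-min readings differ wildly but whose daily means are
  # the same across sites -> t must be 0 despite raw-reading differences
  ts <- rep(as.POSIXct(c("2014-10-01", "2014-10-02"), tz = "UTC"), each = 4) +
    rep(c(0, 6, 12, 18) * 3600, times = 2)
  shallow <- data.frame(timestamp = ts,
                        temperature_c = c(27, 29, 31, 29, 26, 28, 30, 28),
                        relative_light = c(0, 10, 20, 10, 0, 10, 20, 10))
  deep <- data.frame(timestamp = ts,
                     temperature_c = c(28.8, 29.2, 29.1, 28.9, 27.9, 28.1, 28.2, 27.8),
                     relative_light = c(4, 6, 5, 5, 4, 6, 5, 5))
  s <- summarize_loggers(shallow, deep)
  expect_equal(s$temp_mean[["shallow"]], c(mean(c(27, 29, 31, 29)), mean(c(26, 28, 30, 28))) |> mean())
  expect_equal(s$n_days[["shallow"]], 2L)
  # identical daily means -> t = 0
  expect_equal(s$t_statistic, 0, tolerance = 1e-12)
})

test_that("logger summary recovers generating temperature and light structure", {
  cfg <- sim_config(seed = 21)
  lg <- gen_logger_series(cfg)
  s <- summarize_loggers(lg$shallow, lg$deep)
  expect_lt(abs(s$temp_mean[["shallow"]] - 28.85), 0.3)
  expect_lt(abs(s$temp_mean[["deep"]] - 28.46), 0.3)
  expect_gt(s$variability_ratio, 3.5)
  expect_lt(s$variability_ratio, 6.5)
})

test_that("shallow/deep daily light CV ratio recovers the generating ratio of 5", {
  ratios <- sapply(1:100, function(i) {
    lg <- gen_logger_series(sim_config(seed = 1000 + i))
    summarize_loggers(lg$shallow, lg$deep)$variability_ratio
  })
  expect_lt(abs(mean(ratios) - 5), 1)
})

test_that("logger summary rejects empty or malformed series", {
  lg <- gen_logger_series(sim_config(seed = 2))
  expect_error(summarize_loggers(data.frame(), lg$deep), "empty")
  bad <- lg$shallow
  bad$timestamp <- "not a time"
  expect_error(summarize_loggers(bad, lg$deep), "timestamp")
  expect_error(summarize_loggers(lg$shallow[, -1], lg$deep), "timestamp")
})
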