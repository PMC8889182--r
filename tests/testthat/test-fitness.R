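test_that("tally_outcomes counts dead/alive per treatment and excludes discards", {
  out <- data.frame(
    species = "O. annularis",
    treatment = rep(c("S-D", "S-S"), c(5, 4)),
    genotype_id = paste0("g", 1:9),
    status = c("dead", "alive", "alive", "discarded", "dead",
               "alive", "alive", "alive", "alive"))
  tab <- tally_outcomes(out, "S-D", "S-S")
  expect_equal(tab$dead, c(2L, 0L))
  expect_equal(tab$alive, c(2L, 4L))
  expect_equal(tab$n, c(4L, 4L))   # discard reduced group n by 1
  expect_error(tally_outcomes(out, "D-D", "S-S"), "no \\(non-discarded\\)")
  out$status[1] <- "missing"
  expect_error(tally_outcomes(out, "S-D", "S-S"), "unknown status")
})

test_that("tallies round-trip the generator's bookkeeping", {
  cfg <- sim_config(seed = 60)
  out <- gen_transplant_experiment(cfg)
  tab <- tally_outcomes(out, "S-D", "S-S")
  expect_equal(tab$n, unname(cfg$transplant$n[c("S-D", "S-S")]))
  expect_equal(tab$dead[1], sum(out$status == "dead" & out$treatment == "S-D"))
})

test_that("fisher_one_tailed matches full hypergeometric enumeration", {
  # zero deaths anywhere -> p = 1
  expect_equal(fisher_one_tailed(
    transplant_table(c("a", "b"), c(0, 0), c(10, 10)))$p_value, 1)

  # survivorship-contrast-sized tables against the enumeration oracle
  cases <- list(c(8, 29, 0, 27), c(1, 28, 1, 44), c(8, 30, 1, 28),
                c(1, 44, 0, 27), c(0, 44, 0, 27))
  for (cs in cases) {
    p <- fisher_one_tailed(transplant_table(
      c("A", "B"), dead = c(cs[1], cs[3]),
      alive = c(cs[2] - cs[1], cs[4] - cs[3])))$p_value
    expect_equal(p, fisher_enum_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
  # the printed S-D vs S-S contrast value
  p <- fisher_one_tailed(transplant_table(c("S-D", "S-S"), c(8, 0), c(21, 27)))
  expect_equal(round(p$p_value, 3), 0.003)
})

test_that("one-tailed p agrees with enumeration across exhaustive and random tables", {
  # exhaustive sweep of all tables with N <= 12
  for (n1 in 1:11) for (n2 in 1:(12 - n1)) {
    for (d1 in 0:n1) for (d2 in 0:n2) {
      p <- fisher_one_tailed(transplant_table(
        c("A", "B"), dead = c(d1, d2), alive = c(n1 - d1, n2 - d2)))$p_value
      expect_equal(p, fisher_enum_oracle(d1, n1, d2, n2), tolerance = 1e-12)
    }
  }
  # random tables up to N = 60, cross-checked against the oracle and
  # against the one-sided reference implementation in stats
  set.seed(123)
  for (i in 1:2000) {
    n1 <- sample(1:59, 1)
    n2 <- sample(1:(60 - n1), 1)
    d1 <- sample(0:n1, 1)
    d2 <- sample(0:n2, 1)
    p <- fisher_one_tailed(transplant_table(
      c("A", "B"), dead = c(d1, d2), alive = c(n1 - d1, n2 - d2)))$p_value
    expect_equal(p, fisher_enum_oracle(d1, n1, d2, n2), tolerance = 1e-10)
    if (i <= 200) {
      ref <- stats::fisher.test(matrix(c(d1, d2, n1 - d1, n2 - d2), 2),
                                alternative = "greater")$p.value
      expect_equal(p, ref, tolerance = 1e-8)
    }
  }
})

test_that("p is monotone as deaths shift into the tested group at fixed margins", {
  n1 <- 20L; n2 <- 25L; d <- 10L
  ps <- sapply(max(0, d - n2):min(d, n1), function(k) {
    fisher_one_tailed(transplant_table(
      c("A", "B"), dead = c(k, d - k), alive = c(n1 - k, n2 - (d - k))))$p_value
  })
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("selection differentials standardize by mean fitness", {
  s <- selection_differential(0.96, 0.74, species = c("franksi", "annularis"),
                              habitat = "deep")
  expect_equal(s$s, (0.96 - 0.74) / 0.85, tolerance = 1e-12)
  expect_equal(round(s$s, 3), 0.259)
  expect_equal(s$favored, "franksi")
  expect_equal(selection_differential(0.5, 0.5)$s, 0)
  expect_equal(selection_differential(1, 0.5)$s, 2 / 3, tolerance = 1e-12)
  expect_error(selection_differential(0, 0), "undefined")
  expect_error(selection_differential(1.2, 0.5), "\\[0, 1\\]")
})

test_that("selection differential is antisymmetric and bounded by 2", {
  set.seed(17)
  for (i in 1:50) {
    w <- runif(2)
    expect_equal(selection_differential(w[1], w[2])$s,
                 -selection_differential(w[2], w[1])$s, tolerance = 1e-12)
    expect_lte(abs(selection_differential(w[1], w[2])$s), 2)
  }
  expect_equal(abs(selection_differential(0.8, 0)$s), 2)
})

test_that("survivorship_report on an all-alive experiment is null everywhere", {
  cfg <- sim_config(seed = 3)
  cfg$transplant$death_prob[] <- 0
  rep <- survivorship_report(gen_transplant_experiment(cfg))
  expect_true(all(rep$treatments$mortality == 0))
  expect_true(all(sapply(rep$contrasts, `[[`, "p_value") == 1))
  expect_true(all(sapply(rep$selection, `[[`, "s") == 0))
})

test_that("report text follows the mortality/Fisher presentation convention", {
  cfg <- sim_config(seed = 42)
  txt <- capture.output(print(survivorship_report(gen_transplant_experiment(cfg))))
  expect_true(any(grepl("% mortality \\(Fisher exact test: p = ", txt)))
  expect_true(any(grepl("% vs \\d+% mortality", txt)))
})

test_that("discarded colonies are excluded, not counted as dead", {
  cfg <- sim_config(seed = 8)
  cfg$transplant$n[["S-D"]] <- 30L
  cfg$transplant$n_discard[["S-D"]] <- 1L
  out <- gen_transplant_experiment(cfg)
  rep <- survivorship_report(out)
  expect_equal(rep$n_discarded, 1L)
  expect_equal(rep$treatments$n[rep$treatments$treatment == "S-D"], 29L)
})

test_that("simulated experiments recover the generating deep-habitat advantage", {
  s_true <- (0.96 - 0.73) / mean(c(0.96, 0.73))
  s_est <- sapply(1:500, function(i) {
    out <- gen_transplant_experiment(sim_config(seed = 5000 + i))
    survivorship_report(out)$selection$deep$s
  })
  expect_lt(abs(mean(s_est) - 0.26), 0.05)
  expect_lt(abs(mean(s_est) - s_true), 0.03)
})
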