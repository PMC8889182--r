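#' Fit the linear Qm-depth model for one species
#'
#' The excitation pressure over PSII declines roughly linearly with depth; the
#' fitted line's x-intercept is interpreted as the species' theoretical photic
#' depth limit (see [depth_limit()]). Fitted by ordinary least squares of Qm
#' on depth.
#'
#' @param records a `qm_records` data frame (columns `depth_m`, `qm`; a
#'   single-valued `species` column if present), e.g. from
#'   [estimate_survey_qm()].
#' @param species optional species label.
#' @return A `niche_limit_model` with `slope` (Qm per metre), `intercept`,
#'   `r_squared`, `n`, residual s.d. `sigma`, the retained data and `lm` fit.
#' @export
fit_qm_depth <- function(records, species = NULL) {
  stopifnot(is.data.frame(records))
  for (col in c("depth_m", "qm")) {
    if (!col %in% names(records)) {
      stop("records are missing required column '", col, "'", call. = FALSE)
    }
  }
  if (is.null(species) && "species" %in% names(records)) {
    sp <- unique(records$species)
    if (length(sp) > 1L) {
      stop("records span multiple species; fit one species at a time",
           call. = FALSE)
    }
    species <- sp
  }
  records <- records[!is.na(records$depth_m) & !is.na(records$qm), , drop = FALSE]
  if (nrow(records) < 3L || length(unique(records$depth_m)) < 3L) {
    stop("need >= 3 records at >= 3 distinct depths", call. = FALSE)
  }
  fit <- stats::lm(qm ~ depth_m, data = records)
  cf <- stats::coef(fit)
  structure(list(
    species = species %||% NA_character_,
    slope = unname(cf[2L]),
    intercept = unname(cf[1L]),
    r_squared = summary(fit)$r.squared,
    n = nrow(records),
    sigma = summary(fit)$sigma,
    data = records,
    fit = fit
  ), class = "niche_limit_model")
}

#' Construct a Qm-depth model from known coefficients
#'
#' Builds a `niche_limit_model` directly from published regression
#' coefficients (e.g. Qm = 0.735 - 0.133 * depth), without underlying data.
#' [depth_limit()] on such a model returns the x-intercept without a bootstrap
#' interval.
#'
#' @param intercept Qm at the surface extrapolation (z = 0).
#' @param slope change in Qm per metre of depth (negative for a declining
#'   response).
#' @param species optional species label.
#' @return A `niche_limit_model` without data.
#' @export
niche_limit_model <- function(intercept, slope, species = NULL) {
  stopifnot(is.finite(intercept), is.finite(slope))
  structure(list(
    species = species %||% NA_character_,
    slope = as.numeric(slope),
    intercept = as.numeric(intercept),
    r_squared = NA_real_,
    n = NA_integer_,
    sigma = NA_real_,
    data = NULL,
    fit = NULL
  ), class = "niche_limit_model")
}

#' @export
print.niche_limit_model <- function(x, ...) {
  cat(sprintf("Qm-depth model%s: Qm = %.3f %+.3f * depth",
              if (is.na(x$species)) "" else paste0(" (", x$species, ")"),
              x$intercept, x$slope))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.2f, n = %d)", x$r_squared, x$n))
  cat("\n")
  invisible(x)
}

#' Pointwise confidence band of a fitted Qm-depth line
#'
#' @param model a data-backed `niche_limit_model`.
#' @param depth_m depth grid (m).
#' @param level confidence level.
#' @return Data frame with `depth_m`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(model, depth_m, level = 0.95) {
  stopifnot(inherits(model, "niche_limit_model"))
  if (is.null(model$fit)) {
    stop("confidence bands need a data-backed model", call. = FALSE)
  }
  pr <- stats::predict(model$fit, newdata = data.frame(depth_m = depth_m),
                       interval = "confidence", level = level)
  data.frame(depth_m = depth_m, fit = pr[, "fit"],
             lwr = pr[, "lwr"], upr = pr[, "upr"])
}

#' Theoretical depth limit where the fitted Qm line reaches zero
#'
#' Extrapolates the Qm-depth regression to Qm = 0: z* = -intercept/slope, the
#' depth at which the symbionts' excitation pressure vanishes and the
#' bioenergetics of the symbiosis can no longer be sustained. Uncertainty is
#' quantified by a case-resampling bootstrap of the underlying records
#' (percentile interval); bootstrap replicates whose refitted slope is not
#' negative have no finite limit and are discarded (counted, with a warning
#' when more than 10% are lost).
#'
#' @param model a `niche_limit_model` with negative slope. Models built from
#'   bare coefficients (no data) yield a point estimate with `NA` interval.
#' @param bootstrap_reps number of bootstrap replicates (default 2000); 0
#'   skips the bootstrap.
#' @param seed integer seed, required whenever the bootstrap runs.
#' @param level confidence level for the percentile interval.
#' @return A `depth_limit_estimate` with `z_star` (m), `ci_low`, `ci_high`,
#'   replicate bookkeeping and the seed used. Summaries print z* to 0.1 m.
#' @examples
#' depth_limit(niche_limit_model(0.735, -0.133), bootstrap_reps = 0)
#' @export
depth_limit <- function(model, bootstrap_reps = 2000, seed = NULL, level = 0.95) {
  stopifnot(inherits(model, "niche_limit_model"))
  if (!is.finite(model$slope) || model$slope >= 0) {
    stop("depth limit undefined: Qm must decline with depth (slope < 0)",
         call. = FALSE)
  }
  z_star <- -model$intercept / model$slope
  ci <- c(NA_real_, NA_real_)
  n_discarded <- 0L
  reps_used <- 0L
  if (bootstrap_reps > 0 && !is.null(model$data)) {
    if (is.null(seed)) {
      stop("a seed is required for the bootstrap (reproducibility)",
           call. = FALSE)
    }
    set.seed(as.integer(seed))
    x <- model$data$depth_m
    y <- model$data$qm
    n <- length(x)
    B <- as.integer(bootstrap_reps)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B)
    xm <- matrix(x[idx], nrow = n)
    ym <- matrix(y[idx], nrow = n)
    mx <- colMeans(xm)
    my <- colMeans(ym)
    sxx <- colMeans(xm * xm) - mx * mx
    sxy <- colMeans(xm * ym) - mx * my
    slopes <- sxy / sxx
    ints <- my - slopes * mx
    ok <- is.finite(slopes) & slopes < 0
    n_discarded <- sum(!ok)
    reps_used <- sum(ok)
    if (n_discarded > 0.10 * B) {
      warning(n_discarded, " of ", B,
              " bootstrap replicates had non-negative slope and were discarded",
              call. = FALSE)
    }
    z_boot <- -ints[ok] / slopes[ok]
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(z_boot, c(alpha, 1 - alpha)))
  }
  structure(list(
    species = model$species,
    z_star = z_star,
    ci_low = ci[1L],
    ci_high = ci[2L],
    bootstrap_reps = reps_used,
    discarded = n_discarded,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    level = level
  ), class = "depth_limit_estimate")
}

#' @export
print.depth_limit_estimate <- function(x, ...) {
  cat(sprintf("Theoretical depth limit%s: %.1f m",
              if (is.na(x$species)) "" else paste0(" (", x$species, ")"),
              x$z_star))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  [%.0f%% bootstrap CI %.1f-%.1f m, %d replicates]",
                100 * x$level, x$ci_low, x$ci_high, x$bootstrap_reps))
  }
  cat("\n")
  invisible(x)
}

#' ANCOVA: does the Qm-depth slope differ between two species?
#'
#' Fits the full linear model qm ~ depth + species + depth:species and tests
#' the interaction term by the extra-sum-of-squares F test against the
#' additive model. A significant interaction means the two species' Qm-depth
#' slopes differ, i.e. their symbionts respond differently to light
#' attenuation. Denominator degrees of freedom are N - 4.
#'
#' @param records a `qm_records` data frame covering exactly two species
#'   (columns `species`, `depth_m`, `qm`).
#' @return An `ancova_result` with `f_statistic`, `df1`, `df2`, `p_value` and
#'   per-species slopes.
#' @export
ancova_interaction <- function(records) {
  stopifnot(is.data.frame(records))
  for (col in c("species", "depth_m", "qm")) {
    if (!col %in% names(records)) {
      stop("records are missing required column '", col, "'", call. = FALSE)
    }
  }
  records <- records[!is.na(records$qm) & !is.na(records$depth_m), , drop = FALSE]
  records$species <- factor(records$species)
  if (nlevels(records$species) != 2L) {
    stop("ANCOVA requires exactly two species", call. = FALSE)
  }
  counts <- table(records$species)
  depths <- tapply(records$depth_m, records$species,
                   function(z) length(unique(z)))
  if (any(counts < 3L) || any(depths < 2L)) {
    stop("each species needs >= 3 records at >= 2 distinct depths",
         call. = FALSE)
  }
  full <- stats::lm(qm ~ depth_m * species, data = records)
  reduced <- stats::lm(qm ~ depth_m + species, data = records)
  cmp <- stats::anova(reduced, full)
  cf <- stats::coef(full)
  slopes <- c(unname(cf["depth_m"]),
              unname(cf["depth_m"]) + unname(cf[4L]))
  names(slopes) <- levels(records$species)
  structure(list(
    species = levels(records$species),
    f_statistic = cmp$F[2L],
    df1 = cmp$Df[2L],
    df2 = cmp$Res.Df[2L],
    p_value = cmp$`Pr(>F)`[2L],
    slopes = slopes,
    n = nrow(records)
  ), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("Species x depth interaction: F(%d,%d) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$f_statistic, x$p_value))
  cat(sprintf("  slopes: %s %.3f, %s %.3f (Qm per m)\n",
              x$species[1L], x$slopes[1L], x$species[2L], x$slopes[2L]))
  invisible(x)
}

#' Ratio of Qm-depth slope magnitudes between two models
#'
#' How much more pronounced one species' Qm decline with depth is than
#' another's: |slope_a| / |slope_b|.
#'
#' @param model_a,model_b `niche_limit_model`s, or bare numeric slopes.
#' @return Positive scalar ratio; `slope_ratio(a, b) * slope_ratio(b, a) = 1`.
#' @export
slope_ratio <- function(model_a, model_b) {
  sl <- function(m) {
    if (inherits(m, "niche_limit_model")) m$slope
    else if (is.numeric(m) && length(m) == 1L) m
    else stop("expected a niche_limit_model or a single numeric slope",
              call. = FALSE)
  }
  a <- sl(model_a)
  b <- sl(model_b)
  if (b == 0) stop("denominator slope is zero", call. = FALSE)
  abs(a) / abs(b)
}
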