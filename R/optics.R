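#' Construct and validate an underwater light profile
#'
#' A light profile is a set of paired (depth, irradiance) readings taken down
#' the water column, used to estimate the diffuse attenuation coefficient for
#' downwelling irradiance (Kd). Depth is positive downward in metres with the
#' surface at z = 0; irradiance is in instrument units (or percent, with 100
#' at the surface) and must be strictly positive because the attenuation model
#' is fitted on the log scale.
#'
#' @param depth_m numeric vector of depths in metres (>= 0), or a data frame
#'   with columns `depth_m` and `irradiance`.
#' @param irradiance numeric vector of strictly positive irradiance readings,
#'   ignored when `depth_m` is a data frame.
#' @return A `light_profile`, a data frame with columns `depth_m` and
#'   `irradiance`.
#' @examples
#' z <- 0:10
#' light_profile(z, 100 * exp(-0.5 * z))
#' @export
light_profile <- function(depth_m, irradiance = NULL) {
  if (is.data.frame(depth_m)) {
    df <- depth_m
    for (col in c("depth_m", "irradiance")) {
      if (!col %in% names(df)) {
        stop("light profile is missing required column '", col, "'", call. = FALSE)
      }
    }
    depth_m <- df$depth_m
    irradiance <- df$irradiance
  }
  depth_m <- as.numeric(depth_m)
  irradiance <- as.numeric(irradiance)
  if (length(depth_m) != length(irradiance)) {
    stop("depth_m and irradiance must have the same length", call. = FALSE)
  }
  if (anyNA(depth_m) || anyNA(irradiance) ||
      any(!is.finite(depth_m)) || any(!is.finite(irradiance))) {
    stop("light profile readings must be finite and non-missing", call. = FALSE)
  }
  if (any(depth_m < 0)) {
    stop("depths must be non-negative (positive downward, surface at 0 m)",
         call. = FALSE)
  }
  if (any(irradiance <= 0)) {
    stop("all irradiance values must be strictly positive (log-linear fit)",
         call. = FALSE)
  }
  if (length(depth_m) < 3 || length(unique(depth_m)) < 3) {
    stop("a light profile needs at least 3 readings at 3 distinct depths",
         call. = FALSE)
  }
  structure(data.frame(depth_m = depth_m, irradiance = irradiance),
            class = c("light_profile", "data.frame"))
}

#' Construct an optical water-column model
#'
#' Houses the exponential attenuation law E(z) = E0 * exp(-Kd * z). Usually
#' produced by [fit_kd()], but can be built directly from a known attenuation
#' coefficient (e.g. a published Kd) to evaluate irradiance at depth.
#'
#' @param kd diffuse attenuation coefficient for downwelling irradiance
#'   (m^-1); higher values mean murkier water.
#' @param e0 surface irradiance (instrument units, or 100 for percent scale).
#' @param r_squared goodness of fit of the log-linear regression, if fitted.
#' @param n number of profile readings behind the fit, if fitted.
#' @param fit the underlying `lm` object, if fitted.
#' @return An object of class `optical_model`.
#' @seealso [fit_kd()], [percent_surface_irradiance()], [depth_for_irradiance()]
#' @export
optical_model <- function(kd, e0 = 100, r_squared = NA_real_,
                          n = NA_integer_, fit = NULL) {
  kd <- as.numeric(kd)
  e0 <- as.numeric(e0)
  stopifnot(length(kd) == 1L, length(e0) == 1L)
  if (!is.finite(kd)) stop("kd must be finite", call. = FALSE)
  if (!is.finite(e0) || e0 <= 0) stop("e0 must be positive", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  }
  structure(list(kd = kd, e0 = e0, r_squared = r_squared,
                 n = n, fit = fit),
            class = "optical_model")
}

#' @export
print.optical_model <- function(x, ...) {
  cat("Optical model: E(z) = E0 * exp(-Kd * z)\n")
  cat(sprintf("  Kd = %.4g m^-1, E0 = %.4g", x$kd, x$e0))
  if (!is.na(x$r_squared)) cat(sprintf(", R^2 = %.3f (n = %d)", x$r_squared, x$n))
  cat("\n")
  invisible(x)
}

#' Estimate the diffuse attenuation coefficient Kd from a light profile
#'
#' Fits the attenuation law E(z) = E0 * exp(-Kd * z) by ordinary least squares
#' of log(irradiance) on depth: the slope is -Kd and the intercept log(E0).
#' The log-linear fit is standard optical-oceanography practice and assumes
#' multiplicative (log-normal) sensor error.
#'
#' @param profile a [light_profile()] (or a data frame coercible to one).
#' @return An [optical_model()] with `kd`, `e0`, `r_squared`, `n` and the
#'   underlying `lm` fit.
#' @examples
#' z <- seq(0, 10, by = 0.5)
#' fit_kd(light_profile(z, 100 * exp(-0.40 * z)))
#' @export
fit_kd <- function(profile) {
  profile <- light_profile(profile)
  fit <- stats::lm(log(irradiance) ~ depth_m, data = profile)
  cf <- stats::coef(fit)
  optical_model(kd = -unname(cf[2L]),
                e0 = exp(unname(cf[1L])),
                r_squared = summary(fit)$r.squared,
                n = nrow(profile),
                fit = fit)
}

# Accept either an optical_model or a bare Kd value.
as_optical_model <- function(model) {
  if (inherits(model, "optical_model")) return(model)
  if (is.numeric(model) && length(model) == 1L) return(optical_model(kd = model))
  stop("expected an optical_model or a single numeric Kd", call. = FALSE)
}

#' Percent of surface irradiance at depth
#'
#' Evaluates E(z)/E0 as a percentage: 100 * exp(-Kd * z). Strictly decreasing
#' in both depth and Kd; equals 100 at the surface.
#'
#' @param model an [optical_model()] or a single numeric Kd (m^-1).
#' @param depth_m depth(s) in metres, non-negative.
#' @return Numeric vector of percentages in (0, 100].
#' @examples
#' percent_surface_irradiance(0.40, c(3.5, 9.5))
#' @export
percent_surface_irradiance <- function(model, depth_m) {
  model <- as_optical_model(model)
  depth_m <- as.numeric(depth_m)
  if (anyNA(depth_m) || any(depth_m < 0)) {
    stop("depth_m must be non-negative (positive downward)", call. = FALSE)
  }
  100 * exp(-model$kd * depth_m)
}

#' Depth at which a given percent of surface irradiance remains
#'
#' Inverse of [percent_surface_irradiance()]: z = -log(percent/100) / Kd.
#' Useful for expressing a species' habitat range as an irradiance band.
#'
#' @param model an [optical_model()] or a single numeric Kd; `kd` must be > 0.
#' @param percent percent of surface irradiance, in (0, 100].
#' @return Depth(s) in metres.
#' @export
depth_for_irradiance <- function(model, percent) {
  model <- as_optical_model(model)
  if (model$kd <= 0) {
    stop("depth_for_irradiance requires an attenuating model (kd > 0)",
         call. = FALSE)
  }
  percent <- as.numeric(percent)
  if (anyNA(percent) || any(percent <= 0) || any(percent > 100)) {
    stop("percent must lie in (0, 100]", call. = FALSE)
  }
  -log(percent / 100) / model$kd
}

#' Translate a depth response across waters of different clarity
#'
#' Two water columns produce the same attenuation factor when Kd * dz is
#' equal, so a response observed over a depth increase `delta_z_reference` in
#' water with `kd_reference` is expected over
#' `kd_reference * delta_z_reference / kd_target` metres in water with
#' `kd_target`. E.g. the light reduction over 6 m in turbid water
#' (Kd = 0.40 m^-1) needs about 40 m in very clear water (Kd = 0.06 m^-1).
#'
#' @param kd_reference attenuation coefficient of the reference site (m^-1).
#' @param delta_z_reference depth increase at the reference site (m).
#' @param kd_target attenuation coefficient of the target site (m^-1).
#' @return Equivalent depth increase at the target site, in metres.
#' @export
equivalent_depth_increase <- function(kd_reference, delta_z_reference, kd_target) {
  args <- c(kd_reference = kd_reference, delta_z_reference = delta_z_reference,
            kd_target = kd_target)
  if (anyNA(args) || any(args <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  kd_reference * delta_z_reference / kd_target
}

#' Summarize paired shallow/deep logger time series
#'
#' Aggregates 30-min (or any sub-daily) logger readings to calendar-day means,
#' then reports per-site daily-temperature means and standard deviations, a
#' two-sample t test comparing daily temperatures between sites, and the ratio
#' of the coefficients of variation of daily mean relative light
#' (shallow CV / deep CV). Light variability is computed on daily means rather
#' than raw readings so the diel cycle does not dominate the CV.
#'
#' @param shallow,deep data frames with columns `timestamp` (POSIXct or
#'   ISO-8601 character), `temperature_c` and `relative_light`.
#' @param var.equal logical; use the classical pooled-variance Student t test
#'   (default) or Welch's test.
#' @return An object of class `environment_summary` with per-site statistics,
#'   `variability_ratio`, `t_statistic`, `df` and `p_value`.
#' @export
summarize_loggers <- function(shallow, deep, var.equal = TRUE) {
  agg_s <- aggregate_daily(shallow, "shallow")
  agg_d <- aggregate_daily(deep, "deep")
  tt <- stats::t.test(agg_s$temperature_c, agg_d$temperature_c,
                      var.equal = var.equal)
  cv <- function(x) stats::sd(x) / mean(x)
  cv_s <- cv(agg_s$relative_light)
  cv_d <- cv(agg_d$relative_light)
  structure(list(
    sites = c("shallow", "deep"),
    n_days = c(shallow = nrow(agg_s), deep = nrow(agg_d)),
    temp_mean = c(shallow = mean(agg_s$temperature_c),
                  deep = mean(agg_d$temperature_c)),
    temp_sd = c(shallow = stats::sd(agg_s$temperature_c),
                deep = stats::sd(agg_d$temperature_c)),
    light_cv = c(shallow = cv_s, deep = cv_d),
    variability_ratio = cv_s / cv_d,
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    test = if (var.equal) "Student two-sample t" else "Welch two-sample t"
  ), class = "environment_summary")
}

# Collapse a logger series to calendar-day means; drops (and reports) days
# without readings implicitly since only observed days appear.
aggregate_daily <- function(series, label) {
  if (!is.data.frame(series) || nrow(series) == 0L) {
    stop("logger series '", label, "' is empty", call. = FALSE)
  }
  for (col in c("timestamp", "temperature_c", "relative_light")) {
    if (!col %in% names(series)) {
      stop("logger series '", label, "' is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  ts <- series$timestamp
  if (!inherits(ts, "POSIXt")) {
    ts <- tryCatch(
      as.POSIXct(as.character(ts), tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                "%Y-%m-%d %H:%M", "%Y-%m-%d")),
      error = function(e) NA)
  }
  if (anyNA(ts)) {
    stop("logger series '", label, "' has unparseable timestamps", call. = FALSE)
  }
  day <- as.Date(ts)
  out <- data.frame(
    day = sort(unique(day)),
    temperature_c = as.numeric(tapply(series$temperature_c, day, mean)),
    relative_light = as.numeric(tapply(series$relative_light, day, mean))
  )
  if (nrow(out) < 2L) {
    stop("logger series '", label, "' needs readings on at least 2 days",
         call. = FALSE)
  }
  out
}

#' @export
print.environment_summary <- function(x, ...) {
  cat("Environment summary (daily aggregates)\n")
  cat(sprintf("  shallow: %.2f +/- %.2f C over %d days\n",
              x$temp_mean["shallow"], x$temp_sd["shallow"], x$n_days["shallow"]))
  cat(sprintf("  deep:    %.2f +/- %.2f C over %d days\n",
              x$temp_mean["deep"], x$temp_sd["deep"], x$n_days["deep"]))
  cat(sprintf("  %s: t = %.2f, df = %.1f, p = %.3g\n",
              x$test, x$t_statistic, x$df, x$p_value))
  cat(sprintf("  light variability ratio (shallow CV / deep CV) = %.2f\n",
              x$variability_ratio))
  invisible(x)
}
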