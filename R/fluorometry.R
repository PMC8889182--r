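#' Maximum excitation pressure over photosystem II (Qm)
#'
#' Qm = 1 - (dF/Fm') / (Fv/Fm), where dF/Fm' is the effective quantum yield
#' of PSII measured under peak ambient light (noon) and Fv/Fm the maximum
#' quantum yield measured on dark-acclimated tissue (dusk). Qm approaches 1
#' under excess light (high excitation pressure, photoinhibition risk) and 0
#' under light limitation. Values are not clamped: measurement noise can make
#' individual Qm slightly negative, and such values are retained.
#'
#' Scale invariance: multiplying both yields by a common factor leaves Qm
#' unchanged.
#'
#' @param delta_f_fm_prime effective quantum yield of PSII at noon, in [0, 1].
#' @param fv_fm maximum quantum yield of PSII at dusk, in (0, 1].
#' @return Numeric vector of Qm values (<= 1 for non-negative inputs).
#'   Missing inputs propagate to `NA`.
#' @examples
#' compute_qm(0.31, 0.62) # 0.5
#' @export
compute_qm <- function(delta_f_fm_prime, fv_fm) {
  delta_f_fm_prime <- as.numeric(delta_f_fm_prime)
  fv_fm <- as.numeric(fv_fm)
  if (any(fv_fm <= 0, na.rm = TRUE)) {
    stop("fv_fm must be strictly positive", call. = FALSE)
  }
  if (any(delta_f_fm_prime < 0, na.rm = TRUE)) {
    stop("delta_f_fm_prime must be non-negative", call. = FALSE)
  }
  1 - delta_f_fm_prime / fv_fm
}

#' Calibrate Fv/Fm against depth for one species
#'
#' Dusk Fv/Fm measurements are logistically expensive, so surveys typically
#' measure them on a subsample of colonies spread over the species' depth
#' range and predict Fv/Fm for the remaining colonies from a linear
#' depth regression (Fv/Fm increases with depth as symbionts photoacclimate
#' to low light).
#'
#' @param records a data frame of fluorometry records with columns `depth_m`
#'   and `fv_fm` (rows with missing `fv_fm` are dropped); a `species` column,
#'   if present, must be single-valued.
#' @param species optional species label; defaults to the records' species.
#' @return A `depth_calibration` with `slope` (Fv/Fm per metre), `intercept`,
#'   `r_squared`, `n` and the calibration depth range.
#' @export
calibrate_fvfm_depth <- function(records, species = NULL) {
  stopifnot(is.data.frame(records))
  for (col in c("depth_m", "fv_fm")) {
    if (!col %in% names(records)) {
      stop("records are missing required column '", col, "'", call. = FALSE)
    }
  }
  if (is.null(species) && "species" %in% names(records)) {
    sp <- unique(records$species)
    if (length(sp) > 1L) {
      stop("records span multiple species; calibrate one species at a time",
           call. = FALSE)
    }
    species <- sp
  }
  keep <- !is.na(records$fv_fm) & !is.na(records$depth_m)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(dropped, " record(s) without measured fv_fm dropped from calibration")
  }
  records <- records[keep, , drop = FALSE]
  if (nrow(records) < 3L || length(unique(records$depth_m)) < 3L) {
    stop("calibration needs >= 3 records at >= 3 distinct depths", call. = FALSE)
  }
  fit <- stats::lm(fv_fm ~ depth_m, data = records)
  cf <- stats::coef(fit)
  structure(list(
    species = species %||% NA_character_,
    slope = unname(cf[2L]),
    intercept = unname(cf[1L]),
    r_squared = summary(fit)$r.squared,
    n = nrow(records),
    depth_range = range(records$depth_m),
    fit = fit
  ), class = "depth_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.depth_calibration <- function(x, ...) {
  cat(sprintf("Fv/Fm depth calibration%s\n",
              if (is.na(x$species)) "" else paste0(" for ", x$species)))
  cat(sprintf("  Fv/Fm = %.4f %+.4f * depth  (R^2 = %.2f, n = %d, %g-%g m)\n",
              x$intercept, x$slope, x$r_squared, x$n,
              x$depth_range[1L], x$depth_range[2L]))
  invisible(x)
}

# lower truncation bound for predicted Fv/Fm: (0, 1] has no minimum, so a
# small positive floor keeps downstream Qm defined.
.fvfm_floor <- 1e-3

#' Predict Fv/Fm at depth from a calibration
#'
#' Evaluates the calibration line and truncates the result into (0, 1] (the
#' physical range of a quantum yield); truncation and extrapolation beyond the
#' calibration depth range both raise warnings rather than errors.
#'
#' @param calibration a [calibrate_fvfm_depth()] result, or a list with
#'   `slope` and `intercept`.
#' @param depth_m depth(s) in metres.
#' @return Predicted Fv/Fm value(s) in (0, 1].
#' @export
predict_fvfm <- function(calibration, depth_m) {
  stopifnot(is.list(calibration),
            !is.null(calibration$slope), !is.null(calibration$intercept))
  depth_m <- as.numeric(depth_m)
  rng <- calibration$depth_range
  if (!is.null(rng) && any(depth_m < rng[1L] | depth_m > rng[2L], na.rm = TRUE)) {
    warning("predicting Fv/Fm outside the calibration depth range (",
            rng[1L], "-", rng[2L], " m): extrapolation", call. = FALSE)
  }
  pred <- calibration$intercept + calibration$slope * depth_m
  hi <- pred > 1
  lo <- pred <= 0
  if (any(hi, na.rm = TRUE) || any(lo, na.rm = TRUE)) {
    warning(sum(hi, na.rm = TRUE) + sum(lo, na.rm = TRUE),
            " predicted Fv/Fm value(s) truncated into (0, 1]", call. = FALSE)
  }
  pred[which(hi)] <- 1
  pred[which(lo)] <- .fvfm_floor
  pred
}

#' Compute Qm for survey colonies, predicting Fv/Fm where unmeasured
#'
#' For each survey record, Fv/Fm is taken from the measurement when present
#' and otherwise predicted from the species' depth calibration; Qm is then
#' 1 - (dF/Fm')/(Fv/Fm). The `source` column records which route was used.
#' Records missing dF/Fm' are skipped with a message.
#'
#' @param records fluorometry records for one species with columns `species`,
#'   `colony_id`, `depth_m`, `delta_f_fm_prime` and optionally `fv_fm`.
#' @param calibration the species' [calibrate_fvfm_depth()] result; its
#'   species label must match the records.
#' @return A `qm_records` data frame with columns `species`, `colony_id`,
#'   `depth_m`, `qm`, `source` (`"measured"` or `"fvfm_predicted"`).
#' @export
estimate_survey_qm <- function(records, calibration) {
  stopifnot(is.data.frame(records))
  for (col in c("species", "colony_id", "depth_m", "delta_f_fm_prime")) {
    if (!col %in% names(records)) {
      stop("records are missing required column '", col, "'", call. = FALSE)
    }
  }
  sp <- unique(records$species)
  if (length(sp) != 1L) {
    stop("records must cover exactly one species", call. = FALSE)
  }
  if (!is.na(calibration$species) && !identical(calibration$species, sp)) {
    stop("calibration species (", calibration$species,
         ") does not match records (", sp, ")", call. = FALSE)
  }
  usable <- !is.na(records$delta_f_fm_prime)
  if (any(!usable)) {
    message(sum(!usable), " record(s) missing delta_f_fm_prime skipped")
  }
  records <- records[usable, , drop = FALSE]
  has_fvfm <- if ("fv_fm" %in% names(records)) !is.na(records$fv_fm) else
    rep(FALSE, nrow(records))
  fvfm <- numeric(nrow(records))
  fvfm[has_fvfm] <- records$fv_fm[has_fvfm]
  if (any(!has_fvfm)) {
    fvfm[!has_fvfm] <- predict_fvfm(calibration, records$depth_m[!has_fvfm])
  }
  out <- data.frame(
    species = records$species,
    colony_id = records$colony_id,
    depth_m = records$depth_m,
    qm = compute_qm(records$delta_f_fm_prime, fvfm),
    source = ifelse(has_fvfm, "measured", "fvfm_predicted"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("qm_records", "data.frame")
  out
}

#' Two-sample comparison of a fluorometry variable between treatments
#'
#' Runs a two-sample t test on Fv/Fm or Qm between two treatment groups of a
#' reciprocal transplant (e.g. shallow-to-deep vs shallow-to-shallow). Welch's
#' unequal-variance test is the default; set `var.equal = TRUE` for the
#' classical pooled test.
#'
#' @param group_a,group_b numeric vectors, or data frames holding `variable`.
#' @param variable which variable the values represent (`"fv_fm"` or `"qm"`);
#'   used for labelling, and for column extraction when data frames are given.
#' @param labels character vector of two group labels.
#' @param var.equal logical, passed to [stats::t.test()].
#' @return A `t_test_result` with group means/s.d., `t_statistic`, `df` and
#'   `p_value` (two-sided).
#' @export
compare_treatments <- function(group_a, group_b,
                               variable = c("fv_fm", "qm"),
                               labels = c("A", "B"),
                               var.equal = FALSE) {
  variable <- match.arg(variable)
  pull <- function(g) {
    if (is.data.frame(g)) {
      if (!variable %in% names(g)) {
        stop("data frame group lacks column '", variable, "'", call. = FALSE)
      }
      g <- g[[variable]]
    }
    g <- as.numeric(g)
    g[!is.na(g)]
  }
  a <- pull(group_a)
  b <- pull(group_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = var.equal)
  structure(list(
    variable = variable,
    labels = labels,
    n = c(length(a), length(b)),
    means = c(mean(a), mean(b)),
    sds = c(stats::sd(a), stats::sd(b)),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    test = if (var.equal) "Student" else "Welch"
  ), class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s: %s %0.3f +/- %0.3f vs %s %0.3f +/- %0.3f\n",
              x$variable, x$labels[1L], x$means[1L], x$sds[1L],
              x$labels[2L], x$means[2L], x$sds[2L]))
  cat(sprintf("  %s t-value = %.2f, df = %.1f, p = %.3g\n",
              x$test, x$t_statistic, x$df, x$p_value))
  invisible(x)
}
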