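# CSV schemas shared by readers, writers and the generator.
.schemas <- list(
  profile = c("depth_m", "irradiance"),
  loggers = c("timestamp", "site", "temperature_c", "relative_light"),
  pam = c("species", "colony_id", "depth_m", "treatment", "timepoint_d",
          "delta_f_fm_prime", "fv_fm"),
  outcomes = c("species", "treatment", "genotype_id", "status")
)

# Read a CSV, check required columns, and drop rows failing `validator`
# (a function row-df -> logical) with a line-numbered warning.
read_checked_csv <- function(path, schema, validator = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("file is empty: ", path, call. = FALSE)
  missing <- setdiff(.schemas[[schema]], names(df))
  if (length(missing) > 0L) {
    stop("'", basename(path), "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(validator)) {
    ok <- validator(df)
    ok[is.na(ok)] <- FALSE
    if (any(!ok)) {
      # +1 for the header line
      warning("'", basename(path), "': rejected ", sum(!ok),
              " malformed row(s) at line(s) ",
              paste(which(!ok) + 1L, collapse = ", "), call. = FALSE)
      df <- df[ok, , drop = FALSE]
    }
    if (nrow(df) == 0L) {
      stop("'", basename(path), "': no valid rows remain", call. = FALSE)
    }
  }
  df
}

#' Read a light-profile CSV
#'
#' Expected columns: `depth_m,irradiance` (header required). Rows with
#' non-finite depth, negative depth or non-positive irradiance are rejected
#' with a line-numbered warning.
#'
#' @param path CSV file path.
#' @return A [light_profile()].
#' @export
read_light_profile <- function(path) {
  df <- read_checked_csv(path, "profile", function(d) {
    is.finite(suppressWarnings(as.numeric(d$depth_m))) &
      is.finite(suppressWarnings(as.numeric(d$irradiance))) &
      as.numeric(d$depth_m) >= 0 & as.numeric(d$irradiance) > 0
  })
  light_profile(as.numeric(df$depth_m), as.numeric(df$irradiance))
}

#' Read a logger CSV and split it by site
#'
#' Expected columns: `timestamp,site,temperature_c,relative_light` with
#' ISO-8601 timestamps and site labels `shallow`/`deep`.
#'
#' @param path CSV file path.
#' @return List with `shallow` and `deep` data frames.
#' @export
read_logger_series <- function(path) {
  df <- read_checked_csv(path, "loggers", function(d) {
    d$site %in% c("shallow", "deep") &
      is.finite(suppressWarnings(as.numeric(d$temperature_c))) &
      is.finite(suppressWarnings(as.numeric(d$relative_light)))
  })
  lapply(split(df, factor(df$site, levels = c("shallow", "deep"))), function(x) {
    x[order(x$timestamp), , drop = FALSE]
  })
}

#' Read a PAM fluorometry CSV
#'
#' Expected columns:
#' `species,colony_id,depth_m,treatment,timepoint_d,delta_f_fm_prime,fv_fm`;
#' empty cells mark missing yields. Rows with non-positive depth or yields
#' outside \[0, 1\] are rejected with a line-numbered warning.
#'
#' @param path CSV file path.
#' @return Data frame of fluorometry records.
#' @export
read_pam_records <- function(path) {
  in_unit <- function(x) is.na(x) | (x >= 0 & x <= 1)
  df <- read_checked_csv(path, "pam", function(d) {
    depth <- suppressWarnings(as.numeric(d$depth_m))
    is.finite(depth) & depth > 0 &
      in_unit(suppressWarnings(as.numeric(d$delta_f_fm_prime))) &
      in_unit(suppressWarnings(as.numeric(d$fv_fm)))
  })
  df$depth_m <- as.numeric(df$depth_m)
  df$delta_f_fm_prime <- as.numeric(df$delta_f_fm_prime)
  df$fv_fm <- as.numeric(df$fv_fm)
  df
}

#' Read a transplant-outcome CSV
#'
#' Expected columns: `species,treatment,genotype_id,status` with status one
#' of `alive`, `dead`, `discarded`.
#'
#' @param path CSV file path.
#' @return Data frame of transplant outcomes.
#' @export
read_transplant_outcomes <- function(path) {
  read_checked_csv(path, "outcomes", function(d) {
    d$status %in% c("alive", "dead", "discarded")
  })
}

#' Write the four synthetic datasets as CSV files
#'
#' Emits `profile.csv`, `loggers.csv`, `pam.csv` (all species, survey +
#' calibration records) and `outcomes.csv` with the exact schemas the readers
#' expect. Output is byte-identical for identical configs.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulated_data <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(profile = file.path(dir, "profile.csv"),
             loggers = file.path(dir, "loggers.csv"),
             pam = file.path(dir, "pam.csv"),
             outcomes = file.path(dir, "outcomes.csv"))
  prof <- gen_light_profile(config)
  utils::write.csv(as.data.frame(prof), paths["profile"], row.names = FALSE)
  lg <- gen_logger_series(config)
  lg <- rbind(lg$shallow, lg$deep)
  lg$timestamp <- format(lg$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(lg, paths["loggers"], row.names = FALSE)
  pam <- do.call(rbind, lapply(names(config$species), function(sp) {
    out <- gen_fluorometry_survey(config, sp)
    attributes(out)[c("qm_true", "fvfm_true")] <- NULL
    out
  }))
  utils::write.csv(pam, paths["pam"], row.names = FALSE)
  utils::write.csv(gen_transplant_experiment(config), paths["outcomes"],
                   row.names = FALSE)
  invisible(paths)
}

#' Run the full photic-niche analysis pipeline
#'
#' Orchestrates the four analysis stages on in-memory data or CSV paths:
#' optics (Kd fit and percent irradiance at the transplant depths),
#' environment (logger summary), fluorometry + niche limits (per-species
#' Fv/Fm calibration, survey Qm, Qm-depth fit, bootstrap depth limit, and the
#' cross-species ANCOVA), and fitness (survivorship report). Identical inputs
#' and seed give identical reports.
#'
#' @param data either a list with elements `profile`, `loggers` (list of
#'   `shallow`/`deep`), `pam`, `outcomes`, or a named list/vector of the four
#'   CSV paths (same names).
#' @param bootstrap_reps bootstrap replicates for each depth limit.
#' @param seed integer seed for the bootstrap streams (mandatory when
#'   `bootstrap_reps > 0`).
#' @param report_depths depths (m) at which percent surface irradiance is
#'   reported.
#' @return An `analysis_report` list with blocks `optics`, `environment`,
#'   `niche`, `fitness` and `provenance`.
#' @export
run_pipeline <- function(data, bootstrap_reps = 2000, seed = NULL,
                         report_depths = c(3.5, 9.5)) {
  if (bootstrap_reps > 0 && is.null(seed)) {
    stop("a seed is required when the bootstrap is enabled", call. = FALSE)
  }
  if (all(vapply(data, is.character, TRUE))) {
    data <- list(profile = read_light_profile(data[["profile"]]),
                 loggers = read_logger_series(data[["loggers"]]),
                 pam = read_pam_records(data[["pam"]]),
                 outcomes = read_transplant_outcomes(data[["outcomes"]]))
  }
  for (el in c("profile", "pam", "outcomes")) {
    if (is.null(data[[el]])) stop("pipeline input '", el, "' missing", call. = FALSE)
  }

  optics <- fit_kd(data$profile)
  env <- if (!is.null(data$loggers)) {
    summarize_loggers(data$loggers$shallow, data$loggers$deep)
  }

  pam <- data$pam
  species <- sort(unique(pam$species))
  niche <- list(species = list())
  qm_all <- NULL
  for (i in seq_along(species)) {
    sp <- species[i]
    rec <- pam[pam$species == sp, , drop = FALSE]
    calib <- calibrate_fvfm_depth(rec)
    qm <- estimate_survey_qm(rec, calib)
    fitm <- fit_qm_depth(qm)
    dl <- depth_limit(fitm, bootstrap_reps = bootstrap_reps,
                      seed = if (is.null(seed)) NULL else seed + i)
    niche$species[[sp]] <- list(calibration = calib, model = fitm,
                                depth_limit = dl)
    qm_all <- rbind(qm_all, qm)
  }
  if (length(species) == 2L) {
    niche$ancova <- ancova_interaction(qm_all)
    niche$slope_ratio <- slope_ratio(niche$species[[1L]]$model,
                                     niche$species[[2L]]$model)
  }

  fitness <- survivorship_report(data$outcomes)

  structure(list(
    optics = list(model = optics,
                  percent_irradiance = stats::setNames(
                    percent_surface_irradiance(optics, report_depths),
                    paste0(report_depths, "m"))),
    environment = env,
    niche = niche,
    fitness = fitness,
    provenance = list(package = "photoniche",
                      version = as.character(utils::packageVersion("photoniche")),
                      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                      bootstrap_reps = bootstrap_reps)
  ), class = "analysis_report")
}

#' Serialize an analysis report to JSON
#'
#' Numeric fields keep full precision; the text rendering (see
#' `print.analysis_report`) follows field conventions instead (mortality as
#' whole percent, depth limits to 0.1 m, yields to 3 decimals).
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param path optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  x <- list(
    optics = list(
      kd_per_m = report$optics$model$kd,
      e0 = report$optics$model$e0,
      r_squared = report$optics$model$r_squared,
      percent_surface_irradiance = as.list(report$optics$percent_irradiance)
    ),
    environment = if (!is.null(report$environment)) {
      e <- report$environment
      list(temp_mean_c = as.list(e$temp_mean), temp_sd_c = as.list(e$temp_sd),
           n_days = as.list(e$n_days), light_cv = as.list(e$light_cv),
           variability_ratio = e$variability_ratio,
           t_statistic = e$t_statistic, df = e$df, p_value = e$p_value)
    },
    niche = c(
      list(species = lapply(report$niche$species, function(s) list(
        calibration = list(slope_per_m = s$calibration$slope,
                           intercept = s$calibration$intercept,
                           r_squared = s$calibration$r_squared,
                           n = s$calibration$n),
        qm_model = list(slope_per_m = s$model$slope,
                        intercept = s$model$intercept,
                        r_squared = s$model$r_squared, n = s$model$n),
        depth_limit_m = list(z_star = s$depth_limit$z_star,
                             ci_low = s$depth_limit$ci_low,
                             ci_high = s$depth_limit$ci_high,
                             bootstrap_reps = s$depth_limit$bootstrap_reps)
      ))),
      if (!is.null(report$niche$ancova)) list(ancova = list(
        f_statistic = report$niche$ancova$f_statistic,
        df1 = report$niche$ancova$df1, df2 = report$niche$ancova$df2,
        p_value = report$niche$ancova$p_value),
        slope_ratio = report$niche$slope_ratio)
    ),
    fitness = list(
      treatments = report$fitness$treatments,
      contrasts = lapply(report$fitness$contrasts, function(f) list(
        groups = f$table$groups, dead = f$table$dead, n = f$table$n,
        mortality = f$table$mortality, p_value = f$p_value)),
      selection = lapply(report$fitness$selection, function(s) list(
        habitat = s$habitat, favored = s$favored,
        w_favored = s$w_favored, w_other = s$w_other, s = s$s)),
      n_discarded = report$fitness$n_discarded
    ),
    provenance = report$provenance
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Photic-niche analysis report ==\n\nOptics\n")
  print(x$optics$model)
  for (nm in names(x$optics$percent_irradiance)) {
    cat(sprintf("  %s: %.0f%% of surface irradiance\n", nm,
                x$optics$percent_irradiance[[nm]]))
  }
  if (!is.null(x$environment)) {
    cat("\n")
    print(x$environment)
  }
  cat("\nNiche limits\n")
  for (s in x$niche$species) {
    print(s$model)
    print(s$depth_limit)
  }
  if (!is.null(x$niche$ancova)) {
    print(x$niche$ancova)
    cat(sprintf("  slope magnitude ratio = %.2f\n", x$niche$slope_ratio))
  }
  cat("\n")
  print(x$fitness)
  invisible(x)
}
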