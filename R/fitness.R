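#' Build a 2x2 dead/alive contingency table from transplant outcomes
#'
#' Counts dead and alive colonies in two treatment groups of a reciprocal
#' transplant. Records with status `"discarded"` (e.g. colonies that detached
#' during the experiment) are excluded from all tallies first.
#'
#' @param outcomes data frame with columns `species`, `treatment`,
#'   `genotype_id`, `status` (`alive`/`dead`/`discarded`).
#' @param group_a,group_b treatment labels (e.g. `"S-D"`, `"S-S"`). Group A is
#'   the group hypothesised to suffer the higher mortality in the one-tailed
#'   test (see [fisher_one_tailed()]).
#' @return A `transplant_table` with group labels, dead/alive counts and
#'   mortality proportions.
#' @export
tally_outcomes <- function(outcomes, group_a, group_b) {
  stopifnot(is.data.frame(outcomes))
  for (col in c("treatment", "status")) {
    if (!col %in% names(outcomes)) {
      stop("outcomes are missing required column '", col, "'", call. = FALSE)
    }
  }
  bad <- setdiff(unique(outcomes$status), c("alive", "dead", "discarded"))
  if (length(bad) > 0L) {
    stop("unknown status value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  outcomes <- outcomes[outcomes$status != "discarded", , drop = FALSE]
  count <- function(trt) {
    sub <- outcomes[outcomes$treatment == trt, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no (non-discarded) records for treatment '", trt, "'",
           call. = FALSE)
    }
    c(dead = sum(sub$status == "dead"), alive = sum(sub$status == "alive"))
  }
  a <- count(group_a)
  b <- count(group_b)
  transplant_table(groups = c(group_a, group_b),
                   dead = c(a["dead"], b["dead"]),
                   alive = c(a["alive"], b["alive"]))
}

#' Construct a transplant contingency table directly from counts
#'
#' @param groups character vector of two group labels.
#' @param dead,alive non-negative integer vectors of length 2; each group's
#'   total must be positive.
#' @return A `transplant_table`.
#' @export
transplant_table <- function(groups, dead, alive) {
  dead <- as.integer(dead)
  alive <- as.integer(alive)
  stopifnot(length(groups) == 2L, length(dead) == 2L, length(alive) == 2L)
  if (any(dead < 0) || any(alive < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(dead + alive == 0L)) {
    stop("each group must contain at least one colony", call. = FALSE)
  }
  structure(list(
    groups = as.character(groups),
    dead = unname(dead),
    alive = unname(alive),
    n = unname(dead + alive),
    mortality = unname(dead / (dead + alive))
  ), class = "transplant_table")
}

#' @export
print.transplant_table <- function(x, ...) {
  for (i in 1:2) {
    cat(sprintf("  %s: %d dead / %d total (%.0f%% mortality)\n",
                x$groups[i], x$dead[i], x$n[i], 100 * x$mortality[i]))
  }
  invisible(x)
}

#' One-tailed Fisher exact test on a 2x2 dead/alive table
#'
#' Tests whether mortality in the first group exceeds that in the second,
#' conditioning on the table margins: the p-value is the exact hypergeometric
#' tail probability of observing at least as many deaths in group A as seen.
#' The tail probabilities are accumulated from log-factorial terms, which is
#' numerically safe for large counts.
#'
#' The one-tailed direction is fixed as "mortality in the first-listed group
#' exceeds the second", matching the hypothesis that transplantation away
#' from the native depth is disadvantageous; order the groups accordingly.
#'
#' @param table a [transplant_table()].
#' @return A `fisher_result` with the one-tailed `p_value`, the tail
#'   direction and the table.
#' @examples
#' fisher_one_tailed(transplant_table(c("S-D", "S-S"), dead = c(8, 0),
#'                                    alive = c(21, 27)))
#' @export
fisher_one_tailed <- function(table) {
  stopifnot(inherits(table, "transplant_table"))
  a <- table$dead[1L]
  n1 <- table$n[1L]
  n2 <- table$n[2L]
  d <- sum(table$dead)
  N <- n1 + n2
  k <- max(0L, d - n2):min(d, n1)
  log_terms <- lfactorial(n1) + lfactorial(n2) +
    lfactorial(d) + lfactorial(N - d) - lfactorial(N) -
    (lfactorial(k) + lfactorial(n1 - k) +
       lfactorial(d - k) + lfactorial(n2 - (d - k)))
  # normalise by the full support so the tail sum is exact when it spans it
  terms <- exp(log_terms - max(log_terms))
  p <- sum(terms[k >= a]) / sum(terms)
  structure(list(
    p_value = min(1, p),
    tail = paste0("mortality(", table$groups[1L], ") > mortality(",
                  table$groups[2L], ")"),
    table = table
  ), class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("One-tailed Fisher exact test:", x$tail, "\n")
  print(x$table)
  cat(sprintf("  p = %.3g\n", x$p_value))
  invisible(x)
}

#' Standardized fitness (survival) advantage between two species in a habitat
#'
#' The selection differential s is the difference in survival proportions
#' divided by their mean: s = (w1 - w2) / ((w1 + w2)/2). It is dimensionless,
#' antisymmetric under swapping the species, and bounded by |s| <= 2 (equality
#' only when one proportion is zero).
#'
#' @param w_species1,w_species2 survival proportions in \[0, 1\] (1 -
#'   mortality), not both zero.
#' @param species character vector of two species labels.
#' @param habitat optional habitat label (e.g. `"deep"`).
#' @return A `selection_estimate` with the signed `s` (first minus second),
#'   the favored species and both survival proportions.
#' @examples
#' selection_differential(0.96, 0.74) # s ~ 0.26: 26% advantage
#' @export
selection_differential <- function(w_species1, w_species2,
                                   species = c("species1", "species2"),
                                   habitat = NA_character_) {
  w <- c(w_species1, w_species2)
  if (anyNA(w) || any(w < 0) || any(w > 1)) {
    stop("survival proportions must lie in [0, 1]", call. = FALSE)
  }
  if (all(w == 0)) {
    stop("selection differential undefined when both survival proportions are 0",
         call. = FALSE)
  }
  s <- (w[1L] - w[2L]) / mean(w)
  fav <- if (s >= 0) 1L else 2L
  structure(list(
    habitat = habitat,
    species = as.character(species),
    favored = as.character(species)[fav],
    w_favored = w[fav],
    w_other = w[3L - fav],
    s = s
  ), class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf(
    "Selection%s: %s favored, survival %.2f vs %.2f, advantage s = %.0f%%\n",
    if (is.na(x$habitat)) "" else paste0(" in ", x$habitat, " habitat"),
    x$favored, x$w_favored, x$w_other, 100 * abs(x$s)))
  invisible(x)
}

# default pairwise contrasts of a shallow/deep reciprocal transplant:
# each non-native treatment vs the native treatment at each depth.
default_contrasts <- list(c("S-D", "S-S"), c("S-D", "D-D"),
                          c("D-S", "D-D"), c("D-S", "S-S"))

#' Full survivorship report for a reciprocal transplant experiment
#'
#' Summarises per-treatment sample sizes, deaths and mortality percentages;
#' runs the one-tailed Fisher contrasts (by default the four natural pairwise
#' comparisons of non-native vs native treatments); and computes the
#' per-habitat standardized selection differentials between the native and
#' transplanted species (deep habitat: D-D vs S-D; shallow habitat: S-S vs
#' D-S).
#'
#' @param outcomes data frame with columns `species`, `treatment`,
#'   `genotype_id`, `status`.
#' @param contrasts list of 2-element character vectors of treatment labels;
#'   in each, the first-listed group carries the "higher mortality" tail.
#' @return A `survivorship_report` with elements `treatments` (data frame),
#'   `contrasts` (list of Fisher results), `selection` (list of
#'   selection estimates) and `n_discarded`.
#' @export
survivorship_report <- function(outcomes, contrasts = default_contrasts) {
  stopifnot(is.data.frame(outcomes))
  for (col in c("species", "treatment", "genotype_id", "status")) {
    if (!col %in% names(outcomes)) {
      stop("outcomes are missing required column '", col, "'", call. = FALSE)
    }
  }
  n_discarded <- sum(outcomes$status == "discarded")
  kept <- outcomes[outcomes$status != "discarded", , drop = FALSE]
  trts <- unique(kept$treatment)
  if (length(trts) < 2L) {
    stop("outcomes must cover at least 2 treatments", call. = FALSE)
  }
  per <- do.call(rbind, lapply(trts, function(trt) {
    sub <- kept[kept$treatment == trt, , drop = FALSE]
    data.frame(treatment = trt,
               species = paste(sort(unique(sub$species)), collapse = "/"),
               n = nrow(sub),
               dead = sum(sub$status == "dead"),
               stringsAsFactors = FALSE)
  }))
  per$mortality <- per$dead / per$n
  contrasts <- Filter(function(p) all(p %in% trts), contrasts)
  fisher <- lapply(contrasts, function(p) {
    fisher_one_tailed(tally_outcomes(kept, p[1L], p[2L]))
  })
  names(fisher) <- vapply(contrasts, paste, "", collapse = " vs ")

  surv <- function(trt) 1 - per$mortality[per$treatment == trt]
  spp <- function(trt) per$species[per$treatment == trt]
  selection <- list()
  if (all(c("D-D", "S-D") %in% trts)) {
    selection$deep <- selection_differential(
      surv("D-D"), surv("S-D"), species = c(spp("D-D"), spp("S-D")),
      habitat = "deep")
  }
  if (all(c("S-S", "D-S") %in% trts)) {
    selection$shallow <- selection_differential(
      surv("S-S"), surv("D-S"), species = c(spp("S-S"), spp("D-S")),
      habitat = "shallow")
  }
  structure(list(
    treatments = per,
    contrasts = fisher,
    selection = selection,
    n_discarded = n_discarded
  ), class = "survivorship_report")
}

#' @export
print.survivorship_report <- function(x, ...) {
  cat("Survivorship after transplantation\n")
  if (x$n_discarded > 0L) {
    cat(sprintf("  (%d discarded record(s) excluded)\n", x$n_discarded))
  }
  for (i in seq_len(nrow(x$treatments))) {
    r <- x$treatments[i, ]
    cat(sprintf("  %s (%s): n = %d, %.0f%% mortality\n",
                r$treatment, r$species, r$n, 100 * r$mortality))
  }
  cat("Contrasts (one-tailed):\n")
  for (nm in names(x$contrasts)) {
    fr <- x$contrasts[[nm]]
    cat(sprintf("  %s: %.0f%% vs %.0f%% mortality (Fisher exact test: p = %.3g)\n",
                nm, 100 * fr$table$mortality[1L], 100 * fr$table$mortality[2L],
                fr$p_value))
  }
  for (sel in x$selection) print(sel)
  invisible(x)
}
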