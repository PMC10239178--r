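#' Effect decomposition from indirect and direct components
#'
#' Combines an indirect (mediation) effect and a direct effect into the
#' total effect and the proportion mediated. The total effect is the sum of
#' the direct and mediation effects; the proportion mediated divides the
#' mediation effect by the total effect and can be negative or exceed 100%
#' when the two components have opposite signs.
#'
#' @param acme Average causal mediation (indirect) effect.
#' @param ade Average direct effect.
#' @param prop_floor Smallest `|total|` for which the proportion mediated is
#'   reported; below it the proportion is flagged undefined (`NA`).
#' @return A one-row tibble: `acme`, `ade`, `total`, `prop_mediated` (%),
#'   `prop_defined`.
#' @examples
#' mediation_estimate(acme = 0.2776, ade = -0.1483)
#' @export
mediation_estimate <- function(acme, ade, prop_floor = 1e-8) {
  total <- acme + ade
  tibble::tibble(
    acme = acme, ade = ade, total = total,
    prop_mediated = proportion_mediated(acme, total, prop_floor),
    prop_defined = abs(total) >= prop_floor)
}

#' Proportion of a total effect transmitted through the mediator
#'
#' @param acme Mediation (indirect) effect.
#' @param total Total effect.
#' @param prop_floor Smallest `|total|` treated as nonzero.
#' @return Percentage `100 * acme / total`, or `NA` when `|total|` is below
#'   the floor (no exception is raised).
#' @examples
#' proportion_mediated(0.2776, 0.1293)  # 214.7%
#' @export
proportion_mediated <- function(acme, total, prop_floor = 1e-8) {
  ifelse(abs(total) < prop_floor, NA_real_, 100 * acme / total)
}

#' Product-of-coefficients mediation from a fitted model pair
#'
#' Reads the exposure-to-mediator coefficient from the mediator-model fit
#' and the mediator-to-outcome and direct-exposure coefficients from the
#' outcome-model fit: `acme = a * b`, `ade` is the exposure coefficient with
#' the mediator in the model, and `total = acme + ade`. Both fits must come
#' from the same analysis sample for the decomposition to be exact.
#'
#' @param mediator_fit,outcome_fit `eaa_ols` fits of the mediator and
#'   outcome models.
#' @param exposure Exposure term name shared by both fits.
#' @param mediator Mediator term name in the outcome fit.
#' @return A one-row tibble as from [mediation_estimate()].
#' @export
point_mediation <- function(mediator_fit, outcome_fit, exposure, mediator) {
  a <- coef_of(mediator_fit, exposure)
  ade <- coef_of(outcome_fit, exposure)
  b <- coef_of(outcome_fit, mediator)
  mediation_estimate(acme = a * b, ade = ade)
}

default_mediation_options <- function() {
  list(n_boot = 2000L, seed = 1L, subset = "all", standardize = TRUE,
       log_transform = NULL, outlier_multiplier = 3, stratified = FALSE,
       prop_floor = 1e-8, conf_level = 0.95, max_fail_frac = 0.05)
}

mediation_options <- function(...) {
  utils::modifyList(default_mediation_options(), list(...))
}

# Assemble the aligned mediator-/outcome-model design pair for one analysis
# cell: mediator extreme-outlier exclusion (fences estimated once on the
# full input cohort), subset rule, listwise deletion, outcome transform on
# the analysis sample.
prepare_pair <- function(cohort, exposure_set, mediator, outcome, opts) {
  mask <- flag_extreme_outliers(cohort[[mediator]],
                                multiplier = opts$outlier_multiplier)
  n_outliers <- sum(!mask, na.rm = TRUE)
  kept <- is.na(mask) | mask  # NA mediators fall to listwise deletion below
  sub0 <- cohort[kept, , drop = FALSE]

  m_spec <- model_spec(exposure_set, mediator = mediator,
                       subset = opts$subset, role = "mediator")
  dm <- build_design(sub0, m_spec, extra_required = outcome)
  sample <- sub0[dm$rows, , drop = FALSE]

  exp_terms <- exposure_terms_for(exposure_set)
  xm <- dm$x
  n_lead <- 1 + length(exp_terms)  # intercept + exposure block
  xy <- cbind(xm[, seq_len(n_lead), drop = FALSE],
              as.numeric(sample[[mediator]]),
              xm[, -seq_len(n_lead), drop = FALSE])
  colnames(xy) <- c(colnames(xm)[seq_len(n_lead)], mediator,
                    colnames(xm)[-seq_len(n_lead)])

  log_transform <- opts$log_transform %||% (outcome %in% log_scale_outcomes())
  y <- transform_outcome(as.numeric(sample[[outcome]]),
                         log_transform = log_transform,
                         standardize = opts$standardize)
  list(xm = xm, m = dm$y, xy = xy, y = y, n = dm$n,
       exp_terms = exp_terms, mediator = mediator, outcome = outcome,
       n_outliers = n_outliers, stratify = sample$smoking_status)
}

# Case-resampling bootstrap over an aligned design pair. Returns per
# exposure term the acme/ade/total replicate matrices and the point fits.
mediate_core <- function(pair, opts) {
  xm <- pair$xm; xy <- pair$xy
  fm <- fit_ols(xm, pair$m)
  fy <- fit_ols(xy, pair$y)
  exp_terms <- pair$exp_terms
  im <- match(exp_terms, colnames(xm))
  iy <- match(exp_terms, colnames(xy))
  imed <- match(pair$mediator, colnames(xy))
  n <- pair$n; k <- length(exp_terms)
  n_boot <- as.integer(opts$n_boot)
  if (n_boot < 100)
    abort_eaa("`n_boot` must be at least 100.", "config_error")

  acme <- matrix(NA_real_, n_boot, k)
  ade <- matrix(NA_real_, n_boot, k)
  pm <- ncol(xm); py <- ncol(xy)
  strata <- if (isTRUE(opts$stratified)) split(seq_len(n), pair$stratify)
  withr::with_seed(opts$seed, {
    for (b in seq_len(n_boot)) {
      idx <- if (is.null(strata)) sample.int(n, n, replace = TRUE)
             else unlist(lapply(strata, function(s)
               s[sample.int(length(s), length(s), replace = TRUE)]),
               use.names = FALSE)
      bm <- stats::lm.fit(xm[idx, , drop = FALSE], pair$m[idx])
      if (bm$rank < pm) next
      by <- stats::lm.fit(xy[idx, , drop = FALSE], pair$y[idx])
      if (by$rank < py) next
      acme[b, ] <- bm$coefficients[im] * by$coefficients[imed]
      ade[b, ] <- by$coefficients[iy]
    }
  })
  ok <- !is.na(acme[, 1])
  n_failed <- sum(!ok)
  if (n_failed > opts$max_fail_frac * n_boot)
    abort_eaa(sprintf("%d of %d bootstrap refits failed (rank deficiency).",
                      n_failed, n_boot), "instability_error")
  list(fm = fm, fy = fy, acme = acme[ok, , drop = FALSE],
       ade = ade[ok, , drop = FALSE], n_failed = n_failed,
       n_boot = n_boot, exp_terms = exp_terms)
}

boot_pvalue <- function(draws, n_boot) {
  p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
  min(max(p, 1 / n_boot), 1)
}

mediation_result_for <- function(core, pair, exposure, opts) {
  j <- match(exposure, core$exp_terms)
  point <- point_mediation(core$fm, core$fy, exposure, pair$mediator)
  probs <- c((1 - opts$conf_level) / 2, 1 - (1 - opts$conf_level) / 2)
  draws <- list(acme = core$acme[, j], ade = core$ade[, j],
                total = core$acme[, j] + core$ade[, j])
  est <- c(acme = point$acme, ade = point$ade, total = point$total)
  ci <- purrr::map(draws, ~ stats::quantile(.x, probs, names = FALSE))
  estimates <- tibble::tibble(
    effect = names(draws),
    estimate = unname(est),
    conf.low = unname(purrr::map_dbl(ci, 1)),
    conf.high = unname(purrr::map_dbl(ci, 2)),
    p.value = unname(purrr::map_dbl(draws, boot_pvalue, n_boot = core$n_boot)))
  structure(list(
    exposure = exposure, mediator = pair$mediator, outcome = pair$outcome,
    estimates = estimates,
    prop_mediated = point$prop_mediated, prop_defined = point$prop_defined,
    n_analysis = pair$n, n_boot = core$n_boot, seed = opts$seed,
    n_failed = core$n_failed, n_outliers_removed = pair$n_outliers,
    mediator_fit = core$fm, outcome_fit = core$fy),
    class = "eaa_mediation")
}

#' Bootstrap mediation analysis for one exposure-mediator-outcome cell
#'
#' Runs the full single-cell pipeline: mediator extreme-outlier exclusion
#' (3xIQR fences estimated on the input cohort), subset rule (cessation
#' analyses use former smokers only, with pack-years added to the adjustment
#' set), listwise deletion, outcome log/z-score transform on the analysis
#' sample, joint mediator-/outcome-model OLS fits, and a nonparametric
#' case-resampling bootstrap: rows of the analysis sample are resampled with
#' replacement, both models are refit per replicate, and the indirect
#' (ACME), direct (ADE) and total effects are recomputed. 95% confidence
#' intervals are the 2.5/97.5 replicate percentiles; two-sided p-values are
#' `2 * min(tail fractions)`, floored at `1 / n_boot`. Replicates whose
#' refit is rank deficient are dropped and counted.
#'
#' Preprocessing (fences, z-scores) is computed once on the analysis sample
#' and treated as fixed under resampling; point estimates do not depend on
#' the bootstrap seed.
#'
#' @param cohort A cohort tibble.
#' @param exposure One of `"fs"`, `"cs"`, `"fpy"`, `"cpy"`, `"ysc"`.
#' @param mediator,outcome Mediator / outcome column names.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Bootstrap RNG seed.
#' @param ... Further options: `subset` (`"all"`/`"males"`), `standardize`,
#'   `log_transform` (default: log for `fg`/`hba1c`), `outlier_multiplier`,
#'   `stratified` (stratify resampling by smoking group; off by default),
#'   `conf_level`, `prop_floor`.
#' @return An `eaa_mediation` object; see [tidy.eaa_mediation()].
#' @examples
#' cohort <- generate_cohort(sim_truth(n = 600, seed = 3))
#' fit <- run_mediation_analysis(cohort, "cs", "grim_eaa", "fg",
#'                               n_boot = 200, seed = 1)
#' tidy(fit)
#' @export
run_mediation_analysis <- function(cohort, exposure, mediator, outcome,
                                   n_boot = 2000, seed = 1, ...) {
  opts <- mediation_options(n_boot = n_boot, seed = seed, ...)
  exposure_set <- exposure_set_for(exposure)
  pair <- prepare_pair(cohort, exposure_set, mediator, outcome, opts)
  core <- mediate_core(pair, opts)
  mediation_result_for(core, pair, exposure, opts)
}

#' @rdname run_mediation_analysis
#' @details `bootstrap_mediation()` is the lower-level surface: it takes the
#'   cohort as-is (no outlier exclusion or outcome transform) and bootstraps
#'   the model pair for one exposure term.
#' @export
bootstrap_mediation <- function(cohort, exposure, mediator, outcome,
                                n_boot = 2000, seed = 1, ...) {
  run_mediation_analysis(cohort, exposure, mediator, outcome,
                         n_boot = n_boot, seed = seed,
                         outlier_multiplier = Inf, standardize = FALSE,
                         log_transform = FALSE, ...)
}

#' @export
print.eaa_mediation <- function(x, ...) {
  cat(sprintf("<eaa_mediation> %s -> %s -> %s  (n = %d, n_boot = %d)\n",
              x$exposure, x$mediator, x$outcome, x$n_analysis, x$n_boot))
  print(x$estimates)
  if (isTRUE(x$prop_defined))
    cat(sprintf("proportion mediated: %.1f%%\n", x$prop_mediated))
  else cat("proportion mediated: undefined (|total| below floor)\n")
  invisible(x)
}

#' Tidy a mediation result
#' @param x An `eaa_mediation` object.
#' @param ... Unused.
#' @return A tibble with rows `acme`, `ade`, `total` and columns `estimate`,
#'   `conf.low`, `conf.high`, `p.value`, plus identifying columns.
#' @export
tidy.eaa_mediation <- function(x, ...) {
  dplyr::mutate(x$estimates, exposure = x$exposure, mediator = x$mediator,
                outcome = x$outcome, .before = 1)
}

#' One-row summary of a mediation result
#' @param x An `eaa_mediation` object.
#' @param ... Unused.
#' @return A one-row tibble with the point decomposition, proportion
#'   mediated, analysis n and bootstrap bookkeeping.
#' @export
glance.eaa_mediation <- function(x, ...) {
  est <- stats::setNames(x$estimates$estimate, x$estimates$effect)
  tibble::tibble(acme = est[["acme"]], ade = est[["ade"]],
                 total = est[["total"]],
                 acme_p = x$estimates$p.value[x$estimates$effect == "acme"],
                 prop_mediated = x$prop_mediated,
                 prop_defined = x$prop_defined,
                 n_analysis = x$n_analysis, n_boot = x$n_boot,
                 n_failed = x$n_failed,
                 n_outliers_removed = x$n_outliers_removed)
}
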