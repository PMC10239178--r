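#' Specify one mediator- or outcome-model
#'
#' A model spec names the exposure parameterisation, the mediator and
#' (for outcome models) the outcome, the adjustment set, and the analysis
#' subset. Three exposure sets mirror the paired model families:
#' * `"status"` - dummy-coded former (`fs`) and current (`cs`) smoking,
#'   non-smokers as reference;
#' * `"packyears"` - former (`fpy`) and current (`cpy`) smokers' pack-years,
#'   non-smokers coded 0 in both;
#' * `"cessation"` - years since cessation (`ysc`), fit in former smokers
#'   only with pack-years added to the adjustment set.
#'
#' @param exposure_set `"status"`, `"packyears"` or `"cessation"`.
#' @param mediator Mediator column name, or `NULL`.
#' @param outcome Outcome column name (required when `role = "outcome"`).
#' @param covariates Adjustment variables; defaults to age, sex, BMI,
#'   drinking, regular exercise, education and five cell-type proportions.
#' @param subset `"all"` or `"males"` (male-only sensitivity analyses).
#' @param role `"mediator"` (response is the mediator) or `"outcome"`
#'   (response is the outcome; the mediator enters the design).
#' @return A `model_spec` list.
#' @export
model_spec <- function(exposure_set = c("status", "packyears", "cessation"),
                       mediator = NULL, outcome = NULL,
                       covariates = default_covariates(),
                       subset = c("all", "males"),
                       role = c("mediator", "outcome")) {
  exposure_set <- arg_match(exposure_set)
  subset <- arg_match(subset)
  role <- arg_match(role)
  if (role == "outcome" && (is.null(mediator) || is.null(outcome)))
    abort_eaa("Outcome-model specs must name both a mediator and an outcome.",
              "spec_error")
  if (role == "mediator" && is.null(mediator))
    abort_eaa("Mediator-model specs must name a mediator.", "spec_error")
  if (exposure_set == "cessation" && !"pack_years" %in% covariates)
    covariates <- c(covariates, "pack_years")  # FPY adjustment, cessation models
  structure(list(exposure_set = exposure_set, mediator = mediator,
                 outcome = outcome, covariates = covariates, subset = subset,
                 role = role),
            class = "model_spec")
}

exposure_terms_for <- function(exposure_set) {
  switch(exposure_set,
         status = c("fs", "cs"),
         packyears = c("fpy", "cpy"),
         cessation = "ysc")
}

exposure_set_for <- function(exposure) {
  switch(exposure,
         fs = , cs = "status",
         fpy = , cpy = "packyears",
         ysc = "cessation",
         abort_eaa(paste0("Unknown exposure term `", exposure, "`."), "lookup_error"))
}

#' Build the design matrix and response for a model spec
#'
#' Applies the subset rule (males only; former smokers only for cessation
#' models), performs listwise deletion over every required variable, and
#' assembles an intercept-first numeric design with dummy-coded smoking
#' status (non-smokers as reference) or zero-filled pack-year terms.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param spec A [model_spec()].
#' @param extra_required Further columns whose missingness should also drop
#'   rows (used to align a mediator-/outcome-model pair on one sample).
#' @return A list with `x` (design matrix), `y` (response), `n`, and `rows`
#'   (logical row mask into `cohort`).
#' @export
build_design <- function(cohort, spec, extra_required = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  keep <- rep(TRUE, nrow(cohort))
  if (spec$subset == "males") keep <- keep & cohort$sex == "male"
  if (spec$exposure_set == "cessation")
    keep <- keep & cohort$smoking_status == "former"

  exp_terms <- exposure_terms_for(spec$exposure_set)
  response_var <- if (spec$role == "outcome") spec$outcome else spec$mediator
  required <- unique(c(response_var, spec$covariates,
                       if (spec$role == "outcome") spec$mediator,
                       if (spec$exposure_set == "cessation") "years_since_cessation",
                       extra_required))
  required <- intersect(required, names(cohort))
  complete <- !Reduce(`|`, lapply(cohort[required], is.na))
  keep <- keep & complete

  sub <- cohort[keep, , drop = FALSE]
  if (nrow(sub) == 0)
    abort_eaa("No rows remain after subsetting and listwise deletion.",
              "insufficient_data")
  terms <- structural_terms(sub)
  x <- cbind(`(Intercept)` = 1, terms$exposure[, exp_terms, drop = FALSE])
  if (spec$role == "outcome")
    x <- cbind(x, as.numeric(sub[[spec$mediator]]))
  covs <- spec$covariates
  cov_cols <- lapply(covs, function(v) {
    if (v %in% colnames(terms$covariates)) terms$covariates[, v]
    else as.numeric(sub[[v]])
  })
  x <- cbind(x, do.call(cbind, cov_cols))
  colnames(x) <- c("(Intercept)", exp_terms,
                   if (spec$role == "outcome") spec$mediator, covs)
  y <- as.numeric(sub[[response_var]])
  if (nrow(x) <= ncol(x))
    abort_eaa("Fewer rows than design columns after filtering.", "insufficient_data")
  list(x = x, y = y, n = nrow(x), rows = keep)
}

#' Ordinary least squares with classical standard errors
#'
#' Fits by QR decomposition (via [stats::lm.fit()]) and reports coefficient
#' estimates, classical homoskedastic standard errors, t statistics and
#' two-sided p-values. The bootstrap, not these p-values, is the inferential
#' workhorse of the mediation engine; classical SEs serve the
#' exposure-mediator screen table.
#'
#' @param x Numeric design matrix with named columns (include an intercept
#'   column explicitly).
#' @param y Numeric response.
#' @return An `eaa_ols` object; see [tidy.eaa_ols()] and [glance.eaa_ols()].
#' @examples
#' x <- cbind(`(Intercept)` = 1, x = 1:5)
#' fit_ols(x, 2 * (1:5) + 1)
#' @export
fit_ols <- function(x, y) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p)
    abort_eaa("Need more observations than design columns.", "insufficient_data")
  if (anyNA(x) || anyNA(y))
    abort_eaa("Design and response must be complete (apply listwise deletion first).",
              "missing_data")
  fit <- stats::lm.fit(x, y)
  if (fit$rank < p) {
    aliased <- colnames(x)[fit$qr$pivot[(fit$rank + 1):p]]
    abort_eaa(paste0("Rank-deficient design; collinear column(s): ",
                     paste(aliased, collapse = ", "), "."), "collinearity_error")
  }
  rss <- sum(fit$residuals^2)
  df <- n - p
  sigma2 <- rss / df
  r_piv <- qr.R(fit$qr)
  xtx_inv_piv <- chol2inv(r_piv)
  piv <- fit$qr$pivot
  xtx_inv <- matrix(NA_real_, p, p)
  xtx_inv[piv, piv] <- xtx_inv_piv
  se <- sqrt(sigma2 * diag(xtx_inv))
  est <- fit$coefficients
  tval <- est / se
  has_int <- "(Intercept)" %in% colnames(x)
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  structure(list(
    coefficients = tibble::tibble(
      term = colnames(x), estimate = unname(est), std.error = unname(se),
      statistic = unname(tval),
      p.value = 2 * stats::pt(abs(unname(tval)), df, lower.tail = FALSE)),
    residuals = unname(fit$residuals),
    fitted = unname(fit$fitted.values),
    n = n, df.residual = df, r.squared = 1 - rss / tss,
    sigma = sqrt(sigma2), rank = fit$rank, terms = colnames(x)),
    class = "eaa_ols")
}

coef_of <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i))
    abort_eaa(paste0("Term `", term, "` not present in the fit."), "spec_error")
  fit$coefficients$estimate[i]
}

#' @export
print.eaa_ols <- function(x, ...) {
  cat("<eaa_ols> n =", x$n, " R^2 =", signif(x$r.squared, 4), "\n")
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Tidy an OLS fit
#' @param x An `eaa_ols` object.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.eaa_ols <- function(x, ...) x$coefficients

#' One-row model summary of an OLS fit
#' @param x An `eaa_ols` object.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `sigma`, `nobs`, `df.residual`.
#' @export
glance.eaa_ols <- function(x, ...) {
  tibble::tibble(r.squared = x$r.squared, sigma = x$sigma, nobs = x$n,
                 df.residual = x$df.residual)
}

#' Epigenetic age acceleration as age-residualised epigenetic age
#'
#' Regresses an epigenetic age estimate on chronological age (simple linear
#' regression with intercept) and returns the residuals. By construction the
#' residuals are uncorrelated with chronological age; positive values mean
#' faster biological aging than chronological age predicts.
#'
#' @param epigenetic_age,chron_age Numeric vectors of equal length; rows
#'   missing either value get `NA` residuals.
#' @return Numeric vector of residuals (years).
#' @export
residualize_on_age <- function(epigenetic_age, chron_age) {
  if (length(epigenetic_age) != length(chron_age))
    abort_eaa("Epigenetic and chronological age must have equal length.", "spec_error")
  ok <- !is.na(epigenetic_age) & !is.na(chron_age)
  a <- chron_age[ok]
  if (length(a) < 3 || stats::var(a) == 0)
    abort_eaa("Chronological age is constant or nearly empty; cannot residualise.",
              "degenerate_regressor")
  e <- epigenetic_age[ok]
  slope <- stats::cov(e, a) / stats::var(a)
  intercept <- mean(e) - slope * mean(a)
  out <- rep(NA_real_, length(epigenetic_age))
  out[ok] <- e - (intercept + slope * a)
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing design
#' column `j` on all remaining columns (intercept included). Values above 5
#' are flagged as a multicollinearity threat.
#'
#' @param x Numeric design matrix with an intercept column named
#'   `"(Intercept)"` (added if absent).
#' @param threshold Flagging threshold (default 5).
#' @return A tibble: `term`, `vif`, `flagged`.
#' @export
compute_vif <- function(x, threshold = 5) {
  x <- as.matrix(x)
  if (!"(Intercept)" %in% colnames(x))
    x <- cbind(`(Intercept)` = 1, x)
  terms <- setdiff(colnames(x), "(Intercept)")
  if (length(terms) < 2)
    abort_eaa("Need at least 2 non-intercept columns for VIF.", "spec_error")
  vif <- vapply(terms, function(j) {
    others <- x[, setdiff(colnames(x), j), drop = FALSE]
    xj <- x[, j]
    fit <- stats::lm.fit(others, xj)
    r2 <- 1 - sum(fit$residuals^2) / sum((xj - mean(xj))^2)
    if (1 - r2 < 1e-12)
      abort_eaa(paste0("Column `", j, "` is perfectly collinear with the others."),
                "collinearity_error")
    1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(term = terms, vif = unname(vif), flagged = unname(vif) > threshold)
}
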