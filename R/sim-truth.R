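#' Ground-truth parameters for the synthetic cohort generator
#'
#' `sim_truth()` assembles the full parameter set of the synthetic-cohort
#' generator: smoking-group prevalences, per-group covariate distributions,
#' the linear structural equations for the seven DNA-methylation mediators
#' and four health outcomes, residual noise levels, and the joint
#' lung-function missingness rate. Defaults emulate a population-based
#' East-Asian biobank subsample of 2474 adults aged 30-70: group prevalences
#' 75.95% / 12.61% / 11.44% (non / former / current smokers), former smokers'
#' pack-years 12.9 +/- 14.1, current smokers' 20.8 +/- 19.9, years since
#' cessation 12.9 +/- 10.0, and exposure-to-mediator coefficients at the
#' scale observed in that cohort (e.g. current smoking raises GrimAge
#' acceleration by 5.650 years).
#'
#' Pack-years and years since cessation are drawn from gamma distributions
#' whose shape/rate are solved from the configured mean and SD, so both
#' printed moments are reproduced exactly while respecting nonnegativity.
#' Six blood cell fractions are drawn Dirichlet (five are emitted; the
#' granulocyte remainder is implicit). Fasting glucose and HbA1c are
#' generated linearly on the log scale and exponentiated, so a natural-log
#' transform exactly linearises the outcome model.
#'
#' @param n Number of participants.
#' @param prevalence Named numeric triple `c(non, former, current)` summing
#'   to 1.
#' @param age_range Uniform draw bounds for chronological age, in years.
#' @param sex_male_prob Probability of male sex per smoking group
#'   (non, former, current).
#' @param packyears List with `former` and `current` elements, each
#'   `c(mean, sd)` of pack-years within the group.
#' @param ysc `c(mean, sd)` of former smokers' years since cessation.
#' @param bmi,education Per-group `mean`/`sd` matrices (rows non/former/
#'   current); education is rounded to an integer and clamped to 1-7.
#' @param drinking_prob,exercise_prob Per-group Bernoulli probabilities.
#' @param cell_alpha Dirichlet concentration for six blood cell fractions
#'   (B, CD4T, CD8T, mono, NK, granulocyte); five are emitted.
#' @param mediator_model Named list (one element per mediator) of lists with
#'   `intercept`, `exposure` (named coefficients on fs, cs, fpy, cpy, ysc),
#'   `covariates` (named coefficients), and residual `sd`.
#' @param outcome_model Named list (one element per outcome) of lists with
#'   `intercept`, `exposure`, `mediators` (named coefficients on the seven
#'   mediators), `covariates`, residual `sd`, and `log` (generate on log
#'   scale then exponentiate).
#' @param lung_missing_rate Probability that FEV1 and FVC are jointly
#'   missing (no lung-function examination).
#' @param seed Integer RNG seed recorded with the truth and used by
#'   [generate_cohort()].
#'
#' @return A `sim_truth` object (a validated list).
#' @seealso [generate_cohort()], [truth_acme()]
#' @examples
#' truth <- sim_truth(n = 500, seed = 1)
#' cohort <- generate_cohort(truth)
#' @export
sim_truth <- function(n = 2474,
                      prevalence = c(non = 0.7595, former = 0.1261, current = 0.1144),
                      age_range = c(30, 70),
                      sex_male_prob = c(non = 0.392, former = 0.872, current = 0.830),
                      packyears = list(former = c(mean = 12.9, sd = 14.1),
                                       current = c(mean = 20.8, sd = 19.9)),
                      ysc = c(mean = 12.9, sd = 10.0),
                      bmi = default_group_dist(c(24.1, 25.3, 25.4), c(3.7, 3.2, 3.7)),
                      education = default_group_dist(c(5.6, 5.6, 5.4), c(0.9, 0.9, 0.8)),
                      drinking_prob = c(non = 0.038, former = 0.096, current = 0.244),
                      exercise_prob = c(non = 0.436, former = 0.571, current = 0.336),
                      cell_alpha = c(B = 7, CD4T = 20, CD8T = 12, mono = 9, NK = 6, gran = 66),
                      mediator_model = default_mediator_model(),
                      outcome_model = default_outcome_model(),
                      lung_missing_rate = 0.363,
                      seed = 1L) {
  truth <- structure(
    list(n = as.integer(n), prevalence = prevalence, age_range = age_range,
         sex_male_prob = sex_male_prob, packyears = packyears, ysc = ysc,
         bmi = bmi, education = education, drinking_prob = drinking_prob,
         exercise_prob = exercise_prob, cell_alpha = cell_alpha,
         mediator_model = mediator_model, outcome_model = outcome_model,
         lung_missing_rate = lung_missing_rate, seed = as.integer(seed)),
    class = "sim_truth")
  validate_sim_truth(truth)
}

default_group_dist <- function(means, sds) {
  matrix(c(means, sds), ncol = 2,
         dimnames = list(c("non", "former", "current"), c("mean", "sd")))
}

zero_exposure <- function() {
  c(fs = 0, cs = 0, fpy = 0, cpy = 0, ysc = 0)
}

zero_covariates <- function() {
  stats::setNames(numeric(length(default_covariates())), default_covariates())
}

covariate_coefs <- function(...) {
  out <- zero_covariates()
  dots <- c(...)
  out[names(dots)] <- dots
  out
}

# Exposure coefficients follow the observed exposure-mediator regression
# scale of the reference cohort; residual SDs are back-calculated from the
# reported coefficient standard errors at n = 2474.
default_mediator_model <- function() {
  exposure <- function(fs, cs, fpy, cpy, ysc) c(fs = fs, cs = cs, fpy = fpy, cpy = cpy, ysc = ysc)
  list(
    hannum_eaa = list(
      intercept = 0,
      exposure = exposure(0.426, 1.205, 0.021, 0.027, -0.029),
      covariates = covariate_coefs(sex_male = 0.3, bmi = 0.02), sd = 3.6),
    ieaa = list(
      intercept = 0,
      exposure = exposure(0.214, 0.367, 0.021, 0.003, -0.038),
      covariates = covariate_coefs(sex_male = 0.2), sd = 4.1),
    pheno_eaa = list(
      intercept = 0,
      exposure = exposure(1.011, 1.930, 0.051, 0.043, -0.091),
      covariates = covariate_coefs(sex_male = 0.4, bmi = 0.05), sd = 4.8),
    grim_eaa = list(
      intercept = -1.5,
      exposure = exposure(1.446, 5.650, 0.087, 0.174, -0.108),
      covariates = covariate_coefs(sex_male = 0.8, bmi = 0.06, education = -0.1),
      sd = 3.2),
    dnam_packyears = list(
      intercept = -1.0,
      exposure = exposure(4.705, 14.916, 0.255, 0.567, -0.313),
      covariates = covariate_coefs(age = 0.06, sex_male = 1.0), sd = 6.1),
    dnam_pai1 = list(
      intercept = 10000,
      exposure = exposure(263.389, 1002.309, 12.694, 28.240, -16.028),
      covariates = covariate_coefs(age = 100, sex_male = 800, bmi = 200),
      sd = 2200),
    dunedin_pace = list(
      intercept = 0.75,
      exposure = exposure(0.019, 0.084, 0.001, 0.002, -0.001),
      covariates = covariate_coefs(age = 0.004, bmi = 0.002), sd = 0.095)
  )
}

zero_mediators <- function() {
  stats::setNames(numeric(length(mediator_names())), mediator_names())
}

mediator_coefs <- function(...) {
  out <- zero_mediators()
  dots <- c(...)
  out[names(dots)] <- dots
  out
}

# Mediator-to-outcome effects are free parameters of the generator (the
# reference cohort's values are not identifiable from printed tables);
# defaults are set so second-generation aging markers carry indirect effects
# toward higher glycaemia and lower lung volumes.
default_outcome_model <- function() {
  list(
    fg = list(
      intercept = 3.83,
      exposure = c(fs = 0.005, cs = 0.010, fpy = 2e-4, cpy = 5e-4, ysc = 0),
      mediators = mediator_coefs(pheno_eaa = 0.003, grim_eaa = 0.007,
                                 dnam_packyears = 0.003, dnam_pai1 = 1e-5,
                                 dunedin_pace = 0.20),
      covariates = covariate_coefs(age = 0.002, sex_male = 0.03, bmi = 0.008),
      sd = 0.12, log = TRUE),
    hba1c = list(
      intercept = 1.18,
      exposure = c(fs = 0.002, cs = 0.004, fpy = 1e-4, cpy = 2e-4, ysc = 0),
      mediators = mediator_coefs(pheno_eaa = 0.0035, grim_eaa = 0.008,
                                 dnam_packyears = 0.0035, dnam_pai1 = 8e-6,
                                 dunedin_pace = 0.22),
      covariates = covariate_coefs(age = 0.0015, sex_male = 0.005, bmi = 0.004),
      sd = 0.09, log = TRUE),
    fev1 = list(
      intercept = 3.9,
      exposure = c(fs = -0.02, cs = -0.05, fpy = -0.001, cpy = -0.002, ysc = 0.002),
      mediators = mediator_coefs(pheno_eaa = -0.010, grim_eaa = -0.012,
                                 dnam_packyears = -0.005, dnam_pai1 = -6e-6,
                                 dunedin_pace = -0.25),
      covariates = covariate_coefs(age = -0.025, sex_male = 0.6, bmi = -0.01),
      sd = 0.45, log = FALSE),
    fvc = list(
      intercept = 4.9,
      exposure = c(fs = -0.015, cs = -0.04, fpy = -8e-4, cpy = -0.001, ysc = 0.002),
      mediators = mediator_coefs(pheno_eaa = -0.008, grim_eaa = -0.015,
                                 dnam_packyears = -0.004, dnam_pai1 = -8e-6,
                                 dunedin_pace = -0.20),
      covariates = covariate_coefs(age = -0.028, sex_male = 0.7, bmi = -0.012),
      sd = 0.5, log = FALSE)
  )
}

validate_sim_truth <- function(truth) {
  if (!inherits(truth, "sim_truth"))
    abort_eaa("`truth` must be a sim_truth object.", "config_error")
  if (length(truth$n) != 1L || is.na(truth$n) || truth$n < 1L)
    abort_eaa("`n` must be a positive integer.", "config_error")
  prev <- truth$prevalence
  if (length(prev) != 3L || any(prev < 0) || abs(sum(prev) - 1) > 1e-12)
    abort_eaa("`prevalence` must be three nonnegative values summing to 1 (field: prevalence).",
              "config_error")
  if (any(truth$sex_male_prob < 0 | truth$sex_male_prob > 1))
    abort_eaa("`sex_male_prob` entries must lie in [0, 1] (field: sex_male_prob).", "config_error")
  for (g in c("former", "current")) {
    py <- truth$packyears[[g]]
    if (py[["sd"]] < 0)
      abort_eaa(paste0("Negative SD in packyears$", g, " (field: packyears)."), "config_error")
  }
  if (truth$ysc[["sd"]] < 0)
    abort_eaa("Negative SD in `ysc` (field: ysc).", "config_error")
  if (any(truth$bmi[, "sd"] < 0) || any(truth$education[, "sd"] < 0))
    abort_eaa("Group SDs must be nonnegative (field: bmi/education).", "config_error")
  if (any(truth$cell_alpha <= 0))
    abort_eaa("`cell_alpha` entries must be positive (field: cell_alpha).", "config_error")
  for (m in mediator_names()) {
    mm <- truth$mediator_model[[m]]
    if (is.null(mm))
      abort_eaa(paste0("mediator_model is missing `", m, "`."), "config_error")
    if (mm$sd < 0)
      abort_eaa(paste0("Negative residual SD for mediator `", m, "`."), "config_error")
  }
  for (y in outcome_names()) {
    om <- truth$outcome_model[[y]]
    if (is.null(om))
      abort_eaa(paste0("outcome_model is missing `", y, "`."), "config_error")
    if (om$sd < 0)
      abort_eaa(paste0("Negative residual SD for outcome `", y, "`."), "config_error")
  }
  if (truth$lung_missing_rate < 0 || truth$lung_missing_rate > 1)
    abort_eaa("`lung_missing_rate` must lie in [0, 1] (field: lung_missing_rate).", "config_error")
  truth
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat("  n:", x$n, " seed:", x$seed, "\n")
  cat(sprintf("  prevalence: non %.4f / former %.4f / current %.4f\n",
              x$prevalence[[1]], x$prevalence[[2]], x$prevalence[[3]]))
  cat("  mediators:", paste(names(x$mediator_model), collapse = ", "), "\n")
  cat("  outcomes: ", paste(names(x$outcome_model), collapse = ", "), "\n")
  cat(sprintf("  lung missingness: %.3f\n", x$lung_missing_rate))
  invisible(x)
}

#' Ground-truth indirect effect implied by a simulation truth
#'
#' Under the generator's linear structural equations the average causal
#' mediation effect (ACME) of one exposure term on one outcome through one
#' mediator is the product of the configured exposure-to-mediator and
#' mediator-to-outcome coefficients. For `fg`/`hba1c` the value is on the
#' natural-log outcome scale (the scale on which the generator is linear).
#'
#' @param truth A [sim_truth()] object.
#' @param exposure One of `r paste0('"', exposure_names(), '"', collapse = ", ")`.
#' @param mediator,outcome Mediator / outcome column names.
#' @return A single numeric: the true ACME in (possibly log-) outcome units
#'   per unit of exposure.
#' @examples
#' truth_acme(sim_truth(), "cs", "grim_eaa", "fg")
#' @export
truth_acme <- function(truth, exposure, mediator, outcome) {
  validate_sim_truth(truth)
  if (!exposure %in% exposure_names())
    abort_eaa(paste0("Unknown exposure term `", exposure, "`."), "lookup_error")
  if (!mediator %in% names(truth$mediator_model))
    abort_eaa(paste0("Unknown mediator `", mediator, "`."), "lookup_error")
  if (!outcome %in% names(truth$outcome_model))
    abort_eaa(paste0("Unknown outcome `", outcome, "`."), "lookup_error")
  a <- truth$mediator_model[[mediator]]$exposure[[exposure]]
  b <- truth$outcome_model[[outcome]]$mediators[[mediator]]
  unname(a * b)
}
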