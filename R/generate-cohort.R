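#' Generate a synthetic cohort from a simulation truth
#'
#' Draws a per-participant cohort table with the statistical structure the
#' mediation pipeline assumes: smoking group membership from the configured
#' prevalences; group-conditional covariates (age, sex, BMI, drinking,
#' regular exercise, education, five blood cell-type fractions); pack-years
#' and years since cessation from moment-matched gamma distributions
#' (nonnegative, reproducing the configured mean/SD); the seven
#' DNA-methylation mediators from their linear structural equations plus
#' Gaussian noise; and the four outcomes from theirs, with fasting glucose
#' and HbA1c generated on the log scale and exponentiated. FEV1 and FVC are
#' jointly missing with probability `truth$lung_missing_rate`, mimicking
#' participants who skipped the lung-function examination.
#'
#' Identical `truth` (including its seed) yields an identical table.
#' Covariates are drawn independently within smoking group, so all
#' confounding runs through group membership - the structure the model's
#' adjustment set is designed for.
#'
#' @param truth A [sim_truth()] object.
#' @return A tibble with one row per participant; see the package README for
#'   the column dictionary. Missing lung-function values are `NA`.
#' @examples
#' cohort <- generate_cohort(sim_truth(n = 200, seed = 42))
#' dplyr::count(cohort, smoking_status)
#' @export
generate_cohort <- function(truth) {
  validate_sim_truth(truth)
  withr::with_seed(truth$seed, generate_cohort_impl(truth))
}

# gamma draw matching a target mean/sd exactly; degenerate cases collapse
# to the point mass at `mean`
rgamma_moments <- function(n, mean, sd) {
  if (mean <= 0 || sd == 0) return(rep(max(mean, 0), n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = mean / sd^2)
}

rnorm_int_clamped <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, round(stats::rnorm(n, mean, sd))))
}

generate_cohort_impl <- function(truth) {
  n <- truth$n
  groups <- c("non", "former", "current")
  status <- factor(sample(groups, n, replace = TRUE, prob = truth$prevalence),
                   levels = groups)
  g <- as.integer(status)

  age <- stats::runif(n, truth$age_range[1], truth$age_range[2])
  sex_male <- stats::rbinom(n, 1, truth$sex_male_prob[g])
  bmi <- stats::rnorm(n, truth$bmi[g, "mean"], truth$bmi[g, "sd"])
  bmi <- pmax(bmi, 14)  # physical floor; keeps bmi strictly positive
  drinking <- stats::rbinom(n, 1, truth$drinking_prob[g])
  regular_exercise <- stats::rbinom(n, 1, truth$exercise_prob[g])
  education <- rnorm_int_clamped(n, truth$education[g, "mean"],
                                 truth$education[g, "sd"], 1, 7)

  pack_years <- numeric(n)
  is_former <- status == "former"
  is_current <- status == "current"
  pack_years[is_former] <- rgamma_moments(sum(is_former),
                                          truth$packyears$former[["mean"]],
                                          truth$packyears$former[["sd"]])
  pack_years[is_current] <- rgamma_moments(sum(is_current),
                                           truth$packyears$current[["mean"]],
                                           truth$packyears$current[["sd"]])
  years_since_cessation <- rep(NA_real_, n)
  years_since_cessation[is_former] <- rgamma_moments(sum(is_former),
                                                     truth$ysc[["mean"]],
                                                     truth$ysc[["sd"]])

  # six-part Dirichlet; granulocyte remainder implicit in the emitted five
  alpha <- truth$cell_alpha
  cell_raw <- vapply(alpha, function(a) stats::rgamma(n, shape = a), numeric(n))
  cell <- cell_raw / rowSums(cell_raw)
  colnames(cell) <- names(alpha)

  cohort <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    smoking_status = status,
    pack_years = pack_years,
    years_since_cessation = years_since_cessation,
    age = age,
    sex = factor(ifelse(sex_male == 1, "male", "female"),
                 levels = c("female", "male")),
    bmi = bmi,
    drinking = drinking,
    regular_exercise = regular_exercise,
    education = as.integer(education),
    cell_prop_B = cell[, "B"],
    cell_prop_CD4T = cell[, "CD4T"],
    cell_prop_CD8T = cell[, "CD8T"],
    cell_prop_mono = cell[, "mono"],
    cell_prop_NK = cell[, "NK"]
  )

  terms <- structural_terms(cohort)
  for (m in mediator_names()) {
    mm <- truth$mediator_model[[m]]
    mu <- mm$intercept +
      drop(terms$exposure %*% mm$exposure[colnames(terms$exposure)]) +
      drop(terms$covariates %*% mm$covariates[colnames(terms$covariates)])
    cohort[[m]] <- mu + stats::rnorm(n, 0, mm$sd)
  }

  med_mat <- as.matrix(cohort[mediator_names()])
  for (y in outcome_names()) {
    om <- truth$outcome_model[[y]]
    mu <- om$intercept +
      drop(terms$exposure %*% om$exposure[colnames(terms$exposure)]) +
      drop(med_mat %*% om$mediators[mediator_names()]) +
      drop(terms$covariates %*% om$covariates[colnames(terms$covariates)])
    val <- mu + stats::rnorm(n, 0, om$sd)
    cohort[[y]] <- if (isTRUE(om$log)) exp(val) else val
  }

  lung_missing <- stats::rbinom(n, 1, truth$lung_missing_rate) == 1
  cohort$fev1[lung_missing] <- NA_real_
  cohort$fvc[lung_missing] <- NA_real_

  attr(cohort, "seed") <- truth$seed
  cohort
}

# numeric exposure and covariate term matrices shared by the generator and
# by design-matrix construction
structural_terms <- function(cohort) {
  is_former <- cohort$smoking_status == "former"
  is_current <- cohort$smoking_status == "current"
  ysc_term <- ifelse(is_former & !is.na(cohort$years_since_cessation),
                     cohort$years_since_cessation, 0)
  exposure <- cbind(
    fs = as.numeric(is_former),
    cs = as.numeric(is_current),
    fpy = ifelse(is_former, cohort$pack_years, 0),
    cpy = ifelse(is_current, cohort$pack_years, 0),
    ysc = ysc_term
  )
  covariates <- cbind(
    age = cohort$age,
    sex_male = as.numeric(cohort$sex == "male"),
    bmi = cohort$bmi,
    drinking = as.numeric(cohort$drinking),
    regular_exercise = as.numeric(cohort$regular_exercise),
    education = as.numeric(cohort$education),
    cell_prop_B = cohort$cell_prop_B,
    cell_prop_CD4T = cohort$cell_prop_CD4T,
    cell_prop_CD8T = cohort$cell_prop_CD8T,
    cell_prop_mono = cohort$cell_prop_mono,
    cell_prop_NK = cohort$cell_prop_NK
  )
  list(exposure = exposure, covariates = covariates)
}
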