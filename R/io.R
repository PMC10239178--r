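#' Read and write cohort tables
#'
#' Cohorts are stored as delimited text (CSV) with missing values as empty
#' fields. `write_cohort()` records the generator seed (when present) in a
#' `# seed:` comment line; `read_cohort()` restores column types, the
#' smoking-status and sex factor levels, and the seed attribute.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()`: a cohort tibble. `write_cohort()`: `path`,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  seed <- attr(cohort, "seed")
  body <- readr::format_csv(cohort, na = "")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) cat(sprintf("# seed: %d\n", seed), file = con)
  cat(body, file = con)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  seed <- NULL
  if (startsWith(first, "# seed:"))
    seed <- as.integer(trimws(sub("# seed:", "", first)))
  cohort <- readr::read_csv(path, na = "", comment = "#",
                            show_col_types = FALSE)
  if ("smoking_status" %in% names(cohort))
    cohort$smoking_status <- factor(cohort$smoking_status,
                                    levels = c("non", "former", "current"))
  if ("sex" %in% names(cohort))
    cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
  if ("education" %in% names(cohort))
    cohort$education <- as.integer(cohort$education)
  if (!is.null(seed)) attr(cohort, "seed") <- seed
  cohort
}

#' Serialise simulation truths to YAML
#'
#' @param truth A [sim_truth()] object.
#' @param path YAML file path.
#' @return `read_truth_config()`: a `sim_truth`. `write_truth_config()`:
#'   `path`, invisibly.
#' @export
write_truth_config <- function(truth, path) {
  validate_sim_truth(truth)
  serial <- truth
  serial$bmi <- matrix_to_list(truth$bmi)
  serial$education <- matrix_to_list(truth$education)
  # named atomic vectors lose their names in YAML sequences; emit maps
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(listify(unclass(serial)), path)
  invisible(path)
}

#' @rdname write_truth_config
#' @export
read_truth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$bmi <- list_to_matrix(raw$bmi)
  raw$education <- list_to_matrix(raw$education)
  for (f in c("prevalence", "sex_male_prob", "drinking_prob", "exercise_prob",
              "ysc", "cell_alpha"))
    raw[[f]] <- unlist(raw[[f]])
  raw$age_range <- unlist(raw$age_range)
  raw$packyears <- purrr::map(raw$packyears, unlist)
  raw$mediator_model <- purrr::map(raw$mediator_model, function(m) {
    m$exposure <- unlist(m$exposure)
    m$covariates <- unlist(m$covariates)
    m
  })
  raw$outcome_model <- purrr::map(raw$outcome_model, function(m) {
    m$exposure <- unlist(m$exposure)
    m$mediators <- unlist(m$mediators)
    m$covariates <- unlist(m$covariates)
    m
  })
  validate_sim_truth(structure(raw, class = "sim_truth"))
}

matrix_to_list <- function(m) {
  purrr::map(stats::setNames(rownames(m), rownames(m)),
             ~ as.list(stats::setNames(m[.x, ], colnames(m))))
}

list_to_matrix <- function(l) {
  rows <- names(l)
  cols <- names(l[[1]])
  out <- matrix(unlist(purrr::map(l, unlist)), nrow = length(rows),
                byrow = TRUE, dimnames = list(rows, cols))
  out
}
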