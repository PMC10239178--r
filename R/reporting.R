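#' Baseline characteristics by smoking group
#'
#' Computes the descriptive table customarily reported for a cohort
#' stratified by smoking status: group sizes and shares, mean (SD) for
#' continuous variables, count (%) for binary variables, and a cross-group
#' test per row - Kruskal-Wallis (rank-based, with the standard tie
#' correction) for continuous rows and a Pearson chi-square test of
#' independence without continuity correction for categorical rows.
#' Pack-years and years since cessation are summarised only within the
#' group(s) where they are defined and carry no cross-group test.
#'
#' @param cohort A cohort tibble.
#' @param continuous,binary Variable names for the two row types; defaults
#'   cover the standard table.
#' @return An `eaa_cohort_summary` object with `groups` (tibble: group, n,
#'   pct) and `rows` (tibble: variable, type, per-group statistics, test,
#'   p.value).
#' @examples
#' cohort <- generate_cohort(sim_truth(n = 400, seed = 5))
#' cohort_summary(cohort)
#' @export
cohort_summary <- function(cohort,
                           continuous = c("age", "bmi", "education",
                                          "fg", "hba1c", "fev1", "fvc"),
                           binary = c("sex_male", "drinking",
                                      "regular_exercise")) {
  status <- droplevels(factor(cohort$smoking_status))
  present <- levels(status)[table(status) > 0]
  if (length(present) < 2)
    abort_eaa("Need at least 2 non-empty smoking groups.", "insufficient_data")
  if (length(present) < nlevels(factor(cohort$smoking_status)))
    warn("Empty smoking group(s) omitted from the summary.")
  status <- factor(as.character(status), levels = present)

  dat <- cohort
  if ("sex" %in% names(dat))
    dat$sex_male <- as.numeric(dat$sex == "male")
  n_total <- nrow(dat)
  groups <- tibble::tibble(
    group = present,
    n = as.integer(table(status)[present]),
    pct = 100 * as.integer(table(status)[present]) / n_total)

  summarise_cont <- function(v) {
    x <- dat[[v]]
    stats <- purrr::map_chr(present, function(g) {
      xi <- x[status == g & !is.na(x)]
      if (length(xi) == 0) return("-")
      sprintf("%.1f (%.1f)", mean(xi), stats::sd(xi))
    })
    ok <- !is.na(x)
    p <- tryCatch(stats::kruskal.test(x[ok], status[ok])$p.value,
                  error = function(e) NA_real_)
    tibble::tibble(variable = v, type = "continuous",
                   !!!stats::setNames(as.list(stats), present),
                   test = "kruskal", p.value = p)
  }
  summarise_bin <- function(v) {
    x <- dat[[v]]
    stats <- purrr::map_chr(present, function(g) {
      xi <- x[status == g & !is.na(x)]
      if (length(xi) == 0) return("-")
      sprintf("%d (%.1f%%)", sum(xi == 1), 100 * mean(xi == 1))
    })
    ok <- !is.na(x)
    tab <- table(x[ok], status[ok])
    p <- if (nrow(tab) < 2) 1 else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    tibble::tibble(variable = v, type = "binary",
                   !!!stats::setNames(as.list(stats), present),
                   test = "chisq", p.value = p)
  }
  group_only <- function(v, in_groups) {
    x <- dat[[v]]
    stats <- purrr::map_chr(present, function(g) {
      if (!g %in% in_groups) return("-")
      xi <- x[status == g & !is.na(x)]
      if (length(xi) == 0) return("-")
      sprintf("%.1f (%.1f)", mean(xi), stats::sd(xi))
    })
    tibble::tibble(variable = v, type = "continuous",
                   !!!stats::setNames(as.list(stats), present),
                   test = NA_character_, p.value = NA_real_)
  }

  rows <- dplyr::bind_rows(
    purrr::map(intersect(continuous, names(dat)), summarise_cont),
    if ("pack_years" %in% names(dat))
      dplyr::bind_rows(
        group_only("pack_years", c("former", "current")),
        if ("years_since_cessation" %in% names(dat))
          group_only("years_since_cessation", "former")),
    purrr::map(intersect(binary, names(dat)), summarise_bin))

  structure(list(groups = groups, rows = rows, n = n_total),
            class = "eaa_cohort_summary")
}

#' @export
print.eaa_cohort_summary <- function(x, ...) {
  cat("<eaa_cohort_summary> n =", x$n, "\n")
  print(x$groups)
  print(x$rows, n = Inf)
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' Correlations use pairwise-complete observations. Variables with zero
#' variance yield `NA` entries (flagged with a warning), not an error.
#'
#' @param cohort A data frame.
#' @param vars At least two numeric column names.
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(cohort, vars) {
  if (length(vars) < 2)
    abort_eaa("Need at least 2 variables.", "spec_error")
  x <- as.matrix(cohort[vars])
  degenerate <- vapply(vars, function(v)
    stats::var(x[, v], na.rm = TRUE) %in% c(0, NA), logical(1))
  if (any(degenerate))
    warn(paste0("Zero-variance variable(s): ",
                paste(vars[degenerate], collapse = ", "),
                "; correlations set to NA."))
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Write publication-style report tables
#'
#' Emits machine-readable CSVs shaped like the customary report: baseline
#' characteristics, the exposure-mediator screen, per-exposure total
#' effects, and the full mediation grid (effect, bootstrap CI, raw and
#' FDR-adjusted p-value, significance flag, proportion mediated, per-cell
#' sample size). Effects are rounded to 4 decimals and proportions to 1
#' decimal, the conventional printed precision. Generation is pure:
#' identical inputs give identical bytes.
#'
#' @param grid An `eaa_grid` object.
#' @param summary Optional `eaa_cohort_summary`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(grid, summary = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  r4 <- function(x) round(x, 4)

  if (!is.null(summary)) {
    p <- file.path(dir, "table_characteristics.csv")
    readr::write_csv(summary$rows, p, na = "")
    paths <- c(paths, p)
    p <- file.path(dir, "table_group_sizes.csv")
    readr::write_csv(summary$groups, p, na = "")
    paths <- c(paths, p)
  }

  if (nrow(grid$screen) > 0) {
    p <- file.path(dir, "table_screen.csv")
    screen <- dplyr::mutate(grid$screen, dplyr::across(
      c("estimate", "std.error"), r4))
    readr::write_csv(screen, p, na = "")
    paths <- c(paths, p)
  }

  cells <- grid$cells
  p <- file.path(dir, "table_total_effects.csv")
  totals <- cells %>%
    dplyr::select("exposure", "mediator", "outcome", "total", "total_low",
                  "total_high", "total_p", "n_analysis") %>%
    dplyr::mutate(dplyr::across(c("total", "total_low", "total_high"), r4))
  readr::write_csv(totals, p, na = "")
  paths <- c(paths, p)

  p <- file.path(dir, "table_mediation.csv")
  med <- cells %>%
    dplyr::select("exposure", "mediator", "outcome", "acme", "acme_low",
                  "acme_high", "p.value", "fdr", "significant",
                  "prop_mediated", "n_analysis") %>%
    dplyr::mutate(dplyr::across(c("acme", "acme_low", "acme_high"), r4),
                  prop_mediated = round(.data$prop_mediated, 1))
  readr::write_csv(med, p, na = "")
  paths <- c(paths, p)

  invisible(paths)
}
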