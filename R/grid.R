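#' Bonferroni threshold for the exposure-mediator screen
#'
#' The screen tests every mediator against every smoking exposure variable;
#' the per-test threshold divides the family alpha by the number of tests.
#' With the default seven DNAm markers and five smoking variables this is
#' `0.05 / 35 = 0.0014`.
#'
#' @param alpha Family-wise alpha (in (0, 1)).
#' @param n_mediators,n_exposures Positive integers.
#' @return A single numeric threshold.
#' @examples
#' bonferroni_threshold(0.05, 7, 5)
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_mediators = 7, n_exposures = 5) {
  stopifnot(alpha > 0, alpha < 1, n_mediators >= 1, n_exposures >= 1)
  alpha / (n_mediators * n_exposures)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, take
#' `q_(i) = min over j >= i of m * p_(j) / j`, cap at 1, return in the
#' original order. A thin validated surface over
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    abort_eaa("p-values must lie in [0, 1] with no missing values.",
              "validation_error")
  stats::p.adjust(p, method = "BH")
}

#' Specify the full mediation grid
#'
#' @param exposures Exposure terms (default all five smoking variables).
#' @param mediators Mediator columns (default the seven DNAm markers).
#' @param outcomes Outcome columns (default all four).
#' @param screen Run the Bonferroni exposure-mediator screen and drop
#'   mediators with no surviving association? (default `TRUE`).
#' @param screen_alpha Family alpha for the screen (default 0.05; the
#'   per-test threshold divides by `mediators x exposures`).
#' @param fdr_alpha FDR significance level over the mediation p-values.
#' @param fdr_family `"all"` (one family over every mediation p-value, the
#'   default) or `"exposure"` (adjust within each exposure's table).
#' @param n_boot,seed Bootstrap options shared by all cells; per-cell seeds
#'   are derived deterministically from `seed`.
#' @param subset `"all"` or `"males"`.
#' @param ... Further per-cell options passed to
#'   [run_mediation_analysis()] (e.g. `stratified`).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(exposures = exposure_names(),
                      mediators = mediator_names(),
                      outcomes = outcome_names(),
                      screen = TRUE, screen_alpha = 0.05,
                      fdr_alpha = 0.05, fdr_family = c("all", "exposure"),
                      n_boot = 2000, seed = 1, subset = "all", ...) {
  fdr_family <- arg_match(fdr_family)
  structure(list(exposures = exposures, mediators = mediators,
                 outcomes = outcomes, screen = screen,
                 screen_alpha = screen_alpha, fdr_alpha = fdr_alpha,
                 fdr_family = fdr_family, n_boot = n_boot,
                 seed = as.integer(seed), subset = subset,
                 cell_options = list(...)),
            class = "grid_spec")
}

#' Bonferroni screen of exposure-mediator associations
#'
#' Regresses each DNAm marker on the smoking variables (status pair,
#' pack-years pair, and - in former smokers - years since cessation), with
#' that marker's extreme outliers excluded and the standard adjustment set.
#' A mediator is dropped only when none of its exposure associations passes
#' the Bonferroni threshold `screen_alpha / (mediators x exposures)`; such a
#' marker is not a plausible mediator and is omitted from the mediation
#' grid.
#'
#' @param cohort A cohort tibble.
#' @param grid A [grid_spec()] (defaults to the full grid).
#' @return A list with `table` (tibble: mediator, exposure, estimate,
#'   std.error, p.value, pass), `kept` (character), and `threshold`.
#' @export
screen_mediators <- function(cohort, grid = grid_spec()) {
  threshold <- bonferroni_threshold(grid$screen_alpha,
                                    length(grid$mediators),
                                    length(grid$exposures))
  sets <- unique(purrr::map_chr(grid$exposures, exposure_set_for))
  rows <- purrr::map(grid$mediators, function(m) {
    mask <- flag_extreme_outliers(cohort[[m]])
    sub0 <- cohort[is.na(mask) | mask, , drop = FALSE]
    purrr::map(sets, function(set) {
      spec <- model_spec(set, mediator = m, subset = grid$subset,
                         role = "mediator")
      d <- tryCatch(build_design(sub0, spec),
                    eaamediate_error = function(e)
                      abort_eaa(paste0("Screen fit failed for mediator `", m,
                                       "`, exposure set `", set, "`: ",
                                       conditionMessage(e)), "screen_error"))
      fit <- fit_ols(d$x, d$y)
      terms <- intersect(exposure_terms_for(set), grid$exposures)
      dplyr::mutate(
        dplyr::filter(tidy(fit), .data$term %in% terms),
        mediator = m, .before = 1)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  table <- rows %>%
    dplyr::rename(exposure = "term") %>%
    dplyr::select(-"statistic") %>%
    dplyr::mutate(pass = .data$p.value < threshold)
  kept <- table %>%
    dplyr::group_by(.data$mediator) %>%
    dplyr::summarise(keep = any(.data$pass)) %>%
    dplyr::filter(.data$keep) %>%
    dplyr::pull("mediator")
  kept <- intersect(grid$mediators, kept)  # preserve configured order
  list(table = table, kept = kept, threshold = threshold)
}

cell_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 10007 + idx * 7919) %% 2147483629 + 1)
}

#' Run the full exposure x mediator x outcome mediation grid
#'
#' Screens mediators (optional), then runs the bootstrap mediation analysis
#' for every kept mediator, exposure and outcome. Exposure terms that share
#' a model pair (former/current status; former/current pack-years) are read
#' from the same joint fits, so one set of bootstrap refits serves both
#' exposures. All mediation p-values form one family for
#' Benjamini-Hochberg FDR control (with the default six kept mediators,
#' five exposures and four outcomes: 120 tests).
#'
#' @param cohort A cohort tibble.
#' @param grid A [grid_spec()].
#' @return An `eaa_grid` object: `cells` (one row per mediation test, with
#'   ACME/ADE/total estimates, bootstrap CIs, raw and FDR-adjusted p-values,
#'   significance flags, proportion mediated and per-cell analysis n),
#'   `screen`, `kept_mediators`, `failures`, and the spec.
#' @examples
#' cohort <- generate_cohort(sim_truth(n = 500, seed = 2))
#' g <- run_grid(cohort, grid_spec(mediators = "grim_eaa",
#'                                 exposures = c("fs", "cs"),
#'                                 outcomes = "fg", n_boot = 200))
#' tidy(g)
#' @export
run_grid <- function(cohort, grid = grid_spec()) {
  screen <- if (isTRUE(grid$screen)) screen_mediators(cohort, grid)
            else list(table = tibble::tibble(), kept = grid$mediators,
                      threshold = NA_real_)
  kept <- screen$kept
  sets <- unique(purrr::map_chr(grid$exposures, exposure_set_for))

  tasks <- tidyr::expand_grid(mediator = kept, outcome = grid$outcomes,
                              set = sets)
  results <- vector("list", nrow(tasks) * 2L)
  failures <- list()
  r <- 0L
  for (i in seq_len(nrow(tasks))) {
    m <- tasks$mediator[i]; y <- tasks$outcome[i]; set <- tasks$set[i]
    terms <- intersect(exposure_terms_for(set), grid$exposures)
    opts <- do.call(mediation_options,
                    c(list(n_boot = grid$n_boot, seed = cell_seed(grid$seed, i),
                           subset = grid$subset), grid$cell_options))
    cell <- tryCatch({
      pair <- prepare_pair(cohort, set, m, y, opts)
      core <- mediate_core(pair, opts)
      purrr::map(terms, ~ mediation_result_for(core, pair, .x, opts))
    }, eaamediate_error = function(e) e)
    if (inherits(cell, "error")) {
      failures <- c(failures, list(tibble::tibble(
        mediator = m, outcome = y, exposure_set = set,
        message = conditionMessage(cell))))
      next
    }
    for (res in cell) { r <- r + 1L; results[[r]] <- res }
  }
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(mediator = character(), outcome = character(),
                   exposure_set = character(), message = character())
  n_expected <- nrow(tasks)
  if (nrow(failures) > 0.10 * n_expected)
    abort_eaa(sprintf("%d of %d grid cells failed.", nrow(failures), n_expected),
              "grid_error")

  results <- results[seq_len(r)]
  cells <- purrr::map_dfr(results, function(res) {
    g <- glance(res)
    est <- res$estimates
    tot <- est[est$effect == "total", ]
    ind <- est[est$effect == "acme", ]
    tibble::tibble(
      exposure = res$exposure, mediator = res$mediator, outcome = res$outcome,
      acme = ind$estimate, acme_low = ind$conf.low, acme_high = ind$conf.high,
      p.value = ind$p.value,
      ade = g$ade, total = tot$estimate,
      total_low = tot$conf.low, total_high = tot$conf.high,
      total_p = tot$p.value,
      prop_mediated = g$prop_mediated, prop_defined = g$prop_defined,
      n_analysis = g$n_analysis, n_failed = g$n_failed)
  })
  if (nrow(cells) > 0) {
    if (grid$fdr_family == "all") {
      cells$fdr <- bh_adjust(cells$p.value)
    } else {
      cells <- cells %>%
        dplyr::group_by(.data$exposure) %>%
        dplyr::mutate(fdr = bh_adjust(.data$p.value)) %>%
        dplyr::ungroup()
    }
    cells$significant <- cells$fdr < grid$fdr_alpha
  } else {
    cells$fdr <- numeric(0)
    cells$significant <- logical(0)
  }
  structure(list(cells = cells, screen = screen$table,
                 kept_mediators = kept, screen_threshold = screen$threshold,
                 failures = failures, spec = grid),
            class = "eaa_grid")
}

#' @export
print.eaa_grid <- function(x, ...) {
  cat(sprintf("<eaa_grid> %d mediation tests (%d mediators kept of %d; FDR %s)\n",
              nrow(x$cells), length(x$kept_mediators),
              length(x$spec$mediators), x$spec$fdr_family))
  cat(sprintf("  significant at FDR < %.2f: %d\n", x$spec$fdr_alpha,
              sum(x$cells$significant)))
  if (nrow(x$failures) > 0)
    cat(sprintf("  failed cells: %d\n", nrow(x$failures)))
  invisible(x)
}

#' Tidy a mediation grid
#' @param x An `eaa_grid` object.
#' @param ... Unused.
#' @return The per-test cells tibble.
#' @export
tidy.eaa_grid <- function(x, ...) x$cells

#' One-row summary of a mediation grid
#' @param x An `eaa_grid` object.
#' @param ... Unused.
#' @return A one-row tibble: test counts, kept mediators, significant cells.
#' @export
glance.eaa_grid <- function(x, ...) {
  tibble::tibble(n_tests = nrow(x$cells),
                 n_kept_mediators = length(x$kept_mediators),
                 n_significant = sum(x$cells$significant),
                 n_failed_cells = nrow(x$failures),
                 fdr_alpha = x$spec$fdr_alpha)
}
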