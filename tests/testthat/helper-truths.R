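# Truth variants used across tests ------------------------------------------

# status-only structural model: dose and cessation paths zeroed so the
# status model pair is correctly specified and the generator ACME equals the
# pipeline estimand
truth_status_only <- function(n = 2000, seed = 1, ...) {
  truth <- sim_truth(n = n, seed = seed, ...)
  for (m in names(truth$mediator_model))
    truth$mediator_model[[m]]$exposure[c("fpy", "cpy", "ysc")] <- 0
  for (y in names(truth$outcome_model))
    truth$outcome_model[[y]]$exposure[c("fpy", "cpy", "ysc")] <- 0
  truth
}

# complete null: no exposure -> mediator and no mediator -> outcome paths
truth_null <- function(n = 500, seed = 1, ...) {
  truth <- sim_truth(n = n, seed = seed, ...)
  for (m in names(truth$mediator_model))
    truth$mediator_model[[m]]$exposure[] <- 0
  for (y in names(truth$outcome_model)) {
    truth$outcome_model[[y]]$mediators[] <- 0
    truth$outcome_model[[y]]$exposure[] <- 0
  }
  truth
}

# deterministic limit: no noise anywhere, no covariate effects, no missing
# lung exams; mediators and outcomes are exact linear functions of the
# exposure terms
truth_noiseless <- function(n = 400, seed = 1, ...) {
  truth <- sim_truth(n = n, seed = seed, lung_missing_rate = 0, ...)
  for (m in names(truth$mediator_model)) {
    truth$mediator_model[[m]]$sd <- 0
    truth$mediator_model[[m]]$covariates[] <- 0
  }
  for (y in names(truth$outcome_model)) {
    truth$outcome_model[[y]]$sd <- 0
    truth$outcome_model[[y]]$covariates[] <- 0
  }
  truth
}

# small random regression problem with named columns
random_design <- function(n, p, seed) {
  withr::with_seed(seed, {
    x <- cbind(`(Intercept)` = 1,
               matrix(rnorm(n * (p - 1)), n, p - 1,
                      dimnames = list(NULL, paste0("x", seq_len(p - 1)))))
    y <- rnorm(n)
    list(x = x, y = y)
  })
}
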