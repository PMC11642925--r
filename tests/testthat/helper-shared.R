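# Expensive shared fixtures, built once per test run on first use.
.shared <- new.env(parent = emptyenv())

# a small simulated study: 4 subjects per group, 3 regions (including the
# small low-binding DBS analogue), refitted reference library
shared_dataset <- function() {
  if (is.null(.shared$dataset)) {
    set.seed(401)
    design <- default_truth_parameters(n_per_group = 4, seed = 401)
    lib <- make_reference_library(n = 10, noise = design$sigma_model,
                                  seed = 402, refit_n_starts = 6)
    .shared$dataset <- simulate_dataset(design, lib, seed = 403,
                                        regions = c("DBS", "FC", "OC"))
  }
  .shared$dataset
}

shared_nls <- function() {
  if (is.null(.shared$nls)) {
    ds <- shared_dataset()
    .shared$nls <- fit_dataset_nls(list(tac_table = ds$tac_table,
                                        ref_fits = ds$ref_fits),
                                   n_starts = 3, seed = 404)
  }
  .shared$nls
}

shared_simba <- function() {
  if (is.null(.shared$simba)) {
    ds <- shared_dataset()
    reg <- ds$design$regions
    mu0 <- c(logR1 = reg$logR1[reg$region == "DBS"],
             logk2prime = ds$design$logk2prime_mean,
             logBPND = reg$logBPND[reg$region == "DBS"])
    spec <- simba_spec(
      priors = simba_priors(intercept_mean = mu0),
      mcmc = list(chains = 2, warmup = 500, iter = 400, seed = 405))
    .shared$simba <- suppressWarnings(fit_simba(ds, spec))
  }
  .shared$simba
}
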