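#!/usr/bin/env Rscript
# Opt-in long-running evaluation: end-to-end power and false-positive-rate
# replicates for both the hierarchical model and the mixed-model
# comparator, at study sizes approaching the full simulation design.
# Expect many hours on a single CPU. Not part of the test suite or the
# acceptance script.
#
#   Rscript scripts/full_scale_power.R --seed 1 --replicates 20 \
#       --n-per-group 10 --out results/full_power.json

suppressMessages(library(refsimba))

args <- commandArgs(trailingOnly = TRUE)
arg_of <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(arg_of("--seed", "1"))
n_rep <- as.integer(arg_of("--replicates", "20"))
npg <- as.integer(arg_of("--n-per-group", "10"))
out <- arg_of("--out", "results/full_power.json")
null_effect <- as.numeric(arg_of("--effect", "0"))   # 0 = FPR, 0.04 = power
dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)

design <- default_truth_parameters(n_per_group = npg, seed = seed)
design$treatment_effect_logBPND <- null_effect
lib <- make_reference_library(n = 100, noise = design$sigma_model,
                              seed = seed + 1)
reg <- design$regions
mu0 <- c(logR1 = reg$logR1[reg$region == "DBS"],
         logk2prime = design$logk2prime_mean,
         logBPND = reg$logBPND[reg$region == "DBS"])

z_simba <- z_lme <- numeric(0)
for (r in seq_len(n_rep)) {
  message("replicate ", r, " / ", n_rep)
  ds <- simulate_dataset(design, lib, seed = seed + 100 + r,
                         regions = c("DBS", "FC", "OC"))
  spec <- simba_spec(priors = simba_priors(intercept_mean = mu0),
                     mcmc = list(chains = 2, warmup = 400, iter = 400,
                                 seed = seed + 200 + r))
  fit <- suppressWarnings(fit_simba(ds, spec))
  ctr <- extract_contrast(fit, stats::setNames(1, treatment_contrast_name(fit)))
  z_simba <- c(z_simba, ctr$mean / ctr$sd)
  nls <- fit_dataset_nls(list(tac_table = ds$tac_table,
                              ref_fits = ds$ref_fits),
                         n_starts = 3, seed = seed + 300 + r)
  est <- merge(nls, ds$meta, by = c("subject_id", "measurement_id"))
  est$logBPND <- log(pmax(est$BPND, 1e-3))
  lc <- try(lme_contrast(est), silent = TRUE)
  if (!inherits(lc, "try-error") && !lc$singular) {
    z_lme <- c(z_lme, lc$estimate / lc$se)
  }
}

res <- list(
  simba = unclass(power_fpr(z_simba, seed = seed))[
    c("power", "power_exact", "ci95", "n_replicates")],
  lme = unclass(power_fpr(z_lme, seed = seed))[
    c("power", "power_exact", "ci95", "n_replicates")],
  effect = null_effect, n_per_group = npg)
jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
message("wrote ", out)
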