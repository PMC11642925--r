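#' Fit the hierarchical multivariate model by Hamiltonian Monte Carlo
#'
#' Runs the adaptive HMC sampler on the joint posterior of
#' [simba_model()]. Chains are initialised either from the prior
#' neighbourhood (`init = "prior"`, with jitter) or — the default — from a
#' fast conventional NLS pass whose per-TAC estimates seed the global
#' intercepts and fixed effects (`init = "nls"`), the usual practice for
#' TAC-level hierarchical models where the posterior neighbourhood is well
#' identified but far from the origin. Per-TAC posterior-mean PK
#' parameters, pointwise log likelihoods and convergence diagnostics
#' (split-Rhat, effective sample size, divergence counts) are computed
#' from the post-warmup draws.
#'
#' @param dataset a `sim_dataset` or compatible list (needs `tac_table`,
#'   `meta`, `region_info`, `ref_fits`, `frames`).
#' @param spec a [simba_spec()]; MCMC options (chains, warmup, iter, seed)
#'   live in `spec$mcmc`.
#' @param init `"nls"` or `"prior"`.
#' @return An object of class `simba_fit`: see
#'   [effective_parameters()], [extract_contrast()], [tac_estimates()].
#' @export
fit_simba <- function(dataset, spec = simba_spec(), init = c("nls", "prior")) {
  init <- match.arg(init)
  model <- simba_model(dataset, spec)
  mc <- spec$mcmc
  v0 <- model$init_vector()
  if (init == "nls") {
    v0 <- nls_init_vector(model, dataset, v0, seed = mc$seed)
  }
  inv_mass0 <- curvature_inv_mass(model$lp_grad, v0)
  chains <- vector("list", mc$chains)
  for (ch in seq_len(mc$chains)) {
    set.seed(mc$seed + 1000L * ch)
    vch <- v0 + 0.02 * stats::rnorm(model$P)
    chains[[ch]] <- hmc_chain(model$lp_grad, vch, n_warmup = mc$warmup,
                              n_iter = mc$iter, seed = mc$seed + ch,
                              adapt_delta = mc$adapt_delta,
                              traj_length = mc$traj_length,
                              max_leapfrog = mc$max_leapfrog,
                              inv_mass = inv_mass0)
  }
  draws_list <- lapply(chains, `[[`, "draws")
  draws <- do.call(rbind, draws_list)
  colnames(draws) <- model$param_names
  diag <- mcmc_diagnostics(draws_list)
  divergences <- sum(vapply(chains, `[[`, integer(1), "divergences"))
  div_rate <- divergences / nrow(draws)
  if (div_rate > mc$divergence_warn) {
    warning(sprintf("divergence rate %.1f%% exceeds %.1f%%; treat posterior with caution",
                    100 * div_rate, 100 * mc$divergence_warn))
  }

  # per-draw derived quantities: per-TAC eta and pointwise log likelihood
  n_draws <- nrow(draws)
  m <- model$m
  eta_sum <- matrix(0, model$n_tac, m)
  eta2_sum <- matrix(0, model$n_tac, m)
  theta_sum <- matrix(0, model$n_tac, m)
  loglik_obs <- matrix(NA_real_, n_draws, model$n_obs)
  for (d in seq_len(n_draws)) {
    st <- model$lp_grad(draws[d, ], want_pointwise = TRUE)
    eta_sum <- eta_sum + st$eta
    eta2_sum <- eta2_sum + st$eta^2
    theta_sum <- theta_sum + exp(st$eta)
    loglik_obs[d, ] <- as.numeric(st$loglik_obs)
  }
  eta_mean <- eta_sum / n_draws
  eta_sd <- sqrt(pmax(eta2_sum / n_draws - eta_mean^2, 0))
  theta_mean <- theta_sum / n_draws
  tac_params <- cbind(model$design$keys,
                      as.data.frame(theta_mean),
                      as.data.frame(eta_mean), as.data.frame(eta_sd))
  pk_nat <- sub("^log", "", model$spec$parameters)
  names(tac_params) <- c(names(model$design$keys), pk_nat,
                         model$spec$parameters,
                         paste0("sd_", model$spec$parameters))

  structure(
    list(model = model, draws = draws, chains = mc$chains,
         n_iter = mc$iter, tac_params = tac_params,
         loglik_obs = loglik_obs,
         diagnostics = list(rhat = stats::setNames(diag$rhat, model$param_names),
                            ess = stats::setNames(diag$ess, model$param_names),
                            divergences = divergences,
                            divergence_rate = div_rate,
                            accept_rate = vapply(chains, `[[`, numeric(1),
                                                 "accept_rate"),
                            step_size = vapply(chains, `[[`, numeric(1),
                                               "step_size"))),
    class = "simba_fit")
}

#' @export
print.simba_fit <- function(x, ...) {
  cat(sprintf(
    "<simba_fit: %d TACs, %d chains x %d draws, max Rhat %.3f, %d divergences>\n",
    x$model$n_tac, x$chains, x$n_iter, max(x$diagnostics$rhat, na.rm = TRUE),
    x$diagnostics$divergences))
  invisible(x)
}

# quick NLS-based initialisation of intercepts, fixed effects and the
# sigma intercept
#' @keywords internal
nls_init_vector <- function(model, dataset, v0, seed = 1) {
  design <- model$design
  spec <- model$spec
  est <- try(fit_dataset_nls(list(tac_table = dataset$tac_table,
                                  ref_fits = dataset$ref_fits),
                             n_starts = 2, seed = seed), silent = TRUE)
  if (inherits(est, "try-error")) return(v0)
  est <- est[order(est$subject_id, est$measurement_id, est$region), ]
  ok <- is.finite(est$BPND) & est$BPND > 1e-3 & is.finite(est$R1)
  if (mean(ok) < 0.5) return(v0)
  leta <- cbind(logR1 = log(pmax(est$R1, 1e-3)),
                logk2prime = log(pmax(est$k2prime, 1e-4)),
                logBPND = log(pmax(est$BPND, 1e-3)))
  for (i in seq_along(spec$parameters)) {
    p <- spec$parameters[i]
    if (p == "logk4") next
    yv <- leta[ok, p]
    X <- design$X[[p]][ok, , drop = FALSE]
    if (ncol(X)) {
      cf <- try(stats::lm.fit(cbind(1, X), yv)$coefficients, silent = TRUE)
      if (!inherits(cf, "try-error") && all(is.finite(cf))) {
        v0[model$idx$alpha[i]] <- cf[1]
        v0[model$idx$beta[[p]]] <- cf[-1]
      }
    } else {
      v0[model$idx$alpha[i]] <- mean(yv)
    }
  }
  # clamp towards the prior where the NLS pass is wild
  v0[model$idx$alpha] <- pmin(pmax(v0[model$idx$alpha], -5), 5)
  v0
}

#' Per-TAC posterior-mean parameter estimates
#'
#' @param fit a `simba_fit`.
#' @return Data frame with one row per TAC: keys, posterior-mean natural-
#'   scale parameters (R1, k2prime, BPND, ...), posterior mean and SD of
#'   each log-scale parameter.
#' @export
tac_estimates <- function(fit) {
  stopifnot(inherits(fit, "simba_fit"))
  fit$tac_params
}

#' Effective number of parameters
#'
#' Estimates model complexity from the pointwise log-likelihood draws: the
#' effective number of parameters is the sum over observations of the
#' posterior variance of the log predictive density (the complexity
#' penalty of leave-one-out-style information criteria). Under strong
#' hierarchical shrinkage this is far below the nominal parameter count.
#' Observations whose pointwise variance exceeds 0.4 are counted as
#' unstable and surfaced as a diagnostic.
#'
#' @param fit a `simba_fit` (or any list with a draws-by-observations
#'   `loglik_obs` matrix and an `n_tac` count).
#' @return List with `p_eff` (total), `p_eff_per_tac`, `n_tac`,
#'   `n_unstable` and `unstable` (logical flag).
#' @export
effective_parameters <- function(fit) {
  ll <- if (inherits(fit, "simba_fit")) fit$loglik_obs else fit$loglik_obs
  if (is.null(ll)) stopf("no pointwise log-likelihood stored")
  n_tac <- if (inherits(fit, "simba_fit")) fit$model$n_tac else fit$n_tac
  vars <- apply(ll, 2, stats::var)
  p_eff <- sum(vars)
  n_unstable <- sum(vars > 0.4)
  list(p_eff = p_eff, p_eff_per_tac = p_eff / n_tac, n_tac = n_tac,
       n_unstable = n_unstable, unstable = n_unstable > 0)
}

#' Posterior summary of a linear contrast of model coefficients
#'
#' @param fit a `simba_fit`.
#' @param contrast named numeric vector of coefficients over sampled
#'   parameter names (e.g. the group-by-time interaction coefficient for
#'   the treatment-minus-placebo difference-in-differences).
#' @return List with `mean`, `sd`, `ci80`, `ci95` and the contrast draws.
#' @export
extract_contrast <- function(fit, contrast) {
  stopifnot(inherits(fit, "simba_fit"))
  unknown <- setdiff(names(contrast), colnames(fit$draws))
  if (length(unknown)) {
    stopf("unknown coefficient(s): %s", paste(unknown, collapse = ", "),
          class = "refsimba_contrast_error")
  }
  x <- drop(fit$draws[, names(contrast), drop = FALSE] %*% contrast)
  list(mean = mean(x), sd = stats::sd(x),
       ci80 = unname(stats::quantile(x, c(0.1, 0.9))),
       ci95 = unname(stats::quantile(x, c(0.025, 0.975))),
       draws = x)
}

#' Name of the treatment-minus-placebo contrast coefficient
#'
#' Convenience helper returning the sampled-coefficient name of the
#' group-by-time interaction on logBPND under the default model formula.
#'
#' @param fit a `simba_fit`.
#' @return Character scalar.
#' @export
treatment_contrast_name <- function(fit) {
  nm <- grep("^beta_logBPND_.*(group|patient).*(time|post)", colnames(fit$draws),
             value = TRUE)
  if (length(nm) != 1) {
    stopf("could not identify a unique group-by-time coefficient (found: %s)",
          paste(nm, collapse = ", "), class = "refsimba_contrast_error")
  }
  nm
}
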