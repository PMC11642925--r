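#' Prepare the hierarchical model for sampling
#'
#' Assembles the design, the vectorised kinetic forward model, the
#' unconstrained parameter packing and the joint log posterior with its
#' analytic gradient (the kinetic-curve Jacobian uses central differences
#' on the three log-scale PK parameters; everything else — hierarchy,
#' covariances, sigma model, priors, transforms — is differentiated
#' exactly). Non-centred parameterisations are used for every deviation
#' block to avoid funnel geometry at the small TAC-deviation scale.
#'
#' @param dataset a `sim_dataset` or compatible list.
#' @param spec a [simba_spec()].
#' @return A list of class `simba_model` with the design, parameter index,
#'   `lp_grad(v)` and initialisation helpers.
#' @export
simba_model <- function(dataset, spec) {
  design <- build_design(dataset, spec)
  fwd <- srtm_batch_prep(design$ref_list, design$frames)
  m <- length(spec$parameters)
  n_sub <- length(design$subjects)
  n_reg <- length(design$regions)
  n_tac <- nrow(design$keys)
  H <- ncol(design$Y)
  mc2 <- m * (m - 1) / 2
  kbb <- ncol(design$B)
  n_slope <- length(design$slope_params)
  use_cov <- isTRUE(spec$sigma$covariates)
  use_ssub <- isTRUE(spec$sigma$subject_dev)
  use_sreg <- isTRUE(spec$sigma$region_dev)
  pr <- spec$priors
  mu_s0 <- pr$sigma$intercept_mean
  if (is.na(mu_s0)) mu_s0 <- log(0.05 * mean(apply(design$Y, 1, max)))

  # parameter index registry
  idx <- list(); pos <- 0L
  take <- function(n) { out <- pos + seq_len(n); pos <<- pos + n; out }
  idx$alpha <- take(m)
  idx$beta <- lapply(spec$parameters, function(p) take(ncol(design$X[[p]])))
  names(idx$beta) <- spec$parameters
  tac_fixed <- isTRUE(pr$tac_sd_fixed)
  idx$z_sub <- take(n_sub * m); idx$z_reg <- take(n_reg * m)
  idx$z_tac <- take(n_tac * m)
  idx$usd_sub <- take(m); idx$usd_reg <- take(m)
  idx$usd_tac <- if (tac_fixed) integer(0) else take(m)
  idx$y_sub <- take(mc2); idx$y_reg <- take(mc2); idx$y_tac <- take(mc2)
  if (n_slope) {
    idx$z_slope <- take(n_reg * n_slope)
    idx$usd_slope <- take(n_slope)
  }
  idx$sig0 <- take(1)
  if (use_cov) idx$sig_gamma <- take(3)
  idx$sig_spline <- take(kbb)
  if (use_ssub) { idx$z_sig_sub <- take(n_sub); idx$usd_sig_sub <- take(1) }
  if (use_sreg) { idx$z_sig_reg <- take(n_reg); idx$usd_sig_reg <- take(1) }
  P <- pos

  sd_scales <- function(which) {
    s <- pr[[paste0("sd_", which)]]
    unname(s[spec$parameters])
  }
  s_sub <- sd_scales("subject"); s_reg <- sd_scales("region")
  s_tac <- sd_scales("tac")
  mu0 <- unname(pr$intercept_mean[spec$parameters])
  if (anyNA(mu0)) {
    mu0[is.na(mu0)] <- ifelse(spec$parameters[is.na(mu0)] == "logk4",
                              pr$k4_prior[["mean"]], 0)
  }

  param_names <- c(
    paste0("alpha_", spec$parameters),
    unlist(lapply(spec$parameters, function(p) {
      cn <- colnames(design$X[[p]])
      if (length(cn)) paste0("beta_", p, "_", cn) else character(0)
    })),
    paste0("z_sub_", rep(seq_len(n_sub), m), "_", rep(spec$parameters, each = n_sub)),
    paste0("z_reg_", rep(seq_len(n_reg), m), "_", rep(spec$parameters, each = n_reg)),
    paste0("z_tac_", rep(seq_len(n_tac), m), "_", rep(spec$parameters, each = n_tac)),
    paste0("log_sd_subject_", spec$parameters),
    paste0("log_sd_region_", spec$parameters),
    if (!tac_fixed) paste0("log_sd_tac_", spec$parameters),
    paste0("corr_subject_", seq_len(mc2)),
    paste0("corr_region_", seq_len(mc2)),
    paste0("corr_tac_", seq_len(mc2)),
    if (n_slope) c(paste0("z_slope_", rep(seq_len(n_reg), n_slope), "_",
                          rep(design$slope_params, each = n_reg)),
                   paste0("log_sd_slope_", design$slope_params)),
    "sigma_intercept",
    if (use_cov) c("sigma_b_logdur", "sigma_b_logvol", "sigma_b_logdose"),
    paste0("sigma_spline_", seq_len(kbb)),
    if (use_ssub) c(paste0("z_sigma_sub_", seq_len(n_sub)), "log_sd_sigma_subject"),
    if (use_sreg) c(paste0("z_sigma_reg_", seq_len(n_reg)), "log_sd_sigma_region"))
  stopifnot(length(param_names) == P)

  eta_of <- function(v) {
    alpha <- v[idx$alpha]
    dev <- function(zi, n_b, sd, y_i) {
      Z <- matrix(v[zi], n_b, m)
      fw <- corr_chol_forward(v[y_i], m, pr$lkj_eta)
      S <- fw$L * sd          # diag(sd) %*% L
      Z %*% t(S)
    }
    dev_sub <- dev(idx$z_sub, n_sub, exp(v[idx$usd_sub]), idx$y_sub)
    dev_reg <- dev(idx$z_reg, n_reg, exp(v[idx$usd_reg]), idx$y_reg)
    dev_tac <- dev(idx$z_tac, n_tac,
                   if (tac_fixed) s_tac else exp(v[idx$usd_tac]), idx$y_tac)
    eta <- matrix(0, n_tac, m)
    for (i in seq_len(m)) {
      p <- spec$parameters[i]
      eta[, i] <- alpha[i] + dev_sub[design$sub_idx, i] +
        dev_reg[design$reg_idx, i] + dev_tac[, i]
      if (ncol(design$X[[p]])) {
        eta[, i] <- eta[, i] + drop(design$X[[p]] %*% v[idx$beta[[p]]])
      }
    }
    if (n_slope) {
      sd_sl <- exp(v[idx$usd_slope])
      Zs <- matrix(v[idx$z_slope], n_reg, n_slope)
      for (s in seq_len(n_slope)) {
        i <- match(design$slope_params[s], spec$parameters)
        eta[, i] <- eta[, i] +
          sd_sl[s] * Zs[design$reg_idx, s] * design$age_dec
      }
    }
    colnames(eta) <- spec$parameters
    eta
  }

  logsig_of <- function(v) {
    sig_frame <- drop(design$B %*% v[idx$sig_spline])
    sig_tac <- rep(v[idx$sig0], n_tac)
    if (use_cov) {
      g <- v[idx$sig_gamma]
      sig_frame <- sig_frame + g[1] * design$clogdur
      sig_tac <- sig_tac + g[2] * design$clogvol + g[3] * design$clogdose
    }
    if (use_ssub) {
      sig_tac <- sig_tac +
        (exp(v[idx$usd_sig_sub]) * v[idx$z_sig_sub])[design$sub_idx]
    }
    if (use_sreg) {
      sig_tac <- sig_tac +
        (exp(v[idx$usd_sig_reg]) * v[idx$z_sig_reg])[design$reg_idx]
    }
    outer(sig_tac, rep(1, H)) + matrix(sig_frame, n_tac, H, byrow = TRUE)
  }

  lp_grad <- function(v, want_pointwise = FALSE) {
    g <- numeric(P)
    alpha <- v[idx$alpha]
    # deviation blocks
    blocks <- list(
      sub = list(z = idx$z_sub, usd = idx$usd_sub, y = idx$y_sub,
                 n = n_sub, scale = s_sub, fixed = FALSE,
                 map = design$sub_idx),
      reg = list(z = idx$z_reg, usd = idx$usd_reg, y = idx$y_reg,
                 n = n_reg, scale = s_reg, fixed = FALSE,
                 map = design$reg_idx),
      tac = list(z = idx$z_tac, usd = idx$usd_tac, y = idx$y_tac,
                 n = n_tac, scale = s_tac, fixed = tac_fixed,
                 map = seq_len(n_tac)))
    lp <- 0
    bstate <- list()
    for (b in names(blocks)) {
      bl <- blocks[[b]]
      Z <- matrix(v[bl$z], bl$n, m)
      sd <- if (bl$fixed) bl$scale else exp(v[bl$usd])
      fw <- corr_chol_forward(v[bl$y], m, pr$lkj_eta)
      S <- fw$L * sd
      bstate[[b]] <- list(Z = Z, sd = sd, fw = fw, S = S,
                          dev = Z %*% t(S))
      lp <- lp - 0.5 * sum(Z^2) + fw$log_extra
      if (!bl$fixed) {
        lp <- lp + sum(-sd^2 / (2 * bl$scale^2) + v[bl$usd])
      }
    }
    eta <- matrix(0, n_tac, m)
    for (i in seq_len(m)) {
      p <- spec$parameters[i]
      eta[, i] <- alpha[i] + bstate$sub$dev[design$sub_idx, i] +
        bstate$reg$dev[design$reg_idx, i] + bstate$tac$dev[, i]
      if (ncol(design$X[[p]])) {
        eta[, i] <- eta[, i] + drop(design$X[[p]] %*% v[idx$beta[[p]]])
      }
    }
    if (n_slope) {
      sd_sl <- exp(v[idx$usd_slope])
      Zs <- matrix(v[idx$z_slope], n_reg, n_slope)
      for (s in seq_len(n_slope)) {
        i <- match(design$slope_params[s], spec$parameters)
        eta[, i] <- eta[, i] + sd_sl[s] * Zs[design$reg_idx, s] * design$age_dec
      }
      lp <- lp - 0.5 * sum(Zs^2) +
        sum(-sd_sl^2 / (2 * pr$sigma$age_slope_sd^2) + v[idx$usd_slope])
    }
    # forward model with parameter Jacobian
    fg <- if (spec$model == "srtm") {
      srtm_batch_grad(fwd, eta[, 1], eta[, 2], eta[, 3])
    } else {
      frtm_batch_grad(fwd, eta[, 1], eta[, 2], eta[, 3], eta[, 4])
    }
    if (!all(is.finite(fg$mu))) {
      return(list(lp = -Inf, grad = g))
    }
    logsig <- logsig_of(v)
    sigma2 <- exp(2 * logsig)
    resid <- design$Y - fg$mu
    loglik_obs <- -0.5 * log(2 * pi) - logsig - 0.5 * resid^2 / sigma2
    loglik <- sum(loglik_obs)
    lp <- lp + loglik
    # priors on alpha, beta, sigma parameters
    lp <- lp - sum((alpha - mu0)^2) / (2 * pr$intercept_sd^2)
    for (p in spec$parameters) {
      if (length(idx$beta[[p]])) {
        lp <- lp - sum((v[idx$beta[[p]]] / design$coef_sds[[p]])^2) / 2
      }
    }
    lp <- lp - (v[idx$sig0] - mu_s0)^2 / (2 * pr$sigma$intercept_sd^2)
    if (use_cov) lp <- lp - sum(v[idx$sig_gamma]^2) / (2 * pr$sigma$coef_sd^2)
    lp <- lp - sum(v[idx$sig_spline]^2) / (2 * pr$sigma$spline_sd^2)
    if (use_ssub) {
      sds <- exp(v[idx$usd_sig_sub])
      lp <- lp - 0.5 * sum(v[idx$z_sig_sub]^2) -
        sds^2 / (2 * pr$sigma$sd_subject^2) + v[idx$usd_sig_sub]
    }
    if (use_sreg) {
      sds <- exp(v[idx$usd_sig_reg])
      lp <- lp - 0.5 * sum(v[idx$z_sig_reg]^2) -
        sds^2 / (2 * pr$sigma$sd_region^2) + v[idx$usd_sig_reg]
    }

    # --- gradients ---
    gmu <- resid / sigma2
    g_logsig <- resid^2 / sigma2 - 1
    g_eta <- matrix(0, n_tac, m)
    for (i in seq_len(m)) g_eta[, i] <- rowSums(gmu * fg$dmu[[i]])
    g[idx$alpha] <- colSums(g_eta) - (alpha - mu0) / pr$intercept_sd^2
    for (i in seq_len(m)) {
      p <- spec$parameters[i]
      if (length(idx$beta[[p]])) {
        g[idx$beta[[p]]] <- drop(crossprod(design$X[[p]], g_eta[, i])) -
          v[idx$beta[[p]]] / design$coef_sds[[p]]^2
      }
    }
    Gb <- list(sub = rowsum(g_eta, design$sub_idx, reorder = TRUE),
               reg = rowsum(g_eta, design$reg_idx, reorder = TRUE),
               tac = g_eta)
    for (b in names(blocks)) {
      bl <- blocks[[b]]; st <- bstate[[b]]
      G <- Gb[[b]]
      gS <- crossprod(G, st$Z)               # m x m
      gZ <- G %*% st$S - st$Z
      g[bl$z] <- as.numeric(gZ)
      if (!bl$fixed) {
        g_sd <- rowSums(gS * st$fw$L)
        g[bl$usd] <- g_sd * st$sd + (1 - st$sd^2 / bl$scale^2)
      }
      gL <- gS * st$sd                        # row-scaled by sd
      g[bl$y] <- corr_chol_backward(st$fw, gL)
    }
    if (n_slope) {
      for (s in seq_len(n_slope)) {
        i <- match(design$slope_params[s], spec$parameters)
        gdev <- rowsum(g_eta[, i] * design$age_dec, design$reg_idx,
                       reorder = TRUE)[, 1]
        g[idx$z_slope[(s - 1) * n_reg + seq_len(n_reg)]] <-
          gdev * sd_sl[s] - Zs[, s]
        g[idx$usd_slope[s]] <- sum(gdev * Zs[, s]) * sd_sl[s] +
          (1 - sd_sl[s]^2 / pr$sigma$age_slope_sd^2)
      }
    }
    rs <- rowSums(g_logsig); cs <- colSums(g_logsig)
    g[idx$sig0] <- sum(rs) - (v[idx$sig0] - mu_s0) / pr$sigma$intercept_sd^2
    if (use_cov) {
      g[idx$sig_gamma] <- c(sum(cs * design$clogdur),
                            sum(rs * design$clogvol),
                            sum(rs * design$clogdose)) -
        v[idx$sig_gamma] / pr$sigma$coef_sd^2
    }
    g[idx$sig_spline] <- drop(crossprod(design$B, cs)) -
      v[idx$sig_spline] / pr$sigma$spline_sd^2
    if (use_ssub) {
      sds <- exp(v[idx$usd_sig_sub])
      gdev <- rowsum(rs, design$sub_idx, reorder = TRUE)[, 1]
      g[idx$z_sig_sub] <- gdev * sds - v[idx$z_sig_sub]
      g[idx$usd_sig_sub] <- sum(gdev * v[idx$z_sig_sub]) * sds +
        (1 - sds^2 / pr$sigma$sd_subject^2)
    }
    if (use_sreg) {
      sds <- exp(v[idx$usd_sig_reg])
      gdev <- rowsum(rs, design$reg_idx, reorder = TRUE)[, 1]
      g[idx$z_sig_reg] <- gdev * sds - v[idx$z_sig_reg]
      g[idx$usd_sig_reg] <- sum(gdev * v[idx$z_sig_reg]) * sds +
        (1 - sds^2 / pr$sigma$sd_region^2)
    }
    out <- list(lp = lp, grad = g, loglik = loglik)
    if (want_pointwise) {
      out$loglik_obs <- loglik_obs
      out$mu <- fg$mu
      out$logsig <- logsig
      out$eta <- eta
    }
    out
  }

  init_vector <- function() {
    v <- numeric(P)
    v[idx$alpha] <- mu0
    v[idx$usd_sub] <- log(s_sub / 2)
    v[idx$usd_reg] <- log(s_reg / 2)
    if (!tac_fixed) v[idx$usd_tac] <- log(s_tac / 2)
    if (n_slope) v[idx$usd_slope] <- log(pr$sigma$age_slope_sd / 2)
    v[idx$sig0] <- mu_s0
    if (use_ssub) v[idx$usd_sig_sub] <- log(pr$sigma$sd_subject / 2)
    if (use_sreg) v[idx$usd_sig_reg] <- log(pr$sigma$sd_region / 2)
    v
  }

  structure(
    list(design = design, spec = spec, fwd = fwd, idx = idx, P = P,
         param_names = param_names, lp_grad = lp_grad, eta_of = eta_of,
         logsig_of = logsig_of, init_vector = init_vector, mu_s0 = mu_s0,
         m = m, n_tac = n_tac, n_obs = n_tac * H),
    class = "simba_model")
}

#' Evaluate the joint log posterior of a prepared model
#'
#' Returns the log posterior density, the data log likelihood (the sum of
#' per-frame normal log densities with the kinetic prediction as mean and
#' the structured sigma model as SD) and, optionally, pointwise
#' per-observation log likelihoods, at an unconstrained parameter vector.
#'
#' @param model a [simba_model()].
#' @param v unconstrained parameter vector (defaults to the model's
#'   initialisation point: all deviations zero, intercepts at their prior
#'   means).
#' @param pointwise also return the per-observation log-likelihood matrix.
#' @return List with `lp`, `loglik`, `grad` and optionally `loglik_obs`,
#'   `mu`, `logsig`, `eta`.
#' @export
simba_log_density <- function(model, v = model$init_vector(),
                              pointwise = FALSE) {
  stopifnot(inherits(model, "simba_model"))
  if (length(v) != model$P) {
    stopf("parameter vector has length %d; model has %d parameters",
          length(v), model$P)
  }
  model$lp_grad(v, want_pointwise = pointwise)
}
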