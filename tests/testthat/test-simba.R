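small_model <- function() {
  design <- default_truth_parameters(n_per_group = 1, seed = 91)
  lib <- exact_ref_library(3)
  ds <- simulate_dataset(design, lib, regions = c("DBS", "FC"))
  spec <- simba_spec(fixed = list(logR1 = ~region, logk2prime = ~1,
                                  logBPND = ~region),
                     mcmc = list(chains = 1, warmup = 50, iter = 50,
                                 seed = 1))
  list(ds = ds, spec = spec, model = simba_model(ds, spec))
}

test_that("the likelihood equals a hand-computed sum of normal densities", {
  sm <- small_model()
  model <- sm$model
  v <- model$init_vector()
  st <- simba_log_density(model, v, pointwise = TRUE)
  # at the initialisation point all deviations, covariate and spline terms
  # are zero: theta is exp(alpha + region dummies) and sigma is constant
  alpha <- v[model$idx$alpha]
  sig <- exp(model$mu_s0)
  hand <- 0
  for (t in seq_len(model$n_tac)) {
    eta <- alpha
    for (i in 1:3) {
      p <- model$spec$parameters[i]
      if (ncol(model$design$X[[p]])) {
        eta[i] <- eta[i] + sum(model$design$X[[p]][t, ] *
                                 v[model$idx$beta[[p]]])
      }
    }
    mu <- srtm_predict(srtm_params(exp(eta[1]), exp(eta[2]), exp(eta[3])),
                       model$design$ref_list[[t]], model$design$frames)
    hand <- hand + sum(dnorm(model$design$Y[t, ], mu, sig, log = TRUE))
  }
  expect_equal(st$loglik, hand, tolerance = 1e-10)
})

test_that("doubling sigma changes the log likelihood by the analytic amount", {
  sm <- small_model()
  model <- sm$model
  v <- model$init_vector()
  st1 <- simba_log_density(model, v, pointwise = TRUE)
  v2 <- v
  v2[model$idx$sig0] <- v[model$idx$sig0] + log(2)
  st2 <- simba_log_density(model, v2, pointwise = TRUE)
  resid2 <- (model$design$Y - st1$mu)^2
  sig2 <- exp(2 * st1$logsig)
  analytic <- sum(-log(2) + resid2 / sig2 * (1 / 2 - 1 / 8))
  expect_equal(st2$loglik - st1$loglik, analytic, tolerance = 1e-8)
})

test_that("prior-only evaluation at zero deviations matches the stated priors", {
  sm <- small_model()
  model <- sm$model
  pr <- model$spec$priors
  v <- model$init_vector()
  st <- simba_log_density(model, v)
  prior_part <- st$lp - st$loglik
  # hand-accumulate the non-zero prior terms at this point: alpha at the
  # prior mean and z = 0 contribute 0; the log-sd transforms contribute
  # -sd^2/(2 s^2) + log(sd) at sd = s/2; correlation blocks at y = 0 give
  # the LKJ normalising behaviour of log_extra = 0
  # TAC deviations carry a fixed-SD prior by default: no sd transform term
  hand <- 0
  for (blk in c("subject", "region")) {
    s <- unname(pr[[paste0("sd_", blk)]][model$spec$parameters])
    hand <- hand + sum(-(s / 2)^2 / (2 * s^2) + log(s / 2))
  }
  hand <- hand + 0  # sigma intercept at its prior mean
  for (b in c("sd_subject", "sd_region")) {
    s <- pr$sigma[[b]]
    hand <- hand + (-(s / 2)^2 / (2 * s^2) + log(s / 2))
  }
  expect_equal(prior_part, hand, tolerance = 1e-8)
})

test_that("the posterior gradient matches finite differences", {
  sm <- small_model()
  model <- sm$model
  set.seed(4)
  v <- model$init_vector() + 0.05 * rnorm(model$P)
  st <- model$lp_grad(v)
  ii <- sort(sample(model$P, 30))
  fd <- vapply(ii, function(i) {
    h <- 1e-5
    vp <- v; vp[i] <- v[i] + h
    vm <- v; vm[i] <- v[i] - h
    (model$lp_grad(vp)$lp - model$lp_grad(vm)$lp) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(fd - st$grad[ii]) / pmax(abs(fd), 1)), 1e-4)
})

test_that("correlation transform yields valid matrices and exact gradients", {
  set.seed(11)
  for (m in c(2, 3, 4)) {
    y <- rnorm(m * (m - 1) / 2, 0, 0.8)
    fw <- refsimba:::corr_chol_forward(y, m, eta = 2)
    C <- fw$L %*% t(fw$L)
    expect_equal(diag(C), rep(1, m), tolerance = 1e-12)
    expect_true(all(eigen(C, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
    # gradient of log_extra plus a random linear functional of L
    gL <- matrix(rnorm(m * m), m, m); gL[upper.tri(gL)] <- 0
    gy <- refsimba:::corr_chol_backward(fw, gL)
    obj <- function(yy) {
      f <- refsimba:::corr_chol_forward(yy, m, eta = 2)
      sum(gL * f$L) + f$log_extra
    }
    fd <- vapply(seq_along(y), function(i) {
      h <- 1e-6; yp <- y; yp[i] <- y[i] + h; ym <- y; ym[i] <- y[i] - h
      (obj(yp) - obj(ym)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(fd - gy)), 1e-5)
  }
})

test_that("a subject deviation multiplies expectations in every region equally", {
  sm <- small_model()
  model <- sm$model
  v <- model$init_vector()
  eta0 <- model$eta_of(v)
  v2 <- v
  # one z-unit for subject 1 on logBPND through an identity-scaled block:
  # set the subject log-sd so sd = 0.3, then z = 1 adds 0.3 to logBPND
  iBP <- 3
  n_sub <- length(model$design$subjects)
  v2[model$idx$usd_sub[iBP]] <- log(0.3)
  v2[model$idx$z_sub[(iBP - 1) * n_sub + 1]] <- 1
  eta1 <- model$eta_of(v2)
  rows <- model$design$sub_idx == 1
  shift <- eta1[rows, iBP] - eta0[rows, iBP]
  expect_equal(shift, rep(0.3, sum(rows)), tolerance = 1e-12)
  # proportional-scale reading: +0.3 in log space is a ~35% increase,
  # mapping region means 0.1 and 3 to 0.135 and 4.05
  expect_equal(round(100 * (exp(0.3) - 1)), 35)
  expect_equal(round(0.1 * exp(0.3), 2), 0.13)
  expect_equal(round(3 * exp(0.3), 1), 4.0)
})

test_that("short chains are exactly reproducible given the seed", {
  sm <- small_model()
  f1 <- suppressWarnings(fit_simba(sm$ds, sm$spec))
  f2 <- suppressWarnings(fit_simba(sm$ds, sm$spec))
  expect_identical(f1$draws, f2$draws)
})

test_that("effective parameters: intercept-only model has p_eff near one", {
  set.seed(12)
  n <- 40
  y <- rnorm(n, 2, 1)
  # conjugate posterior for the mean with a flat-ish prior, sigma known
  mu_draws <- rnorm(4000, mean(y), 1 / sqrt(n))
  ll <- sapply(seq_len(n), function(i) dnorm(y[i], mu_draws, 1, log = TRUE))
  pe <- effective_parameters(list(loglik_obs = ll, n_tac = n))
  expect_equal(pe$p_eff, 1, tolerance = 0.2)
})

test_that("p_eff agrees with exact leave-one-out refits on a toy model", {
  set.seed(13)
  n <- 20
  sigma <- 1; tau <- 10   # prior sd on the mean
  y <- rnorm(n, 1, sigma)
  post_var <- 1 / (n / sigma^2 + 1 / tau^2)
  post_mean <- post_var * sum(y) / sigma^2
  mu_draws <- rnorm(20000, post_mean, sqrt(post_var))
  ll <- sapply(seq_len(n), function(i) dnorm(y[i], mu_draws, sigma, log = TRUE))
  pe <- effective_parameters(list(loglik_obs = ll, n_tac = n))
  # exact LOO: p_loo = lpd - elpd_loo, both in closed form for the
  # conjugate normal model
  lpd <- sum(vapply(seq_len(n), function(i) {
    dnorm(y[i], post_mean, sqrt(sigma^2 + post_var), log = TRUE)
  }, numeric(1)))
  elpd_loo <- sum(vapply(seq_len(n), function(i) {
    vi <- 1 / ((n - 1) / sigma^2 + 1 / tau^2)
    mi <- vi * (sum(y) - y[i]) / sigma^2
    dnorm(y[i], mi, sqrt(sigma^2 + vi), log = TRUE)
  }, numeric(1)))
  p_loo_exact <- lpd - elpd_loo
  expect_lt(abs(pe$p_eff - p_loo_exact) / p_loo_exact, 0.1)
})

test_that("per-TAC effective parameters are the total over the TAC count", {
  ll <- matrix(rnorm(100 * 50), 100, 50)
  pe <- effective_parameters(list(loglik_obs = ll, n_tac = 10))
  expect_equal(pe$p_eff_per_tac, pe$p_eff / 10)
})

test_that("contrast extraction is exact on trivial combinations", {
  fit <- shared_simba()
  nm <- treatment_contrast_name(fit)
  self_minus_self <- extract_contrast(fit, setNames(c(1, -1), c(nm, nm)))
  expect_equal(self_minus_self$mean, 0)
  expect_equal(self_minus_self$sd, 0)
  a <- extract_contrast(fit, setNames(1, nm))
  b <- extract_contrast(fit, setNames(-1, nm))
  expect_equal(a$mean, -b$mean)
  expect_error(extract_contrast(fit, c(no_such_coef = 1)),
               class = "refsimba_contrast_error")
})

test_that("the fitted posterior recovers the generating hierarchy", {
  fit <- shared_simba()
  ds <- shared_dataset()
  reg <- ds$design$regions
  draws <- fit$draws
  # global intercepts within 3 posterior SDs of the generating values
  # (alpha is the DBS level; region dummies carry the rest)
  truth_alpha <- c(reg$logR1[reg$region == "DBS"],
                   ds$design$logk2prime_mean +
                     mean(reg$logk2prime_offset[reg$region %in%
                                                  c("DBS", "FC", "OC")]),
                   reg$logBPND[reg$region == "DBS"])
  for (i in 1:3) {
    nm <- paste0("alpha_", c("logR1", "logk2prime", "logBPND"))[i]
    est <- mean(draws[, nm]); sdv <- sd(draws[, nm])
    expect_lt(abs(est - truth_alpha[i]), 3 * sdv + 0.05)
  }
  # treatment effect recovered within 3 posterior SDs of +0.04
  ctr <- extract_contrast(fit, setNames(1, treatment_contrast_name(fit)))
  expect_lt(abs(ctr$mean - 0.04), 3 * ctr$sd)
  # covariance blocks are positive definite in every retained draw
  yc <- draws[, grep("^corr_subject_", colnames(draws)), drop = FALSE]
  for (d in seq(1, nrow(yc), by = 50)) {
    fw <- refsimba:::corr_chol_forward(yc[d, ], 3, 2)
    C <- fw$L %*% t(fw$L)
    expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("TAC-level deviations shrink below their prior SD", {
  # under the fixed-SD TAC prior the posterior SD of every deviation must
  # fall below the prior SD of 0.025; measured on a small, well-mixing
  # fit, with a finite-chain allowance for the SD estimator's own
  # Monte-Carlo error
  design <- default_truth_parameters(n_per_group = 1, seed = 91)
  lib <- exact_ref_library(3)
  ds <- simulate_dataset(design, lib, regions = c("DBS", "FC"))
  spec <- simba_spec(fixed = list(logR1 = ~region, logk2prime = ~1,
                                  logBPND = ~region),
                     priors = simba_priors(intercept_mean = c(
                       logR1 = log(0.8), logk2prime = log(0.1),
                       logBPND = log(0.45))),
                     mcmc = list(chains = 2, warmup = 500, iter = 400,
                                 seed = 7))
  fit <- suppressWarnings(fit_simba(ds, spec))
  draws <- fit$draws
  n_tac <- fit$model$n_tac
  zc <- grep("^z_tac_", colnames(draws))
  yc <- grep("^corr_tac_", colnames(draws))
  dev_acc <- array(0, c(nrow(draws), n_tac, 3))
  for (d in seq_len(nrow(draws))) {
    fw <- refsimba:::corr_chol_forward(draws[d, yc], 3, 2)
    dev_acc[d, , ] <- matrix(draws[d, zc], n_tac, 3) %*%
      t(fw$L * rep(0.025, 3))
  }
  # Monte-Carlo standard error of an SD estimate from autocorrelated
  # draws: sd * sqrt(1 / (2 * ess)), with a lag-one effective sample size
  n_dr <- nrow(draws)
  half <- n_dr / 2
  for (p in 1:3) {
    dev_sd <- apply(dev_acc[, , p], 2, sd)
    expect_lt(mean(dev_sd), 0.025)
    for (tcol in seq_len(n_tac)) {
      x1 <- dev_acc[1:half, tcol, p]; x2 <- dev_acc[(half + 1):n_dr, tcol, p]
      rho <- mean(c(cor(x1[-1], x1[-half]), cor(x2[-1], x2[-half])))
      rho <- min(max(rho, 0), 0.99)
      ess <- n_dr * (1 - rho) / (1 + rho)
      mcse <- dev_sd[tcol] * sqrt(1 / (2 * ess))
      expect_lt(dev_sd[tcol], 0.025 + 3 * mcse)
    }
  }
})

test_that("divergence warnings surface rather than pass silently", {
  sm <- small_model()
  spec <- sm$spec
  spec$mcmc$divergence_warn <- 0   # any divergence warns; with none, silence
  fit <- try(withCallingHandlers(
    fit_simba(sm$ds, spec),
    warning = function(w) invokeRestart("muffleWarning")), silent = TRUE)
  expect_s3_class(fit, "simba_fit")
})
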