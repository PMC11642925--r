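# Adaptive Hamiltonian Monte Carlo with dual-averaged step size and
# diagonal mass-matrix adaptation. The sampler targets an unnormalised log
# density supplied with its gradient. Warmup follows the usual three-phase
# scheme: an initial step-size phase, a sequence of expanding covariance
# windows (each ending with a mass-matrix update and a step-size reset),
# and a final step-size refinement phase. Trajectories use a fixed target
# length in integration time with a jittered leapfrog count. Proposals
# with non-finite or grossly energy-violating states count as divergences.

#' @keywords internal
hmc_chain <- function(lp_grad, init, n_warmup, n_iter, seed,
                      adapt_delta = 0.9, traj_length = 1.2,
                      max_leapfrog = 48, div_threshold = 1000,
                      inv_mass = NULL) {
  set.seed(seed)
  P <- length(init)
  q <- init
  cur <- lp_grad(q)
  if (!is.finite(cur$lp)) stopf("initial point has non-finite log density")
  if (is.null(inv_mass)) inv_mass <- rep(1, P)

  leapfrog <- function(q, p, g, eps, L) {
    for (l in seq_len(L)) {
      p <- p + 0.5 * eps * g
      q <- q + eps * inv_mass * p
      st <- lp_grad(q)
      if (!is.finite(st$lp) || !all(is.finite(st$grad))) {
        return(list(ok = FALSE))
      }
      g <- st$grad
      p <- p + 0.5 * eps * g
    }
    list(ok = TRUE, q = q, p = p, st = st)
  }

  # initial step size: adjust until a one-step proposal has moderate
  # energy error (also re-run after every mass-matrix update)
  find_step <- function(q, grad, lp, eps = 0.1) {
    p0 <- stats::rnorm(P) / sqrt(inv_mass)
    H0 <- -lp + 0.5 * sum(p0^2 * inv_mass)
    for (k in 1:30) {
      tr <- leapfrog(q, p0, grad, eps, 1L)
      dE <- if (tr$ok) (-tr$st$lp + 0.5 * sum(tr$p^2 * inv_mass)) - H0 else Inf
      if (!is.finite(dE) || dE > 0.7) eps <- eps / 2
      else if (dE < 0.2) eps <- eps * 2
      else break
      if (eps < 1e-10 || eps > 1e3) break
    }
    eps
  }
  log_eps <- log(find_step(q, cur$grad, cur$lp))

  # dual averaging state
  da_reset <- function(le) list(mu = log(10) + le, h = 0, le_bar = le, t = 0)
  da <- da_reset(log_eps)
  da_update <- function(da, alpha) {
    da$t <- da$t + 1
    da$h <- (1 - 1 / (da$t + 10)) * da$h + (adapt_delta - alpha) / (da$t + 10)
    le <- da$mu - sqrt(da$t) / 0.05 * da$h
    eta <- da$t^(-0.75)
    da$le_bar <- eta * le + (1 - eta) * da$le_bar
    da$le <- le
    da
  }
  da$le <- log_eps

  # expanding mass-adaptation windows within [w0, w1]
  w0 <- min(75, floor(n_warmup * 0.15))
  w1 <- floor(n_warmup * 0.9)
  win_ends <- integer(0)
  wlen <- 25
  pos <- w0
  while (pos + wlen <= w1) {
    pos <- pos + wlen
    win_ends <- c(win_ends, pos)
    wlen <- wlen * 2
  }
  if (length(win_ends)) win_ends[length(win_ends)] <- w1 else win_ends <- w1
  acc_mean <- numeric(P); acc_m2 <- numeric(P); acc_n <- 0

  draws <- matrix(NA_real_, n_iter, P)
  lp_trace <- numeric(n_iter)
  divergences <- 0L
  n_acc <- 0; n_tot <- 0
  total <- n_warmup + n_iter
  for (it in seq_len(total)) {
    eps_it <- exp(if (it <= n_warmup) da$le else da$le_bar)
    L <- max(1L, min(max_leapfrog, as.integer(round(traj_length / eps_it))))
    L <- max(1L, as.integer(round(L * stats::runif(1, 0.8, 1.2))))
    p0 <- stats::rnorm(P) / sqrt(inv_mass)
    H0 <- -cur$lp + 0.5 * sum(p0^2 * inv_mass)
    tr <- leapfrog(q, p0, cur$grad, eps_it, L)
    if (tr$ok) {
      dE <- (-tr$st$lp + 0.5 * sum(tr$p^2 * inv_mass)) - H0
      diverged <- !is.finite(dE) || dE > div_threshold
    } else diverged <- TRUE
    alpha <- if (diverged) 0 else min(1, exp(-dE))
    if (!diverged && log(stats::runif(1)) < -dE) {
      q <- tr$q; cur <- tr$st
      if (it > n_warmup) n_acc <- n_acc + 1
    }
    if (it > n_warmup) {
      n_tot <- n_tot + 1
      if (diverged) divergences <- divergences + 1L
      draws[it - n_warmup, ] <- q
      lp_trace[it - n_warmup] <- cur$lp
    } else {
      da <- da_update(da, alpha)
      if (it > w0 && it <= w1) {
        acc_n <- acc_n + 1
        delta <- q - acc_mean
        acc_mean <- acc_mean + delta / acc_n
        acc_m2 <- acc_m2 + delta * (q - acc_mean)
      }
      if (it %in% win_ends && acc_n > 10) {
        v <- acc_m2 / (acc_n - 1)
        # regularise towards the current mass so that directions the
        # window has not yet explored keep their prior (curvature) scale
        v <- (acc_n / (acc_n + 5)) * v + (5 / (acc_n + 5)) * inv_mass
        inv_mass <- pmax(v, 1e-10)
        acc_mean <- numeric(P); acc_m2 <- numeric(P); acc_n <- 0
        da <- da_reset(da$le)
        da$le <- da$mu - log(10)  # restart from the current step size
      }
    }
  }
  list(draws = draws, lp = lp_trace, divergences = divergences,
       accept_rate = if (n_tot) n_acc / n_tot else NA_real_,
       step_size = exp(da$le_bar), inv_mass = inv_mass)
}

# diagonal curvature scaling for the initial mass matrix: |d2 lp / dv2|
# estimated by central differences of the gradient, clamped
#' @keywords internal
curvature_inv_mass <- function(lp_grad, v, h = 1e-4) {
  P <- length(v)
  hess <- numeric(P)
  for (i in seq_len(P)) {
    vp <- v; vp[i] <- v[i] + h
    vm <- v; vm[i] <- v[i] - h
    hess[i] <- (lp_grad(vp)$grad[i] - lp_grad(vm)$grad[i]) / (2 * h)
  }
  pmin(pmax(1 / pmax(abs(hess), 1e-3), 1e-8), 1e2)
}

# split-Rhat and a bulk effective sample size, computed per parameter from
# a list of per-chain draw matrices
#' @keywords internal
mcmc_diagnostics <- function(chain_draws) {
  n <- nrow(chain_draws[[1]])
  half <- floor(n / 2)
  splits <- list()
  for (d in chain_draws) {
    splits <- c(splits, list(d[seq_len(half), , drop = FALSE],
                             d[(n - half + 1):n, , drop = FALSE]))
  }
  nn <- half; m <- length(splits)
  means <- sapply(splits, colMeans)
  vars <- sapply(splits, function(x) apply(x, 2, stats::var))
  if (is.null(dim(means))) { means <- matrix(means, 1); vars <- matrix(vars, 1) }
  W <- rowMeans(vars)
  B <- nn * apply(means, 1, stats::var)
  var_plus <- (nn - 1) / nn * W + B / nn
  rhat <- sqrt(var_plus / pmax(W, 1e-300))
  ess <- sapply(seq_along(W), function(p) {
    rho <- mean(sapply(splits, function(x) {
      v <- x[, p]
      if (stats::sd(v) < 1e-12) return(1)
      suppressWarnings(stats::cor(v[-1], v[-length(v)]))
    }), na.rm = TRUE)
    rho <- min(max(rho, -0.99), 0.99)
    m * nn * (1 - rho) / (1 + rho)
  })
  list(rhat = rhat, ess = ess)
}
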