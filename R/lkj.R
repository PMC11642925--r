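# Cholesky-factor-of-correlation transform with LKJ prior, in the
# unconstrained parameterisation used by NUTS-style samplers: y (length
# m(m-1)/2) -> z = tanh(y) (canonical partial correlations) -> lower
# triangular L with unit-norm rows. log_extra accumulates the log Jacobian
# of the transform plus the LKJ(eta) log density on L, so that sampling the
# unconstrained y targets an LKJ(eta) correlation prior exactly.

#' @keywords internal
corr_chol_forward <- function(y, m, eta = 2) {
  L <- diag(m)
  z <- tanh(y)
  W <- matrix(1, m, m)  # W[i, j]: remaining squared norm before column j
  idx <- 0L
  log_extra <- 0
  for (i in seq_len(m)[-1]) {
    w <- 1
    for (j in seq_len(i - 1)) {
      idx <- idx + 1L
      W[i, j] <- w
      L[i, j] <- z[idx] * sqrt(w)
      log_extra <- log_extra + 0.5 * log(w) + log1p(-z[idx]^2)
      w <- w * (1 - z[idx]^2)
    }
    L[i, i] <- sqrt(w)
    log_extra <- log_extra + (m - i + 2 * eta - 2) * log(L[i, i])
  }
  list(L = L, z = z, W = W, log_extra = log_extra, m = m, eta = eta)
}

# reverse pass: gL is the gradient of the downstream objective w.r.t. L;
# returns the gradient w.r.t. the unconstrained y, including the gradient
# of log_extra itself.
#' @keywords internal
corr_chol_backward <- function(fw, gL) {
  m <- fw$m; z <- fw$z; W <- fw$W; L <- fw$L; eta <- fw$eta
  gy <- numeric(length(z))
  idx_base <- cumsum(c(0, seq_len(m - 1) - 1))  # start index per row i (i>=2)
  for (i in seq_len(m)[-1]) {
    nj <- i - 1
    row_idx <- idx_base[i - 1 + 1] + seq_len(nj)  # positions of row i's y
    # recompute w sequence forward
    wv <- W[i, seq_len(nj)]
    # gradient w.r.t. final w (through L[i,i] and the LKJ prior term)
    gw <- gL[i, i] * 0.5 / L[i, i] +
      (m - i + 2 * eta - 2) * (0.5 / L[i, i]^2)  # d log L_ii / d w = 1/(2 w)
    gz <- numeric(nj)
    for (j in rev(seq_len(nj))) {
      zj <- z[row_idx[j]]; wj <- wv[j]
      # w_next = wj * (1 - zj^2)
      gz[j] <- gz[j] + gw * (-2 * zj * wj)
      gw_prev <- gw * (1 - zj^2)
      # L[i, j] = zj * sqrt(wj)
      gz[j] <- gz[j] + gL[i, j] * sqrt(wj)
      gw_prev <- gw_prev + gL[i, j] * zj * 0.5 / sqrt(wj)
      # log_extra terms: 0.5 log(wj) + log(1 - zj^2)
      gw_prev <- gw_prev + 0.5 / wj
      gz[j] <- gz[j] - 2 * zj / (1 - zj^2)
      gw <- gw_prev
    }
    # gw now is gradient w.r.t. w_0 = 1 (constant): discard
    gy[row_idx] <- gz * (1 - z[row_idx]^2)
  }
  gy
}
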