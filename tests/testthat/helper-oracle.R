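# Independent numeric-convolution oracle: trapezoidal integration on a
# fine grid, with the integration split at the integrand's onset kink so
# the quadrature error stays second order.
num_conv_at <- function(f, g, tout, t0 = 0, dt = 0.001) {
  sapply(tout, function(t) {
    if (t <= t0) return(0)
    trap <- function(a, b) {
      if (b - a < dt) {
        s <- c(a, b)
      } else {
        s <- seq(a, b, by = dt)
        if (s[length(s)] < b) s <- c(s, b)
      }
      v <- f(s) * g(t - s)
      sum((v[-1] + v[-length(v)]) * diff(s) / 2)
    }
    kink <- t - t0   # where g's argument crosses the onset of f... and f's own onset
    pieces <- sort(unique(pmin(pmax(c(0, t0, kink, t), 0), t)))
    total <- 0
    for (k in seq_len(length(pieces) - 1)) {
      total <- total + trap(pieces[k], pieces[k + 1])
    }
    total
  })
}

# reference library with exact "estimated" parameters (no refit), for tests
# that need the simulator but not the reference-refit machinery
exact_ref_library <- function(n = 8, frames = default_frames()) {
  base <- default_reference_params()
  entries <- lapply(seq_len(n), function(i) {
    p <- base[[(i - 1) %% length(base) + 1]]
    list(true_params = p, true_curve = feng1tc_predict(p, frames),
         measured_curve = NULL, estimated_params = p, underfit_flag = FALSE)
  })
  structure(list(entries = entries, frames = frames, n_regenerated = 0L),
            class = "ref_library")
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-8)), tol)
}
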