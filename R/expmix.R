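#' Exponential-mixture curves with onset
#'
#' The analytic carrier for all kinetic curves in the package: a finite sum
#' of terms \eqn{c \, (t - t_0)^p \, e^{-\lambda (t - t_0)}} (with integer
#' power \eqn{p \ge 0}), defined to be zero for \eqn{t \le t_0}. This family
#' contains the Feng input shape, is closed under scaling and addition (at a
#' common onset), and — crucially — is closed under convolution with a single
#' exponential, which is what makes the reference-tissue model predictions
#' available in closed form rather than by slow numerical convolution.
#'
#' @param coef,rate,tpow parallel vectors of term coefficients, decay rates
#'   (1/min, `rate >= 0`) and integer powers of `(t - t0)`.
#' @param t0 onset time (minutes); the curve is identically zero at or
#'   before `t0`.
#' @return An object of class `expmix`.
#' @seealso [conv_with_exp()], [eval_expmix()]
#' @export
expmix <- function(coef = numeric(0), rate = numeric(0), tpow = integer(0),
                   t0 = 0) {
  coef <- as.numeric(coef); rate <- as.numeric(rate)
  tpow <- as.integer(tpow)
  if (length(coef) != length(rate) || length(coef) != length(tpow)) {
    stopf("coef, rate and tpow must have equal length")
  }
  assert_finite(c(coef, rate, t0), "expmix terms")
  if (any(rate < 0)) stopf("rates must be >= 0", class = "refsimba_invalid_rate")
  if (any(tpow < 0)) stopf("powers must be >= 0")
  structure(list(coef = coef, rate = rate, tpow = tpow, t0 = t0),
            class = "expmix")
}

#' @export
print.expmix <- function(x, ...) {
  cat(sprintf("<expmix: %d terms, t0 = %.3g min>\n", length(x$coef), x$t0))
  invisible(x)
}

#' Evaluate an exponential-mixture curve
#'
#' @param curve an [expmix()] object.
#' @param t numeric vector of times (minutes).
#' @return Numeric vector of curve values; zero wherever `t <= t0`.
#' @export
eval_expmix <- function(curve, t) {
  assert_finite(t, "t")
  u <- t - curve$t0
  out <- numeric(length(t))
  pos <- u > 0
  if (!any(pos) || length(curve$coef) == 0L) return(out)
  up <- u[pos]
  acc <- numeric(length(up))
  for (j in seq_along(curve$coef)) {
    acc <- acc + curve$coef[j] * up^curve$tpow[j] * exp(-curve$rate[j] * up)
  }
  out[pos] <- acc
  out
}

#' @keywords internal
expmix_scale <- function(curve, s) {
  curve$coef <- curve$coef * s
  curve
}

#' @keywords internal
expmix_add <- function(a, b) {
  if (abs(a$t0 - b$t0) > 1e-12) stopf("expmix addition requires a common onset")
  expmix(c(a$coef, b$coef), c(a$rate, b$rate), c(a$tpow, b$tpow), a$t0)
}

# Merge terms sharing (rate, tpow) and drop zero coefficients.
#' @keywords internal
expmix_simplify <- function(curve, drop_tol = 0) {
  if (length(curve$coef) == 0L) return(curve)
  key <- paste(signif(curve$rate, 14), curve$tpow)
  coef <- as.numeric(tapply(curve$coef, key, sum))
  idx <- match(names(tapply(curve$coef, key, sum)), key)
  keep <- abs(coef) > drop_tol
  expmix(coef[keep], curve$rate[idx][keep], curve$tpow[idx][keep], curve$t0)
}

#' Convolve an exponential-mixture curve with a single exponential
#'
#' Computes the exact convolution \eqn{(f \otimes e^{-\theta t})(t)} for an
#' [expmix()] curve `f`. Each term \eqn{c\,u^p e^{-\lambda u}} (with
#' \eqn{u = t - t_0}) convolves to
#' \deqn{c\,p!\,d^{-(p+1)} e^{-\theta u} -
#'       c\,p! \sum_{m=0}^{p} \frac{d^{m-p-1}}{m!} u^m e^{-\lambda u},
#'       \quad d = \lambda - \theta,}
#' and when the rates (numerically) coincide, \eqn{|d| < \epsilon}, the
#' repeated-root limit \eqn{c\,u^{p+1} e^{-\lambda u}/(p+1)} is used instead
#' of failing.
#'
#' @param curve an [expmix()] curve.
#' @param theta exponential rate (1/min), must be positive.
#' @param eps repeated-root tolerance on `|rate - theta|` (1/min).
#' @return The convolved curve, another [expmix()] with the same onset.
#' @export
conv_with_exp <- function(curve, theta, eps = 1e-6) {
  if (!is.finite(theta) || theta <= 0) {
    stopf("theta must be a positive finite rate", class = "refsimba_invalid_rate")
  }
  coef <- numeric(0); rate <- numeric(0); tpow <- integer(0)
  for (j in seq_along(curve$coef)) {
    cj <- curve$coef[j]; lj <- curve$rate[j]; pj <- curve$tpow[j]
    d <- lj - theta
    if (abs(d) < eps) {
      # repeated root: u^p e^{-l u} (x) e^{-l u} = u^{p+1} e^{-l u} / (p+1)
      coef <- c(coef, cj / (pj + 1))
      rate <- c(rate, lj)
      tpow <- c(tpow, pj + 1L)
    } else {
      fp <- factorial(pj)
      coef <- c(coef, cj * fp / d^(pj + 1))
      rate <- c(rate, theta)
      tpow <- c(tpow, 0L)
      m <- 0:pj
      coef <- c(coef, -cj * fp * d^(m - pj - 1) / factorial(m))
      rate <- c(rate, rep(lj, pj + 1))
      tpow <- c(tpow, as.integer(m))
    }
  }
  expmix_simplify(expmix(coef, rate, tpow, curve$t0))
}

# Exact frame-integral average of an expmix curve over [start, start+duration),
# used by the optional frame-averaging prediction convention.
#' @keywords internal
expmix_frame_average <- function(curve, frames) {
  a <- pmax(frames$start - curve$t0, 0)
  b <- pmax(frames$end - curve$t0, 0)
  total <- numeric(length(a))
  for (j in seq_along(curve$coef)) {
    cj <- curve$coef[j]; lj <- curve$rate[j]; pj <- curve$tpow[j]
    if (lj > 0) {
      # int_0^x u^p e^{-l u} du = p! / l^(p+1) * P(p+1, l x)
      seg <- factorial(pj) / lj^(pj + 1) *
        (stats::pgamma(lj * b, pj + 1) - stats::pgamma(lj * a, pj + 1))
    } else {
      seg <- (b^(pj + 1) - a^(pj + 1)) / (pj + 1)
    }
    total <- total + cj * seg
  }
  total / frames$duration
}
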