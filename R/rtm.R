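#' SRTM parameters
#'
#' The simplified reference tissue model is parameterised here by the
#' relative delivery `R1` (unitless), the reference-region clearance
#' `k2prime` (1/min) and the binding potential `BPND` (unitless). `k2prime`
#' rather than `k2` is chosen as the estimated quantity because it is a
#' property of the reference tissue, shared in theory across regions, which
#' makes pooling it towards a common mean well justified. Derived rates are
#' `k2 = R1 * k2prime` and `k2a = k2 / (1 + BPND)`.
#'
#' @param R1 relative delivery, `> 0`.
#' @param k2prime reference clearance rate (1/min), `> 0`.
#' @param BPND binding potential, `> -1` (the fit domain; the simulator
#'   only generates positive values).
#' @return An object of class `srtm_params`.
#' @export
srtm_params <- function(R1, k2prime, BPND) {
  assert_finite(c(R1, k2prime, BPND), "SRTM parameters")
  if (R1 < 0) stopf("R1 must be >= 0", class = "refsimba_invalid_parameter")
  if (k2prime <= 0) stopf("k2prime must be > 0", class = "refsimba_invalid_rate")
  if (BPND <= -1) stopf("BPND must be > -1", class = "refsimba_invalid_parameter")
  structure(list(R1 = R1, k2prime = k2prime, BPND = BPND),
            class = "srtm_params")
}

#' @export
print.srtm_params <- function(x, ...) {
  cat(sprintf("<srtm_params: R1 = %.3g, k2prime = %.3g /min, BPND = %.3g>\n",
              x$R1, x$k2prime, x$BPND))
  invisible(x)
}

#' @export
n_parameters.srtm_params <- function(p) 3L

#' FRTM parameters
#'
#' The full reference tissue model adds the dissociation rate `k4` (1/min)
#' to the SRTM parameter set; `k3 = BPND * k4`.
#'
#' @inheritParams srtm_params
#' @param k4 dissociation rate (1/min), `> 0`.
#' @return An object of class `frtm_params`.
#' @export
frtm_params <- function(R1, k2prime, BPND, k4) {
  base <- srtm_params(R1, k2prime, BPND)
  assert_finite(k4, "k4")
  if (k4 <= 0) stopf("k4 must be > 0", class = "refsimba_invalid_rate")
  structure(c(base, list(k4 = k4)), class = c("frtm_params", "srtm_params"))
}

#' @export
n_parameters.frtm_params <- function(p) 4L

#' Analytic SRTM target-tissue curve
#'
#' With reference curve \eqn{C_R} and \eqn{k_2 = R_1 k_2'},
#' \eqn{k_{2a} = k_2/(1+BP_{ND})}:
#' \deqn{C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a})\,
#'   (C_R \otimes e^{-k_{2a} t})(t)}
#' computed entirely within the analytic exponential-mixture carrier.
#'
#' @param p an [srtm_params()] object.
#' @param ref reference curve: a [feng1tc_params()] object or an [expmix()]
#'   curve (e.g. a precomputed [feng1tc_curve()]).
#' @return An [expmix()] curve for the target tissue.
#' @export
srtm_curve <- function(p, ref) {
  stopifnot(inherits(p, "srtm_params"))
  cr <- if (inherits(ref, "expmix")) ref else feng1tc_curve(ref)
  if (p$R1 == 0) return(expmix(t0 = cr$t0))
  k2 <- p$R1 * p$k2prime
  k2a <- k2 / (1 + p$BPND)
  out <- expmix_scale(cr, p$R1)
  c2 <- k2 - p$R1 * k2a
  if (c2 != 0) out <- expmix_add(out, expmix_scale(conv_with_exp(cr, k2a), c2))
  out
}

#' Predict a target-region TAC under SRTM
#'
#' @inheritParams srtm_curve
#' @inheritParams feng1tc_predict
#' @return Numeric vector of per-frame activities.
#' @export
srtm_predict <- function(p, ref, frames, frame_average = FALSE) {
  curve <- srtm_curve(p, ref)
  if (frame_average) expmix_frame_average(curve, frames)
  else eval_expmix(curve, frames$mid)
}

#' Analytic FRTM target-tissue curve
#'
#' The full model solution
#' \deqn{C_T(t) = R_1 C_R(t) + (C_R \otimes (a e^{-\alpha t} + b e^{-\beta t}))(t)}
#' where \eqn{\alpha, \beta} are the roots of
#' \eqn{x^2 - (k_2 + k_3 + k_4) x + k_2 k_4}, with
#' \eqn{a = R_1 (k_3 + k_4 - \alpha)(k_2' - \alpha)/(\beta - \alpha)} and
#' \eqn{b = R_1 (\beta - k_3 - k_4)(k_2' - \beta)/(\beta - \alpha)}.
#' Degenerate repeated roots \eqn{\alpha = \beta} are handled by the exact
#' limit \eqn{R_1 (g(\alpha) t - g'(\alpha)) e^{-\alpha t}} with
#' \eqn{g(x) = (k_3 + k_4 - x)(k_2' - x)}, never by failure. At
#' \eqn{BP_{ND} = 0} the curve reduces exactly to the SRTM solution.
#'
#' @param p an [frtm_params()] object.
#' @inheritParams srtm_curve
#' @param root_eps tolerance on \eqn{|\beta - \alpha|} (1/min) below which
#'   the repeated-root limit form is used.
#' @return An [expmix()] curve for the target tissue.
#' @export
frtm_curve <- function(p, ref, root_eps = 1e-6) {
  stopifnot(inherits(p, "frtm_params"))
  cr <- if (inherits(ref, "expmix")) ref else feng1tc_curve(ref)
  if (p$R1 == 0) return(expmix(t0 = cr$t0))
  k2 <- p$R1 * p$k2prime
  k3 <- p$BPND * p$k4
  k4 <- p$k4
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4     # always >= (k2 - k4)^2 + ... >= 0 here
  root <- sqrt(max(disc, 0))
  alpha <- (s - root) / 2
  beta <- (s + root) / 2
  g <- function(x) (k3 + k4 - x) * (p$k2prime - x)
  out <- expmix_scale(cr, p$R1)
  if (beta - alpha < root_eps) {
    # repeated-root limit: kernel R1 * (g(alpha) t - g'(alpha)) e^{-alpha t}
    gprime <- -(p$k2prime - alpha) - (k3 + k4 - alpha)
    kern_t <- expmix_scale(conv_t_exp(cr, alpha), p$R1 * g(alpha))
    kern_0 <- expmix_scale(conv_with_exp(cr, alpha), -p$R1 * gprime)
    out <- expmix_add(out, expmix_add(kern_t, kern_0))
  } else {
    a <- p$R1 * g(alpha) / (beta - alpha)
    b <- -p$R1 * g(beta) / (beta - alpha)
    if (alpha > 0 && a != 0) {
      out <- expmix_add(out, expmix_scale(conv_with_exp(cr, alpha), a))
    }
    if (b != 0) out <- expmix_add(out, expmix_scale(conv_with_exp(cr, beta), b))
  }
  expmix_simplify(out)
}

#' Predict a target-region TAC under FRTM
#'
#' @inheritParams frtm_curve
#' @inheritParams feng1tc_predict
#' @return Numeric vector of per-frame activities.
#' @export
frtm_predict <- function(p, ref, frames, frame_average = FALSE) {
  curve <- frtm_curve(p, ref)
  if (frame_average) expmix_frame_average(curve, frames)
  else eval_expmix(curve, frames$mid)
}

# Convolution of an expmix curve with t * e^{-theta t}, needed only for the
# FRTM repeated-root limit. Computed as d/d(-theta) of conv_with_exp, term
# by term analytically:
#   c u^p e^{-lu} (x) u e^{-theta u}
#     = -c p! (p+1) d^{-(p+2)} e^{-theta u} + c p! d^{-(p+1)} u e^{-theta u}
#       + c p! sum_m (p+1-m) d^{m-p-2} / m! u^m e^{-l u},   d = l - theta,
# with the repeated-root limit u^{p+2} e^{-lu} / ((p+1)(p+2)).
#' @keywords internal
conv_t_exp <- function(curve, theta, eps = 1e-6) {
  coef <- numeric(0); rate <- numeric(0); tpow <- integer(0)
  for (j in seq_along(curve$coef)) {
    cj <- curve$coef[j]; lj <- curve$rate[j]; pj <- curve$tpow[j]
    d <- lj - theta
    if (abs(d) < eps) {
      # int_0^u s^p (u-s) ds * e^{-lu} = u^{p+2} e^{-lu} / ((p+1)(p+2))
      coef <- c(coef, cj / ((pj + 1) * (pj + 2)))
      rate <- c(rate, lj)
      tpow <- c(tpow, pj + 2L)
    } else {
      fp <- factorial(pj)
      coef <- c(coef, -cj * fp * (pj + 1) / d^(pj + 2), cj * fp / d^(pj + 1))
      rate <- c(rate, theta, theta)
      tpow <- c(tpow, 0L, 1L)
      m <- 0:pj
      coef <- c(coef, cj * fp * (pj + 1 - m) * d^(m - pj - 2) / factorial(m))
      rate <- c(rate, rep(lj, pj + 1))
      tpow <- c(tpow, as.integer(m))
    }
  }
  expmix_simplify(expmix(coef, rate, tpow, curve$t0))
}
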