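#' Feng input-shape parameters
#'
#' The tri-exponential Feng shape with a linear rise, used here not as an
#' arterial input function but as a flexible parametric component of the
#' reference-curve model. For \eqn{t > t_0}, with \eqn{\Delta = t - t_0}:
#' \deqn{C(t) = (A_1 \Delta - A_2 - A_3)e^{-\lambda_1 \Delta} +
#'       A_2 e^{-\lambda_2 \Delta} + A_3 e^{-\lambda_3 \Delta}}
#' and \eqn{C(t) = 0} for \eqn{t \le t_0}; the form is continuous at the
#' onset since the coefficients sum to zero there. Rates are canonically
#' ordered \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3} at construction (the
#' \eqn{(A_2,\lambda_2)} and \eqn{(A_3,\lambda_3)} pairs are exchangeable,
#' so ordering removes label switching in fits; \eqn{(A_1,\lambda_1)} is
#' pinned to the fastest rate, which carries the linear-rise term).
#'
#' @param A1,A2,A3 activity-scale coefficients (A1 in activity/min).
#' @param lambda1,lambda2,lambda3 decay rates (1/min), non-negative.
#' @param t0 onset time (minutes), non-negative.
#' @return An object of class `feng_params`.
#' @export
feng_params <- function(A1, A2, A3, lambda1, lambda2, lambda3, t0 = 0) {
  v <- c(A1, A2, A3, lambda1, lambda2, lambda3, t0)
  if (length(v) != 7) stopf("feng_params takes 7 scalars")
  assert_finite(v, "Feng parameters")
  if (t0 < 0) stopf("t0 must be >= 0", class = "refsimba_invalid_parameter")
  if (any(c(lambda1, lambda2, lambda3) < 0)) {
    stopf("Feng rates must be >= 0", class = "refsimba_invalid_parameter")
  }
  # canonical ordering: (A2, lambda2) and (A3, lambda3) are exchangeable
  # (swapping them leaves the curve unchanged), so they are sorted at
  # construction to remove label switching. The linear-rise pair (A1,
  # lambda1) is structurally distinct and must carry the fastest rate.
  if (lambda3 > lambda2) {
    tmp <- c(A2, lambda2)
    A2 <- A3; lambda2 <- lambda3
    A3 <- tmp[1]; lambda3 <- tmp[2]
  }
  if (lambda2 > lambda1) {
    stopf("lambda1 (the linear-rise rate) must be the fastest rate",
          class = "refsimba_invalid_parameter")
  }
  structure(list(A1 = A1, A2 = A2, A3 = A3, lambda1 = lambda1,
                 lambda2 = lambda2, lambda3 = lambda3, t0 = t0),
            class = "feng_params")
}

#' @export
print.feng_params <- function(x, ...) {
  cat(sprintf(
    "<feng_params: A = (%.3g, %.3g, %.3g), lambda = (%.3g, %.3g, %.3g) /min, t0 = %.3g min>\n",
    x$A1, x$A2, x$A3, x$lambda1, x$lambda2, x$lambda3, x$t0))
  invisible(x)
}

#' @rdname feng_params
#' @param p a `feng_params` object.
#' @return `feng_curve()`: the shape as an [expmix()] curve.
#' @export
feng_curve <- function(p) {
  stopifnot(inherits(p, "feng_params"))
  expmix(coef = c(p$A1, -p$A2 - p$A3, p$A2, p$A3),
         rate = c(p$lambda1, p$lambda1, p$lambda2, p$lambda3),
         tpow = c(1L, 0L, 0L, 0L),
         t0 = p$t0)
}

#' Evaluate the Feng input shape
#'
#' @param p a [feng_params()] object.
#' @param t numeric vector of times (minutes).
#' @return Activity values; zero for `t <= t0` and continuous at the onset.
#' @export
feng_input <- function(p, t) {
  stopifnot(inherits(p, "feng_params"))
  eval_expmix(feng_curve(p), t)
}

#' Feng-1TC reference-curve parameters
#'
#' The reference-region TAC model: a Feng input shape convolved with a
#' one-tissue-compartment impulse response \eqn{K_1^{ref} e^{-k_2^{ref} t}}.
#' Both components are estimated from the reference TAC itself, so none of
#' the 9 parameters (6 Feng + 2 one-tissue + onset \eqn{t_0}) carries a
#' biological interpretation — the model is a descriptive basis whose value
#' is that its predictions convolve analytically within [expmix()].
#'
#' @param feng a [feng_params()] object (6 shape parameters + t0).
#' @param K1ref delivery-like coefficient (1/min), `>= 0`.
#' @param k2ref clearance-like rate (1/min), `> 0`.
#' @return An object of class `feng1tc_params`.
#' @export
feng1tc_params <- function(feng, K1ref, k2ref) {
  stopifnot(inherits(feng, "feng_params"))
  assert_finite(c(K1ref, k2ref), "1TC parameters")
  if (K1ref < 0) stopf("K1ref must be >= 0", class = "refsimba_invalid_parameter")
  if (k2ref <= 0) stopf("k2ref must be > 0", class = "refsimba_invalid_rate")
  structure(list(feng = feng, K1ref = K1ref, k2ref = k2ref),
            class = "feng1tc_params")
}

#' @export
print.feng1tc_params <- function(x, ...) {
  cat(sprintf("<feng1tc_params: K1ref = %.3g, k2ref = %.3g /min>\n",
              x$K1ref, x$k2ref))
  print(x$feng)
  invisible(x)
}

#' Number of free parameters of a kinetic parameter set
#'
#' @param p a parameter object (`feng_params`, `feng1tc_params`,
#'   `srtm_params` or `frtm_params`).
#' @return Integer count of free parameters.
#' @export
n_parameters <- function(p) UseMethod("n_parameters")

#' @export
n_parameters.feng_params <- function(p) 7L

#' @export
n_parameters.feng1tc_params <- function(p) n_parameters(p$feng) + 2L

#' Reference curve of the Feng-1TC model as an analytic curve
#'
#' @param p a [feng1tc_params()] object.
#' @return The reference TAC as an [expmix()] curve.
#' @export
feng1tc_curve <- function(p) {
  stopifnot(inherits(p, "feng1tc_params"))
  expmix_scale(conv_with_exp(feng_curve(p$feng), p$k2ref), p$K1ref)
}

#' Predict a reference-region TAC from Feng-1TC parameters
#'
#' @param p a [feng1tc_params()] object.
#' @param frames a [frame_schedule()].
#' @param frame_average if `TRUE`, return exact frame-integral averages;
#'   otherwise (default) the value at the frame midpoint.
#' @return Numeric vector of per-frame activities.
#' @export
feng1tc_predict <- function(p, frames, frame_average = FALSE) {
  stopifnot(inherits(p, "feng1tc_params"))
  if (!inherits(frames, "frame_schedule")) {
    stopf("frames must be a frame_schedule", class = "refsimba_schedule_error")
  }
  curve <- feng1tc_curve(p)
  if (frame_average) expmix_frame_average(curve, frames)
  else eval_expmix(curve, frames$mid)
}

# flatten/unflatten for fitting
#' @keywords internal
feng1tc_to_vector <- function(p) {
  c(A1 = p$feng$A1, A2 = p$feng$A2, A3 = p$feng$A3,
    lambda1 = p$feng$lambda1, lambda2 = p$feng$lambda2,
    lambda3 = p$feng$lambda3, t0 = p$feng$t0,
    K1ref = p$K1ref, k2ref = p$k2ref)
}

#' @keywords internal
feng1tc_from_vector <- function(v) {
  feng1tc_params(
    feng_params(v[["A1"]], v[["A2"]], v[["A3"]],
                v[["lambda1"]], v[["lambda2"]], v[["lambda3"]], v[["t0"]]),
    K1ref = v[["K1ref"]], k2ref = v[["k2ref"]])
}
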