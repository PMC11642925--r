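test_that("Feng input shape is zero before onset and continuous at it", {
  p <- feng_params(100, 1, 0.5, 4, 0.45, 0.05, t0 = 0.5)
  expect_equal(feng_input(p, c(-1, 0, 0.25, 0.5)), rep(0, 4))
  # continuity: the coefficients cancel at the onset
  eps <- 10^-(4:8)
  # bounded by (A1 + A2*l1 + A3*l1) * eps near the onset
  expect_true(all(abs(feng_input(p, 0.5 + eps)) < 120 * eps + 1e-10))
})

test_that("Feng input matches high-precision direct evaluation of the formula", {
  A1 <- 100; A2 <- 1; A3 <- 0.5
  l1 <- 4; l2 <- 0.5; l3 <- 0.05; t0 <- 0.5
  p <- feng_params(A1, A2, A3, l1, l2, l3, t0)
  t <- 1.0; d <- t - t0
  direct <- (A1 * d - A2 - A3) * exp(-l1 * d) + A2 * exp(-l2 * d) +
    A3 * exp(-l3 * d)
  expect_equal(feng_input(p, t), direct, tolerance = 1e-12)
})

test_that("canonical ordering sorts the exchangeable pair and is curve-invariant", {
  pa <- feng_params(50, 1, 0.4, 4, 0.05, 0.3, 0.4)  # lambda3 > lambda2 input
  expect_true(pa$lambda1 >= pa$lambda2 && pa$lambda2 >= pa$lambda3)
  pb <- feng_params(50, 0.4, 1, 4, 0.3, 0.05, 0.4)
  t <- seq(0, 20, by = 0.5)
  expect_equal(feng_input(pa, t), feng_input(pb, t))
  expect_error(feng_params(1, 1, 1, 0.3, 0.5, 0.05, 0),
               class = "refsimba_invalid_parameter")
})

test_that("convolution with an exponential: trivial identities", {
  z <- expmix(t0 = 0.2)
  expect_equal(eval_expmix(conv_with_exp(z, 0.5), c(1, 5, 10)), rep(0, 3))
  # e^{-a t} (x) e^{-b t} = (e^{-a t} - e^{-b t}) / (b - a)
  a <- 0.7; b <- 0.11
  cv <- conv_with_exp(expmix(1, a, 0L, 0), b)
  t <- c(0.5, 2, 7, 30)
  expect_equal(eval_expmix(cv, t), (exp(-a * t) - exp(-b * t)) / (b - a),
               tolerance = 1e-12)
  expect_error(conv_with_exp(expmix(1, a, 0L, 0), -0.1),
               class = "refsimba_invalid_rate")
})

test_that("repeated-rate convolution uses the limit form, not failure", {
  cv <- conv_with_exp(expmix(2, 0.3, 0L, 0), 0.3)
  t <- c(1, 5, 20)
  expect_equal(eval_expmix(cv, t), 2 * t * exp(-0.3 * t), tolerance = 1e-10)
  # continuity across the switching tolerance
  near <- conv_with_exp(expmix(2, 0.3, 0L, 0), 0.3 + 5e-6)
  expect_rel_equal(eval_expmix(near, t), eval_expmix(cv, t), 1e-3)
})

test_that("Feng-1TC closed form matches the numeric convolution oracle", {
  p <- feng_params(100, 1, 0.5, 4, 0.45, 0.05, 0.5)
  f1 <- feng1tc_params(p, K1ref = 1, k2ref = 0.07)
  tout <- c(1.5, 3, 8, 20, 45, 88)
  oracle <- num_conv_at(function(s) feng_input(p, s),
                        function(s) exp(-0.07 * s), tout, t0 = 0.5)
  mine <- eval_expmix(feng1tc_curve(f1), tout)
  expect_rel_equal(mine, oracle, 1e-4)
})

test_that("Feng-1TC frame predictions: zero delivery and oracle agreement", {
  fr <- default_frames()
  p <- feng_params(100, 1, 0.5, 4, 0.45, 0.05, 0.5)
  f0 <- feng1tc_params(p, K1ref = 0, k2ref = 0.1)
  expect_equal(feng1tc_predict(f0, fr), rep(0, length(fr)))
  f1 <- feng1tc_params(p, K1ref = 1, k2ref = 0.1)
  tout <- fr$mid[c(12, 20, 30, 38)]
  oracle <- num_conv_at(function(s) feng_input(p, s),
                        function(s) exp(-0.1 * s), tout, t0 = 0.5)
  expect_rel_equal(feng1tc_predict(f1, fr)[c(12, 20, 30, 38)], oracle, 1e-4)
  expect_error(feng1tc_predict(f1, list(mid = 1:3)),
               class = "refsimba_schedule_error")
})

test_that("SRTM collapses onto the reference and vanishes without delivery", {
  fr <- default_frames()
  ref <- default_reference_params()[[1]]
  cr <- eval_expmix(feng1tc_curve(ref), fr$mid)
  ct <- srtm_predict(srtm_params(1, 0.11, 0), ref, fr)
  expect_equal(ct, cr, tolerance = 1e-12)
  expect_equal(srtm_predict(srtm_params(0, 0.11, 1.5), ref, fr),
               rep(0, length(fr)))
  expect_error(srtm_params(0.9, 0.1, -1.2), class = "refsimba_invalid_parameter")
})

test_that("SRTM closed form matches the numeric convolution oracle", {
  fr <- default_frames()
  ref <- default_reference_params()[[1]]
  crf <- function(s) eval_expmix(feng1tc_curve(ref), s)
  p <- srtm_params(0.9, 0.12, 1.5)
  k2 <- 0.9 * 0.12; k2a <- k2 / 2.5
  tout <- fr$mid[c(10, 18, 27, 38)]
  conv <- num_conv_at(crf, function(s) exp(-k2a * s), tout,
                      t0 = ref$feng$t0)
  oracle <- 0.9 * crf(tout) + (k2 - 0.9 * k2a) * conv
  expect_rel_equal(srtm_predict(p, ref, fr)[c(10, 18, 27, 38)], oracle, 1e-4)
})

test_that("FRTM nests SRTM exactly at BPND = 0 and matches the oracle", {
  fr <- default_frames()
  ref <- default_reference_params()[[2]]
  s0 <- srtm_predict(srtm_params(0.9, 0.12, 0), ref, fr)
  for (k4 in c(0.02, 0.05, 0.2)) {
    f0 <- frtm_predict(frtm_params(0.9, 0.12, 1e-14, k4), ref, fr)
    expect_lt(max(abs(f0 - s0)), 1e-10)
  }
  expect_equal(frtm_predict(frtm_params(1, 0.12, 1e-14, 0.05), ref, fr),
               eval_expmix(feng1tc_curve(ref), fr$mid), tolerance = 1e-9)
  # full FRTM vs numeric oracle
  p <- frtm_params(0.85, 0.12, 2.0, 0.05)
  k2 <- 0.85 * 0.12; k3 <- 0.1; k4 <- 0.05; s <- k2 + k3 + k4
  rt <- sqrt(s^2 - 4 * k2 * k4)
  al <- (s - rt) / 2; be <- (s + rt) / 2
  g <- function(x) (k3 + k4 - x) * (0.12 - x)
  a <- 0.85 * g(al) / (be - al); b <- -0.85 * g(be) / (be - al)
  crf <- function(s) eval_expmix(feng1tc_curve(ref), s)
  tout <- fr$mid[c(10, 20, 30, 38)]
  conv <- num_conv_at(crf, function(s) a * exp(-al * s) + b * exp(-be * s),
                      tout, t0 = ref$feng$t0)
  oracle <- 0.85 * crf(tout) + conv
  expect_rel_equal(frtm_predict(p, ref, fr)[c(10, 20, 30, 38)], oracle, 1e-4)
})

test_that("FRTM degenerate repeated roots are handled by the limit form", {
  fr <- default_frames()
  ref <- default_reference_params()[[1]]
  # k3 ~ 0 and k2 = k4 makes alpha = beta
  v_rep <- frtm_predict(frtm_params(1, 0.05, 1e-9, 0.05), ref, fr)
  expect_true(all(is.finite(v_rep)))
  v_near <- frtm_predict(frtm_params(1, 0.0502, 1e-9, 0.05), ref, fr)
  expect_rel_equal(v_rep, v_near, 0.02)
})

test_that("closed forms agree with the numeric oracle across random draws", {
  set.seed(7)
  ref <- default_reference_params()
  tout <- c(2, 10, 40, 85)
  for (i in 1:12) {
    rp <- ref[[(i - 1) %% length(ref) + 1]]
    p <- srtm_params(runif(1, 0.5, 1.3), runif(1, 0.05, 0.2),
                     runif(1, 0.1, 4))
    k2 <- p$R1 * p$k2prime; k2a <- k2 / (1 + p$BPND)
    crf <- function(s) eval_expmix(feng1tc_curve(rp), s)
    conv <- num_conv_at(crf, function(s) exp(-k2a * s), tout,
                        t0 = rp$feng$t0)
    oracle <- p$R1 * crf(tout) + (k2 - p$R1 * k2a) * conv
    mine <- eval_expmix(srtm_curve(p, rp), tout)
    expect_rel_equal(mine, oracle, 1e-4)
  }
})

test_that("predictions are invariant to the (R1, k2, k2a) reparameterisation", {
  fr <- default_frames()
  ref <- default_reference_params()[[3]]
  p <- srtm_params(0.85, 0.13, 1.2)
  k2 <- p$R1 * p$k2prime
  k2a <- k2 / (1 + p$BPND)
  # rebuild from (R1, k2, k2a): k2prime = k2 / R1, BPND = k2 / k2a - 1
  p2 <- srtm_params(p$R1, k2 / p$R1, k2 / k2a - 1)
  expect_equal(srtm_predict(p, ref, fr), srtm_predict(p2, ref, fr),
               tolerance = 1e-12)
})

test_that("all predicted curves vanish for frames entirely before onset", {
  fr <- frame_schedule(seq(0, 0.4, by = 0.1), rep(0.1, 5))
  ref <- feng1tc_params(feng_params(60, 1, 0.4, 4, 0.3, 0.02, t0 = 0.6),
                        1, 0.08)
  expect_equal(feng1tc_predict(ref, fr), rep(0, 5))
  expect_equal(srtm_predict(srtm_params(0.9, 0.1, 1), ref, fr), rep(0, 5))
  expect_equal(frtm_predict(frtm_params(0.9, 0.1, 1, 0.05), ref, fr),
               rep(0, 5))
})

test_that("frame-integral averaging matches fine midpoint averaging", {
  ref <- default_reference_params()[[1]]
  fr <- default_frames()
  avg <- feng1tc_predict(ref, fr, frame_average = TRUE)
  cv <- feng1tc_curve(ref)
  brute <- vapply(seq_along(fr$start), function(h) {
    s <- seq(fr$start[h], fr$end[h], length.out = 2001)
    v <- eval_expmix(cv, s)
    sum((v[-1] + v[-length(v)]) / 2) * diff(s)[1] / fr$duration[h]
  }, numeric(1))
  expect_rel_equal(avg[-(1:2)], brute[-(1:2)], 1e-5)
})

test_that("frame schedule validation rejects malformed schedules", {
  expect_error(frame_schedule(c(0, 1), c(1, -1)),
               class = "refsimba_schedule_error")
  expect_error(frame_schedule(c(1, 0), c(0.5, 0.5)),
               class = "refsimba_schedule_error")
  expect_error(frame_schedule(c(0, 0.5), c(1, 1)),
               class = "refsimba_schedule_error")
})
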