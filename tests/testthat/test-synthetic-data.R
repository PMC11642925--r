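test_that("the default design passes its own validity checks", {
  design <- default_truth_parameters()
  expect_s3_class(design, "sim_design")
  ev <- eigen(design$Sigma_subject, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(nrow(design$regions), 9)
  expect_true("DBS" %in% design$regions$region)
  # the DBS analogue is small with medium-to-low binding
  dbs <- design$regions[design$regions$region == "DBS", ]
  expect_lt(dbs$volume_ml, 5)
  expect_lt(exp(dbs$logBPND), exp(mean(design$regions$logBPND)))
  # regional mean BPND spans at least an order of magnitude
  bp <- exp(design$regions$logBPND)
  expect_gte(max(bp) / min(bp), 10 * (1 - 1e-9))
  expect_error(default_truth_parameters(n_per_group = 0),
               class = "refsimba_design_error")
})

test_that("the reference library has the requested size and structure", {
  design <- default_truth_parameters()
  lib <- make_reference_library(n = 6, noise = design$sigma_model, seed = 8,
                                refit_n_starts = 4)
  expect_length(lib, 6)
  e <- lib$entries[[1]]
  expect_equal(e$true_curve, feng1tc_predict(e$true_params, lib$frames))
  expect_false(isTRUE(all.equal(e$measured_curve, e$true_curve)))
  expect_s3_class(e$estimated_params, "feng1tc_params")
})

test_that("zero noise makes measured curves exact and refits near-perfect", {
  design <- default_truth_parameters()
  noise <- design$sigma_model
  noise$ref_intercept <- log(1e-12)
  noise$sd_pet_ref <- 0
  lib <- make_reference_library(n = 3, noise = noise, seed = 9,
                                refit_n_starts = 20)
  for (e in lib$entries) {
    expect_equal(e$measured_curve, e$true_curve, tolerance = 1e-8)
    pred <- feng1tc_predict(e$estimated_params, lib$frames)
    rel <- sqrt(mean((pred - e$true_curve)^2)) / sqrt(mean(e$true_curve^2))
    expect_lt(rel, 1e-3)
  }
})

test_that("doubling PET-to-PET noise variability widens the noise distribution", {
  design <- default_truth_parameters()
  n1 <- design$sigma_model
  n2 <- design$sigma_model
  n2$sd_pet_ref <- 2 * n1$sd_pet_ref
  # compare the spread of per-entry residual SDs (noise layers only; the
  # refit is irrelevant to this property, so use cheap refit settings)
  sd_of <- function(noise, seed) {
    lib <- make_reference_library(n = 40, noise = noise, seed = seed,
                                  refit_n_starts = 1)
    vapply(lib$entries, function(e) sd(e$measured_curve - e$true_curve),
           numeric(1))
  }
  s1 <- sd_of(n1, 12)
  s2 <- sd_of(n2, 12)
  expect_gt(var(log(s2)), var(log(s1)))
})

test_that("simulated datasets have the designed size and group structure", {
  design <- default_truth_parameters(n_per_group = 10, seed = 3)
  lib <- exact_ref_library(6)
  ds <- simulate_dataset(design, lib)
  # 10 per group, 20 subjects, measured twice, 9 regions
  expect_equal(nrow(ds$truth), 10 * 2 * 2 * 9)
  expect_equal(length(unique(ds$meta$subject_id)), 20)
  expect_equal(table(ds$meta$group)[["HV"]], 20)
  expect_equal(nrow(ds$tac_table), 360 * length(ds$frames))
  # HVs receive placebo, patients active treatment
  expect_true(all(ds$meta$condition[ds$meta$group == "HV"] == "placebo"))
  expect_true(all(ds$meta$condition[ds$meta$group == "patient"] == "treatment"))
})

test_that("group and treatment effects enter the truth at the designed size", {
  design <- default_truth_parameters(n_per_group = 150, seed = 5)
  lib <- exact_ref_library(6)
  ds <- simulate_dataset(design, lib, regions = c("DBS", "FC"))
  tr <- ds$truth
  # remove the random deviations: the fixed effects remain exactly
  fixed <- tr$logBPND - tr$dev_subject_logBPND - tr$dev_tac_logBPND
  base <- ave(fixed, tr$region, FUN = mean)
  hv_pre <- mean((fixed - base)[tr$group == "HV" & tr$time == "pre"])
  pat_pre <- mean((fixed - base)[tr$group == "patient" & tr$time == "pre"])
  expect_equal(pat_pre - hv_pre, design$group_effect_logBPND,
               tolerance = 1e-12)
  # exact statements, free of Monte-Carlo error:
  dd <- tapply(fixed, list(tr$group, tr$time), mean)
  expect_equal(dd["patient", "post"] - dd["patient", "pre"], 0.04)
  expect_equal(dd["HV", "post"] - dd["HV", "pre"], 0)  # placebo arm
  # raw (noisy) group difference near -0.08 at this n
  raw <- tapply(tr$logBPND[tr$time == "pre"], tr$group[tr$time == "pre"], mean)
  expect_lt(abs((raw[["patient"]] - raw[["HV"]]) - (-0.08)), 0.03)
})

test_that("same seed gives bit-identical datasets", {
  design <- default_truth_parameters(n_per_group = 2, seed = 6)
  lib <- exact_ref_library(4)
  a <- simulate_dataset(design, lib, regions = c("DBS", "FC"))
  b <- simulate_dataset(design, lib, regions = c("DBS", "FC"))
  expect_identical(a$tac_table, b$tac_table)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_dataset(design, lib, seed = 7, regions = c("DBS", "FC"))
  expect_false(identical(a$tac_table, c2$tac_table))
})

test_that("empirical subject covariance approaches the specified matrix", {
  design <- default_truth_parameters(n_per_group = 1000, seed = 10)
  lib <- exact_ref_library(3)
  # subject deviations are in the truth table; one row per subject suffices
  ds <- simulate_dataset(design, lib, regions = c("DBS", "FC"))
  tr <- ds$truth
  one <- tr[!duplicated(tr$subject_id), ]
  emp <- cov(cbind(one$dev_subject_logR1, one$dev_subject_logk2prime,
                   one$dev_subject_logBPND))
  frob <- function(A, B) sqrt(sum((A - B)^2))
  d_big <- frob(emp, design$Sigma_subject)
  small <- one[1:100, ]
  emp_small <- cov(cbind(small$dev_subject_logR1,
                         small$dev_subject_logk2prime,
                         small$dev_subject_logBPND))
  expect_lt(d_big, frob(emp_small, design$Sigma_subject))
  expect_lt(d_big, 0.005)
})

test_that("measurement error reproduces the configured frame-duration law", {
  ds <- shared_dataset()
  design <- ds$design
  tr <- ds$truth
  fr <- ds$frames
  clogdur <- log(fr$duration) - mean(log(fr$duration))
  # reconstruct residuals against the true noiseless curves
  resid <- c(); dur <- c(); smv <- c()
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    p <- srtm_params(row$R1, row$k2prime, row$BPND)
    mu <- srtm_predict(p, ds$ref_true[[row$measurement_id]], fr)
    sub <- ds$tac_table[ds$tac_table$measurement_id == row$measurement_id &
                          ds$tac_table$region == row$region, ]
    sub <- sub[order(sub$frame_start), ]
    resid <- c(resid, sub$activity - mu)
    dur <- c(dur, clogdur)
    smv <- c(smv, design$sigma_model$smooth(fr$mid))
  }
  # control for the smooth-over-time component, which is correlated with
  # frame duration by design of the acquisition schedule
  fitlm <- lm(log(abs(resid) + 1e-12) ~ dur + smv)
  co <- summary(fitlm)$coefficients
  expect_lt(abs(co["dur", "Estimate"] - design$sigma_model$b_logdur),
            2 * co["dur", "Std. Error"] + 0.05)
})
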