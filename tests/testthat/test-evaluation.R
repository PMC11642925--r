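toy_truth <- function(n = 5) {
  data.frame(subject_id = sprintf("s%d", 1:n), measurement_id = "m1",
             region = "R", group = "HV", time = "pre",
             R1 = 1, k2prime = 0.1, BPND = seq_len(n),
             stringsAsFactors = FALSE)
}

test_that("accuracy metrics: identity, constant offset and a hand-worked case", {
  tr <- toy_truth()
  est <- tr[, c("subject_id", "measurement_id", "region", "BPND")]
  a <- accuracy_metrics(est, tr, scope = "all", parameters = "BPND")
  expect_equal(a$rmse, 0)
  expect_equal(a$pearson_r, 1)
  est2 <- est; est2$BPND <- est2$BPND + 0.7
  a2 <- accuracy_metrics(est2, tr, scope = "all", parameters = "BPND")
  expect_equal(a2$rmse, 0.7)
  est3 <- est; est3$BPND <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  a3 <- accuracy_metrics(est3, tr, scope = "all", parameters = "BPND")
  expect_equal(a3$rmse, sqrt(mean(c(0.1, -0.1, 0.2, -0.2, 0.1)^2)))
  expect_equal(a3$pearson_r, cor(c(1.1, 1.9, 3.2, 3.8, 5.1), 1:5))
  expect_equal(a3$n_estimates, 5)
})

test_that("accuracy metrics scope to baseline control and flag unmatched keys", {
  tr <- rbind(toy_truth(), transform(toy_truth(), time = "post"))
  est <- tr[, c("subject_id", "measurement_id", "region", "BPND")]
  est$BPND <- est$BPND + 1
  # duplicate keys in this toy (pre and post share measurement ids), so
  # restrict to one row per key for the scope check
  tr2 <- toy_truth(); tr2$time <- "pre"
  est2 <- tr2[, c("subject_id", "measurement_id", "region", "BPND")]
  a <- accuracy_metrics(est2, tr2, scope = "baseline_control",
                        parameters = "BPND")
  expect_equal(a$n_estimates, 5)
  bad <- est2; bad$subject_id[1] <- "nobody"
  expect_error(accuracy_metrics(bad, tr2, scope = "all"),
               class = "refsimba_join_error")
})

test_that("RMSE reduction arithmetic matches hand computation", {
  a <- data.frame(region = c("A", "B", "C"), parameter = "BPND",
                  rmse = c(0.87, 0.60, 0.31), pearson_r = 0.9,
                  n_estimates = 10)
  b <- data.frame(region = c("A", "B", "C"), parameter = "BPND",
                  rmse = c(1, 1, 1), pearson_r = 0.8, n_estimates = 10)
  rr <- rmse_reduction(a, b)
  expect_equal(sort(rr$table$reduction_pct), c(13, 40, 69))
  expect_equal(rr$summary$mean, mean(c(13, 40, 69)), tolerance = 1e-12)
  expect_equal(rr$summary$median, 40)
  # equal tables give zero reduction; halved RMSE gives 50%
  expect_equal(rmse_reduction(b, b)$summary$mean, 0)
  h <- b; h$rmse <- b$rmse / 2
  expect_equal(rmse_reduction(h, b)$summary$mean, 50)
  # zero baseline RMSE is reported missing
  z <- b; z$rmse[1] <- 0
  rz <- rmse_reduction(a, z)
  expect_true(is.na(rz$table$reduction_pct[rz$table$region == "A"]))
})

test_that("LME contrast is exact on saturated noise-free data and sign-symmetric", {
  d <- expand.grid(subject_id = sprintf("s%02d", 1:12),
                   time = c("pre", "post"), region = c("DBS", "FC"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject_id)) <= 6, "HV",
                    "patient")
  d$logBPND <- 1 + (d$region == "FC") * 0.5 +
    (d$group == "patient") * (-0.08) +
    (d$group == "patient" & d$time == "post") * 0.04
  lc <- lme_contrast(d)
  expect_equal(lc$estimate, 0.04, tolerance = 1e-8)
  d2 <- d
  d2$group <- ifelse(d$group == "HV", "patient", "HV")
  lc2 <- lme_contrast(d2)
  expect_equal(lc2$estimate, -0.04, tolerance = 1e-8)
})

test_that("null LME p-values are approximately uniform", {
  design <- default_truth_parameters(n_per_group = 10, seed = 30)
  reps <- lme_replicates(design, n_replicates = 400, effect = 0,
                         est_noise_sd = 0.1,
                         regions = c("DBS", "FC", "OC"), seed = 31)
  # z against the t reference: convert to two-sided p-values
  p <- 2 * pnorm(-abs(reps$z))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("power estimation: saturated, analytic-normal and CI-width cases", {
  set.seed(40)
  p_sat <- power_fpr(rep(10, 30) + rnorm(30, 0, 1e-6), n_boot = 100)
  expect_gt(p_sat$power, 0.99)
  p_norm <- power_fpr(rnorm(10000), threshold = 1.96, n_boot = 100)
  expect_lt(abs(p_norm$power - 0.05), 0.01)
  expect_true(p_norm$ci95[1] <= p_norm$power &&
                p_norm$power <= p_norm$ci95[2])
  z <- rnorm(500, 1)
  w50 <- power_fpr(z[1:50], n_boot = 200, seed = 2)
  w500 <- power_fpr(z, n_boot = 200, seed = 2)
  expect_gt(diff(w50$ci95), diff(w500$ci95))
  # degenerate statistics fall back to the exact proportion
  deg <- power_fpr(rep(2.5, 25), n_boot = 20)
  expect_equal(deg$power, 1)
  expect_error(power_fpr(rnorm(10)), class = "refsimba_design_error")
})

test_that("hierarchical posterior means beat per-TAC NLS on regional RMSE", {
  fit <- shared_simba()
  ds <- shared_dataset()
  nls <- shared_nls()
  acc_s <- accuracy_metrics(tac_estimates(fit), ds$truth, scope = "all")
  acc_n <- accuracy_metrics(nls[nls$converged & nls$reliable, ], ds$truth, scope = "all")
  rr <- rmse_reduction(acc_s, acc_n)
  bp <- rr$table[rr$table$parameter == "BPND", ]
  expect_true(all(bp$reduction_pct > 0))
})
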