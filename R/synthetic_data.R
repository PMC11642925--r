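#' Default simulation truth parameters
#'
#' A complete simulation design describing a two-group (healthy volunteer
#' vs patient), pre/post (placebo vs active treatment) study with nine
#' brain regions and a cerebellar-like reference region. The PK-parameter
#' hierarchy is log-normal: per-region mean logR1/logBPND (fixed values,
#' playing the role of posterior-mean regional estimates from a large
#' empirical fit), a global mean logk2prime with small fixed regional
#' offsets, multivariate normal subject deviations and TAC
#' (measurement-by-region) deviations, a patient group offset of -0.08 on
#' logBPND and an active-treatment offset of +0.04 on logBPND (placebo 0).
#'
#' The numerical values shipped here are *synthetic* defaults: plausible
#' values for a serotonin-receptor radiotracer with regional mean BPND
#' spanning an order of magnitude and a small, medium-to-low-binding
#' dorsal-brain-stem-like region, chosen once to make simulated TACs and
#' their estimation errors resemble published reference-tissue data. Every
#' element can be overridden.
#'
#' @param n_per_group subjects per group (each measured twice).
#' @param seed integer seed stored with the design.
#' @return An object of class `sim_design` (a list; see source for
#'   fields). Covariance matrices are validated to be symmetric positive
#'   definite.
#' @export
default_truth_parameters <- function(n_per_group = 10, seed = 1) {
  regions <- data.frame(
    region = c("ACC", "AMG", "DBS", "FC", "HIP", "INS", "OC", "THA", "VSTR"),
    logR1 = log(c(0.95, 0.85, 0.80, 1.00, 0.82, 0.95, 1.05, 0.88, 0.92)),
    logBPND = log(c(1.60, 1.10, 0.45, 1.30, 0.55, 1.20, 2.80, 0.28, 1.90)),
    logk2prime_offset = c(0.05, -0.02, 0.03, 0.08, -0.12, 0.02, -0.04,
                          -0.06, 0.06),
    volume_ml = c(12, 4, 2.2, 120, 8, 15, 45, 16, 6),
    stringsAsFactors = FALSE
  )
  sd_subj <- c(logR1 = 0.06, logk2prime = 0.10, logBPND = 0.22)
  cor_subj <- matrix(c(1, 0.3, 0.6,
                       0.3, 1, 0.2,
                       0.6, 0.2, 1), 3, 3,
                     dimnames = list(names(sd_subj), names(sd_subj)))
  sd_tac <- c(logR1 = 0.020, logk2prime = 0.025, logBPND = 0.030)
  cor_tac <- diag(3); dimnames(cor_tac) <- dimnames(cor_subj)
  design <- list(
    n_per_group = n_per_group,
    regions = regions,
    logk2prime_mean = log(0.10),
    group_effect_logBPND = -0.08,
    treatment_effect_logBPND = 0.04,
    placebo_effect_logBPND = 0,
    Sigma_subject = diag(sd_subj) %*% cor_subj %*% diag(sd_subj),
    Sigma_tac = diag(sd_tac) %*% cor_tac %*% diag(sd_tac),
    sigma_model = list(
      intercept = log(0.48),      # log kBq/mL at centred covariates
      b_logdur = -0.5,            # counting statistics: sigma ~ duration^-1/2
      b_logvol = -0.5,            # ditto: sigma ~ region volume^-1/2
      b_logdose = -0.25,          # higher dose, more counts
      smooth = function(t, t_end = 93) 0.9 * (t / t_end)^1.5 - 0.35,
      sd_subject = 0.15,          # PET-to-PET deviation in log sigma
      sd_region = 0.10,
      ref_intercept = log(0.22),  # reference region: large, low-noise
      sd_pet_ref = 0.20           # PET-to-PET sd of log sigma, ref library
    ),
    dose_meanlog = log(450), dose_sdlog = 0.25,  # MBq
    age_mean = 40, age_sd = 12,
    frames = default_frames(),
    seed = seed
  )
  dimnames(design$Sigma_subject) <- dimnames(cor_subj)
  dimnames(design$Sigma_tac) <- dimnames(cor_subj)
  class(design) <- "sim_design"
  validate_sim_design(design)
  design
}

#' @keywords internal
validate_sim_design <- function(design) {
  for (nm in c("Sigma_subject", "Sigma_tac")) {
    S <- design[[nm]]
    if (!isSymmetric(unname(S)) || any(eigen(S, symmetric = TRUE,
                                             only.values = TRUE)$values <= 0)) {
      stopf("%s must be symmetric positive definite", nm,
            class = "refsimba_design_error")
    }
  }
  if (design$n_per_group < 1) {
    stopf("n_per_group must be >= 1", class = "refsimba_design_error")
  }
  invisible(design)
}

#' Default Feng-1TC base parameter sets for reference curves
#'
#' A small library of synthetic Feng-1TC parameter sets whose predicted
#' curves resemble measured cerebellar TACs (rise over a few minutes to a
#' mid-single-digit kBq/mL peak, slow washout); these play the role of
#' fits to empirical reference TACs when none are supplied.
#'
#' @return A list of [feng1tc_params()].
#' @export
default_reference_params <- function() {
  specs <- list(
    c(60, 1.2, 0.40, 4.0, 0.35, 0.020, 0.45, 1.00, 0.080),
    c(45, 0.9, 0.55, 3.2, 0.28, 0.015, 0.60, 1.10, 0.095),
    c(80, 1.5, 0.30, 5.0, 0.42, 0.025, 0.35, 0.90, 0.070),
    c(55, 1.1, 0.45, 3.6, 0.30, 0.018, 0.50, 1.05, 0.110),
    c(70, 0.8, 0.60, 4.5, 0.38, 0.022, 0.40, 0.95, 0.085)
  )
  lapply(specs, function(v) {
    feng1tc_params(feng_params(v[1], v[2], v[3], v[4], v[5], v[6], v[7]),
                   K1ref = v[8], k2ref = v[9])
  })
}

# per-frame log-sigma offsets shared by reference and target noise:
# frame-duration coefficient plus smooth-over-time, both centred covariates
#' @keywords internal
sigma_frame_offsets <- function(frames, sig) {
  clogdur <- log(frames$duration) - mean(log(frames$duration))
  sig$b_logdur * clogdur + sig$smooth(frames$mid)
}

#' Generate a noisy reference-TAC library
#'
#' Builds a library of simulated reference-region curves: true Feng-1TC
#' parameter sets are sampled with replacement from `base_fits`, each true
#' curve receives measurement noise built in four layered stages —
#' (1) per-frame log-sigma offsets from the frame-duration coefficient and
#' the smooth-over-time function; (2) the mean reference noise scale;
#' (3) a PET-to-PET deviation drawn from Normal(0, `sd_pet_ref`); (4) all
#' summed in log-sigma, then per-frame Gaussian noise with that sigma — and
#' every noisy curve is refit with [fit_feng1tc()] to provide *estimated*
#' parameters alongside the *true* ones. Entries whose refit fails are
#' regenerated with a fresh noise draw, up to `retry_cap` attempts.
#'
#' @param base_fits non-empty list of [feng1tc_params()]; defaults to
#'   [default_reference_params()].
#' @param n library size (the full-scale study design uses 500).
#' @param noise sigma-model parameter list (the `sigma_model` element of a
#'   [default_truth_parameters()] design).
#' @param frames a [frame_schedule()].
#' @param seed integer seed; the library is bit-reproducible given it.
#' @param refit_n_starts restarts for the library refits.
#' @param retry_cap regeneration attempts per entry.
#' @return An object of class `ref_library`: list of entries with
#'   `true_params`, `true_curve`, `measured_curve`, `estimated_params`,
#'   `underfit_flag` and shared `frames`.
#' @export
make_reference_library <- function(base_fits = default_reference_params(),
                                   n = 500,
                                   noise = default_truth_parameters()$sigma_model,
                                   frames = default_frames(), seed = 1,
                                   refit_n_starts = 10, retry_cap = 5) {
  if (length(base_fits) < 1) {
    stopf("base_fits must be non-empty", class = "refsimba_design_error")
  }
  if (n < 1) stopf("n must be >= 1", class = "refsimba_design_error")
  set.seed(seed)
  offs <- sigma_frame_offsets(frames, noise)
  entries <- vector("list", n)
  n_regen <- 0L
  for (i in seq_len(n)) {
    for (attempt in seq_len(retry_cap)) {
      truep <- base_fits[[sample.int(length(base_fits), 1)]]
      truec <- feng1tc_predict(truep, frames)
      pet_dev <- stats::rnorm(1, 0, noise$sd_pet_ref)
      logsig <- noise$ref_intercept + offs + pet_dev
      meas <- truec + stats::rnorm(length(truec), 0, exp(logsig))
      fit <- try(fit_feng1tc(tac(frames, meas), n_starts = refit_n_starts,
                             seed = sample.int(.Machine$integer.max, 1)),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) break
      n_regen <- n_regen + 1L
      fit <- NULL
    }
    if (is.null(fit) || inherits(fit, "try-error")) {
      stopf("library entry %d failed to refit after %d attempts", i,
            retry_cap, class = "refsimba_fit_error")
    }
    entries[[i]] <- list(true_params = truep, true_curve = truec,
                         measured_curve = meas,
                         estimated_params = fit$params,
                         underfit_flag = fit$underfit_flag)
  }
  structure(list(entries = entries, frames = frames, n_regenerated = n_regen),
            class = "ref_library")
}

#' @export
print.ref_library <- function(x, ...) {
  cat(sprintf("<ref_library: %d reference TACs, %d frames>\n",
              length(x$entries), length(x$frames$start)))
  invisible(x)
}

#' @export
length.ref_library <- function(x) length(x$entries)

#' Simulate a full TAC dataset from a design and reference library
#'
#' Generates equal-sized healthy-volunteer and patient groups, each subject
#' measured twice. Healthy volunteers receive placebo between measurements
#' (no mean logBPND change); patients receive active treatment (mean
#' logBPND increases by the design's treatment effect at the second
#' measurement); the patient group mean logBPND sits below the
#' healthy-volunteer mean by the group effect. True PK parameters combine
#' the fixed regional means with multivariate-normal subject deviations and
#' per-TAC (measurement-by-region) deviations, all on the log scale.
#'
#' Each measurement samples a reference-library entry: target TACs are
#' generated from the entry's *true* Feng-1TC parameters, while downstream
#' fitting receives the entry's *estimated* parameters — mirroring real
#' analysis, where only the fitted reference curve is available.
#'
#' @param design a `sim_design`, see [default_truth_parameters()].
#' @param library a `ref_library` from [make_reference_library()].
#' @param seed overrides the design's seed when non-`NULL`.
#' @param regions optional character vector restricting the simulated
#'   regions (e.g. a 3-region subset for fast runs).
#' @return A list of class `sim_dataset` with `tac_table` (long format),
#'   `meta` (one row per measurement), `region_info`, `truth` (the ground
#'   truth table, one row per TAC), `ref_fits` (estimated Feng-1TC
#'   parameters keyed by measurement id), `ref_true`, `frames` and
#'   `design`.
#' @export
simulate_dataset <- function(design, library, seed = NULL, regions = NULL) {
  validate_sim_design(design)
  if (length(library) < 1) {
    stopf("reference library is empty", class = "refsimba_design_error")
  }
  set.seed(seed %||% design$seed)
  reg <- design$regions
  if (!is.null(regions)) {
    reg <- reg[reg$region %in% regions, , drop = FALSE]
    if (nrow(reg) == 0) stopf("no regions left after filtering",
                              class = "refsimba_design_error")
  }
  frames <- library$frames
  offs <- sigma_frame_offsets(frames, design$sigma_model)
  n_sub <- 2L * design$n_per_group
  subjects <- sprintf("sub%03d", seq_len(n_sub))
  groups <- rep(c("HV", "patient"), each = design$n_per_group)

  meta <- data.frame(
    measurement_id = sprintf("%s_m%d", rep(subjects, each = 2), rep(1:2, n_sub)),
    subject_id = rep(subjects, each = 2),
    group = rep(groups, each = 2),
    time = rep(c("pre", "post"), n_sub),
    stringsAsFactors = FALSE)
  meta$condition <- ifelse(meta$group == "HV", "placebo", "treatment")
  meta$centre <- "simcentre"
  meta$age <- rep(stats::rnorm(n_sub, design$age_mean, design$age_sd), each = 2)
  meta$injected_dose <- stats::rlnorm(nrow(meta), design$dose_meanlog,
                                      design$dose_sdlog)

  # subject deviations (shared across the subject's measurements/regions)
  subj_dev <- MASS::mvrnorm(n_sub, mu = rep(0, 3), Sigma = design$Sigma_subject)
  rownames(subj_dev) <- subjects
  # per-subject measurement-error deviation in log sigma
  subj_sig_dev <- stats::setNames(
    stats::rnorm(n_sub, 0, design$sigma_model$sd_subject), subjects)
  reg_sig_dev <- stats::setNames(
    stats::rnorm(nrow(reg), 0, design$sigma_model$sd_region), reg$region)

  clogvol_all <- log(reg$volume_ml) - mean(log(design$regions$volume_ml))
  clogdose <- log(meta$injected_dose) - mean(log(meta$injected_dose))

  truth_rows <- list()
  tac_rows <- list()
  ref_fits <- list(); ref_true <- list()
  for (mi in seq_len(nrow(meta))) {
    m <- meta[mi, ]
    entry <- library$entries[[sample.int(length(library), 1)]]
    ref_fits[[m$measurement_id]] <- entry$estimated_params
    ref_true[[m$measurement_id]] <- entry$true_params
    true_cr <- feng1tc_curve(entry$true_params)
    tac_dev <- MASS::mvrnorm(nrow(reg), mu = rep(0, 3),
                             Sigma = design$Sigma_tac)
    if (nrow(reg) == 1) tac_dev <- matrix(tac_dev, 1)
    for (ri in seq_len(nrow(reg))) {
      sdv <- subj_dev[m$subject_id, ]
      logR1 <- reg$logR1[ri] + sdv[1] + tac_dev[ri, 1]
      logk2p <- design$logk2prime_mean + reg$logk2prime_offset[ri] +
        sdv[2] + tac_dev[ri, 2]
      logBP <- reg$logBPND[ri] + sdv[3] + tac_dev[ri, 3] +
        (m$group == "patient") * design$group_effect_logBPND +
        (m$group == "patient" && m$time == "post") *
          design$treatment_effect_logBPND +
        (m$group == "HV" && m$time == "post") * design$placebo_effect_logBPND
      p <- srtm_params(exp(logR1), exp(logk2p), exp(logBP))
      mu <- srtm_predict(p, true_cr, frames)
      logsig <- design$sigma_model$intercept + offs +
        design$sigma_model$b_logvol * clogvol_all[ri] +
        design$sigma_model$b_logdose * clogdose[mi] +
        subj_sig_dev[m$subject_id] + reg_sig_dev[reg$region[ri]]
      y <- mu + stats::rnorm(length(mu), 0, exp(logsig))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subject_id = m$subject_id, measurement_id = m$measurement_id,
        region = reg$region[ri], group = m$group, time = m$time,
        condition = m$condition,
        R1 = p$R1, k2prime = p$k2prime, BPND = p$BPND,
        logR1 = logR1, logk2prime = logk2p, logBPND = logBP,
        dev_subject_logR1 = sdv[1], dev_subject_logk2prime = sdv[2],
        dev_subject_logBPND = sdv[3],
        dev_tac_logR1 = tac_dev[ri, 1], dev_tac_logk2prime = tac_dev[ri, 2],
        dev_tac_logBPND = tac_dev[ri, 3],
        stringsAsFactors = FALSE)
      tac_rows[[length(tac_rows) + 1L]] <- data.frame(
        subject_id = m$subject_id, measurement_id = m$measurement_id,
        centre = m$centre, region = reg$region[ri],
        frame_start = frames$start, frame_duration = frames$duration,
        activity = y, stringsAsFactors = FALSE)
    }
  }
  region_info <- reg[, c("region", "volume_ml")]
  structure(
    list(tac_table = do.call(rbind, tac_rows),
         meta = meta, region_info = region_info,
         truth = do.call(rbind, truth_rows),
         ref_fits = ref_fits, ref_true = ref_true,
         frames = frames, design = design),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset: %d subjects, %d measurements, %d regions, %d target TACs>\n",
    length(unique(x$meta$subject_id)), nrow(x$meta),
    nrow(x$region_info), nrow(x$truth)))
  invisible(x)
}
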