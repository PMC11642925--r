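#' Specify the hierarchical multivariate TAC model
#'
#' Defines the model: which PK parameters are modelled (log scale
#' throughout), the fixed-effect formula of each, the measurement-error
#' (sigma) model structure, the prior set and the MCMC options. Regional
#' differences in logR1 and logBPND enter as unpooled fixed-effect dummy
#' variables (regional means are too heterogeneous to pool), while
#' subject, region and TAC deviations are partially pooled multivariate
#' random effects; sigma carries subject and region deviations but no
#' TAC-level deviations.
#'
#' @param model `"srtm"` (default) or `"frtm"` (adds logk4).
#' @param fixed named list of one-sided formulas over the metadata columns,
#'   one per PK parameter; defaults model region dummies for logR1 and
#'   logBPND and group/time effects for logBPND.
#' @param age_slopes if `TRUE`, parameters whose fixed formula contains
#'   `age_dec` also receive partially pooled per-region random slopes on
#'   centred age (decades).
#' @param sigma list: `covariates` (use centred log frame duration, region
#'   volume and injected dose), `spline_k` (thin-plate-style smooth-over-
#'   time basis dimension), `subject_dev`, `region_dev`.
#' @param priors as returned by [simba_priors()].
#' @param mcmc list: `chains`, `warmup`, `iter`, `seed`, `adapt_delta`,
#'   `traj_length`, `max_leapfrog`.
#' @return An object of class `simba_spec`.
#' @export
simba_spec <- function(model = c("srtm", "frtm"),
                       fixed = NULL,
                       age_slopes = FALSE,
                       sigma = list(),
                       priors = simba_priors(),
                       mcmc = list()) {
  model <- match.arg(model)
  parameters <- c("logR1", "logk2prime", "logBPND")
  if (model == "frtm") parameters <- c(parameters, "logk4")
  if (is.null(fixed)) {
    fixed <- list(logR1 = ~region, logk2prime = ~1,
                  logBPND = ~ region + group * time)
    if (model == "frtm") fixed$logk4 <- ~1
  }
  missing_f <- setdiff(parameters, names(fixed))
  for (p in missing_f) fixed[[p]] <- ~1
  sigma <- utils::modifyList(
    list(covariates = TRUE, spline_k = 8, subject_dev = TRUE,
         region_dev = TRUE), sigma)
  mcmc <- utils::modifyList(
    list(chains = 3, warmup = 1000, iter = 1000, seed = 1,
         adapt_delta = 0.85, traj_length = 1.2, max_leapfrog = 48,
         divergence_warn = 0.05), mcmc)
  structure(list(model = model, parameters = parameters, fixed = fixed,
                 age_slopes = age_slopes, sigma = sigma, priors = priors,
                 mcmc = mcmc),
            class = "simba_spec")
}

#' Prior set for the hierarchical TAC model
#'
#' Weakly informative defaults: moderately informative normal priors (SD
#' 0.25) on the global log-scale intercepts, centred at values supplied by
#' the analyst so that sampling starts in roughly the right neighbourhood;
#' half-normal priors on hierarchy SDs (0.3 for logR1/logBPND subject and
#' region deviations, 0.1 for logk2prime, 0.025 for all TAC-level
#' deviations — the tight TAC prior is what concentrates explanatory power
#' at the subject and region levels); LKJ(2) on the correlation matrices;
#' normal priors on covariate coefficients (SD 0.1 for age, centre and
#' centre-by-region terms, 0.05 for diagnosis/treatment-type terms, and a
#' wide 2.5 for the unpooled region dummies, whose spread is genuinely
#' large).
#'
#' @param intercept_mean named numeric: prior means of the global
#'   intercepts per PK parameter (log scale). Required knowledge about the
#'   radiotracer; defaults are generic serotonin-receptor-like values.
#' @param intercept_sd prior SD of the intercepts.
#' @param sd_subject,sd_region,sd_tac half-normal scales per PK parameter.
#' @param tac_sd_fixed if `TRUE` (default) the TAC-deviation prior SD is
#'   `sd_tac` exactly — the deviations themselves carry zero-centred
#'   normal priors with that SD, which guarantees posterior shrinkage of
#'   every TAC deviation below 0.025. If `FALSE` the TAC scales are
#'   hyperparameters with half-normal(`sd_tac`) priors, like the subject
#'   and region levels.
#' @param lkj_eta LKJ shape for all correlation blocks.
#' @param coef_sd named vector of coefficient prior SDs by term class.
#' @param k4_prior normal prior (mean, sd) on logk4 intercepts (FRTM).
#' @param sigma list of sigma-model priors: `intercept_mean` (`NA` = derive
#'   as log(5% of the mean peak activity) from the data), `intercept_sd`,
#'   `coef_sd`, `spline_sd`, `sd_subject`, `sd_region` (half-normal
#'   scales), `age_slope_sd` (half-normal scale of region-by-age random
#'   slopes).
#' @return A list of class `simba_priors`.
#' @export
simba_priors <- function(intercept_mean = c(logR1 = 0, logk2prime = log(0.1),
                                            logBPND = 0),
                         intercept_sd = 0.25,
                         sd_subject = c(logR1 = 0.3, logk2prime = 0.1,
                                        logBPND = 0.3, logk4 = 0.1),
                         sd_region = c(logR1 = 0.3, logk2prime = 0.1,
                                       logBPND = 0.3, logk4 = 0.1),
                         sd_tac = c(logR1 = 0.025, logk2prime = 0.025,
                                    logBPND = 0.025, logk4 = 0.025),
                         tac_sd_fixed = TRUE,
                         lkj_eta = 2,
                         coef_sd = c(region = 2.5, age = 0.1, centre = 0.1,
                                     group = 0.05, time = 0.05,
                                     treatment = 0.05, other = 0.5),
                         k4_prior = c(mean = log(0.05), sd = 0.25),
                         sigma = list()) {
  sigma <- utils::modifyList(
    list(intercept_mean = NA_real_, intercept_sd = 1, coef_sd = 0.5,
         spline_sd = 0.5, sd_subject = 0.3, sd_region = 0.3,
         age_slope_sd = 0.1), sigma)
  structure(list(intercept_mean = intercept_mean,
                 intercept_sd = intercept_sd,
                 sd_subject = sd_subject, sd_region = sd_region,
                 sd_tac = sd_tac, tac_sd_fixed = tac_sd_fixed,
                 lkj_eta = lkj_eta, coef_sd = coef_sd,
                 k4_prior = k4_prior, sigma = sigma),
            class = "simba_priors")
}

# classify a model-matrix column name into a coefficient prior class
#' @keywords internal
coef_prior_sd <- function(colnames, coef_sd) {
  vapply(colnames, function(nm) {
    lnm <- tolower(nm)
    if (grepl("centre|center|site", lnm)) return(coef_sd[["centre"]])
    if (grepl("age", lnm)) return(coef_sd[["age"]])
    if (grepl("region", lnm)) return(coef_sd[["region"]])
    if (grepl("group|diagnos|patient|mdd", lnm)) return(coef_sd[["group"]])
    if (grepl("treat|drug", lnm)) return(coef_sd[["treatment"]])
    if (grepl("time|post|session", lnm)) return(coef_sd[["time"]])
    coef_sd[["other"]]
  }, numeric(1))
}

#' Build design matrices and index maps for the hierarchical model
#'
#' Expands the per-measurement metadata to one row per TAC, centres the
#' continuous covariates (age is expressed in centred decades, centred
#' over measurements), builds the per-parameter fixed-effect model
#' matrices (treatment coding, intercept excluded — the global intercept
#' is a separate parameter), the subject/region/TAC index maps, the
#' observation matrix and the sigma-model design (centred log frame
#' duration, centred log region volume, centred log injected dose and a
#' low-rank thin-plate-style spline basis over frame midpoints).
#'
#' @param dataset a `sim_dataset` (or a compatible list with `tac_table`,
#'   `meta`, `region_info`, `ref_fits`, `frames`).
#' @param spec a [simba_spec()].
#' @return A list (class `simba_design`) of matrices and index maps; see
#'   the source for the fields.
#' @export
build_design <- function(dataset, spec) {
  tt <- dataset$tac_table
  meta <- dataset$meta
  reg_info <- dataset$region_info
  frames <- dataset$frames

  keys <- unique(tt[, c("subject_id", "measurement_id", "region")])
  keys <- keys[order(keys$subject_id, keys$measurement_id, keys$region), ,
               drop = FALSE]
  rownames(keys) <- NULL
  n_tac <- nrow(keys)
  subjects <- sort(unique(keys$subject_id))
  regions <- reg_info$region
  measurements <- sort(unique(keys$measurement_id))
  if (length(subjects) < 2 || length(regions) < 2) {
    stopf("the hierarchical model needs >= 2 subjects and >= 2 regions",
          class = "refsimba_design_error")
  }

  mrow <- match(keys$measurement_id, meta$measurement_id)
  if (anyNA(mrow)) {
    stopf("metadata missing for measurement(s): %s",
          paste(unique(keys$measurement_id[is.na(mrow)]), collapse = ", "),
          class = "refsimba_design_error")
  }
  data_tac <- meta[mrow, , drop = FALSE]
  data_tac$region <- factor(keys$region, levels = regions)
  if (anyNA(data_tac$region)) {
    stopf("region(s) absent from region_info", class = "refsimba_design_error")
  }
  if ("age" %in% names(data_tac)) {
    age_by_meas <- meta$age
    data_tac$age_dec <- (data_tac$age - mean(age_by_meas)) / 10
  }
  # reference levels: healthy pre-measurement placebo baseline
  preferred <- list(group = c("HV", "control", "patient"),
                    time = c("pre", "post"),
                    condition = c("placebo", "treatment"))
  for (nm in intersect(c("group", "time", "condition", "centre"),
                       names(data_tac))) {
    lev <- unique(as.character(data_tac[[nm]]))
    if (nm %in% names(preferred)) {
      lev <- c(intersect(preferred[[nm]], lev), sort(setdiff(lev, preferred[[nm]])))
    } else lev <- sort(lev)
    data_tac[[nm]] <- factor(data_tac[[nm]], levels = lev)
  }

  X <- list(); coef_sds <- list()
  for (p in spec$parameters) {
    f <- spec$fixed[[p]]
    vars <- all.vars(f)
    missing_vars <- setdiff(vars, names(data_tac))
    if (length(missing_vars)) {
      stopf("covariate(s) not found in metadata for %s: %s", p,
            paste(missing_vars, collapse = ", "),
            class = "refsimba_design_error")
    }
    for (v in vars) {
      if (is.factor(data_tac[[v]]) && nlevels(droplevels(data_tac[[v]])) < 2) {
        stopf("covariate '%s' has a single level; cannot enter the design", v,
              class = "refsimba_design_error")
      }
    }
    mm <- stats::model.matrix(f, data_tac)
    mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
    X[[p]] <- mm
    coef_sds[[p]] <- coef_prior_sd(colnames(mm), spec$priors$coef_sd)
  }

  sub_idx <- match(keys$subject_id, subjects)
  reg_idx <- match(keys$region, regions)
  meas_idx <- match(keys$measurement_id, measurements)

  # observation matrix, TACs x frames, in key order
  H <- length(frames$mid)
  tt_key <- paste(tt$subject_id, tt$measurement_id, tt$region)
  key_key <- paste(keys$subject_id, keys$measurement_id, keys$region)
  Y <- matrix(NA_real_, n_tac, H)
  ord <- order(match(tt_key, key_key), tt$frame_start)
  tts <- tt[ord, ]
  if (nrow(tts) != n_tac * H) {
    stopf("TAC table is not rectangular over a shared frame schedule",
          class = "refsimba_design_error")
  }
  Y <- matrix(tts$activity, n_tac, H, byrow = TRUE)

  # sigma design
  clogdur <- log(frames$duration) - mean(log(frames$duration))
  vol <- reg_info$volume_ml[match(keys$region, reg_info$region)]
  clogvol <- log(vol) - mean(log(reg_info$volume_ml))
  dose <- meta$injected_dose[mrow]
  clogdose <- if (is.null(dose)) rep(0, n_tac) else log(dose) - mean(log(meta$injected_dose))
  kb <- max(3, spec$sigma$spline_k)
  sm <- mgcv::smoothCon(mgcv::s(t, k = kb, bs = "tp"),
                        data = data.frame(t = frames$mid),
                        absorb.cons = TRUE)[[1]]
  B <- sm$X  # H x (kb - 1)
  B <- scale(B, center = FALSE, scale = apply(abs(B), 2, max))  # unit scale

  age_dec <- if ("age_dec" %in% names(data_tac)) data_tac$age_dec else rep(0, n_tac)
  slope_params <- if (spec$age_slopes) {
    spec$parameters[vapply(spec$parameters, function(p)
      "age_dec" %in% all.vars(spec$fixed[[p]]), logical(1))]
  } else character(0)

  ref_list <- dataset$ref_fits[keys$measurement_id]
  if (any(vapply(ref_list, is.null, logical(1)))) {
    stopf("missing reference fit for measurement(s): %s",
          paste(unique(keys$measurement_id[vapply(ref_list, is.null,
                                                  logical(1))]),
                collapse = ", "),
          class = "refsimba_design_error")
  }

  structure(
    list(keys = keys, data_tac = data_tac, X = X, coef_sds = coef_sds,
         subjects = subjects, regions = regions, measurements = measurements,
         sub_idx = sub_idx, reg_idx = reg_idx, meas_idx = meas_idx,
         Y = Y, frames = frames, clogdur = clogdur, clogvol = clogvol,
         clogdose = clogdose, B = B, age_dec = age_dec,
         slope_params = slope_params, ref_list = ref_list),
    class = "simba_design")
}
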