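# refsimba

Simultaneous hierarchical Bayesian quantification and analysis of PET
time-activity curve (TAC) data with reference-tissue models.

## What problem this solves, and for whom

PET neuroimaging studies conventionally quantify each time-activity curve
independently (nonlinear least squares per region per scan) and then feed
the binding estimates into a separate statistical model. For researchers
running reference-tissue designs — the common non-invasive setting where a
region devoid of specific binding (e.g. cerebellum) replaces arterial
sampling — this two-stage pipeline wastes information twice: each TAC is
fit as if the rest of the sample did not exist, and the group analysis
ignores the first stage's estimation error.

`refsimba` fits **all TACs of all regions of all subjects at once** in a
single hierarchical multivariate Bayesian model whose likelihood is the
kinetic model itself (SRTM by default, FRTM optionally). Log-scale PK
parameters get crossed subject/region/TAC random effects with multivariate
shrinkage, covariates (group, treatment, age, centre and centre-by-region
harmonisation terms) enter the same posterior as quantification, and the
measurement-error model is structured (frame duration, region volume,
injected dose, a smooth over frame time, subject and region pooling).

The model for each log PK parameter *i*, subject *j*, region *k* is

    theta[i,j,k] = alpha[i] + X[j,k]' beta[i] + tau[i,j] + upsilon[i,k] + phi[i,j,k]

with `tau`, `upsilon`, `phi` multivariate-normal deviation vectors across
the PK parameters (LKJ-correlated), and the data model

    C_T(t_h) ~ Normal(f_SRTM(theta; C_R)(t_h), sigma[h])

where `C_R` is a 9-parameter analytic reference-curve model (a Feng-type
input shape convolved with a one-tissue impulse response) so that all
convolutions evaluate in closed form. Around the model sit: a bounded
multi-start reference-curve fitter with automated underfit detection, a
conventional per-TAC NLS comparator, a realistic TAC simulator (two
groups, pre/post placebo vs treatment, layered measurement noise, a noisy
reference-curve library), and an evaluation framework (regional RMSE and
correlation against simulated truth, mixed-model comparator, power and
false-positive rates via log-density-spline tail integration).

## Worked example

Simulate a small two-group pre/post study (4 subjects per group, three
regions including the small low-binding dorsal-brain-stem analogue), fit
it conventionally and hierarchically, and compare accuracy:

```r
library(refsimba)

design <- default_truth_parameters(n_per_group = 4, seed = 401)
lib    <- make_reference_library(n = 10, noise = design$sigma_model, seed = 402)
ds     <- simulate_dataset(design, lib, seed = 403, regions = c("DBS", "FC", "OC"))

nls <- fit_dataset_nls(list(tac_table = ds$tac_table, ref_fits = ds$ref_fits),
                       n_starts = 3, seed = 404)

reg <- design$regions
spec <- simba_spec(
  priors = simba_priors(intercept_mean = c(
    logR1 = reg$logR1[reg$region == "DBS"],
    logk2prime = design$logk2prime_mean,
    logBPND = reg$logBPND[reg$region == "DBS"])),
  mcmc = list(chains = 2, warmup = 500, iter = 400, seed = 405))
fit <- fit_simba(ds, spec)

acc_simba <- accuracy_metrics(tac_estimates(fit), ds$truth, scope = "all")
acc_nls   <- accuracy_metrics(nls[nls$converged & nls$reliable, ],
                              ds$truth, scope = "all")
tab <- rmse_reduction(acc_simba, acc_nls)$table
tab[tab$parameter == "BPND", ]
```

On this run the BPND rows of the reduction table print:

```
  region parameter     rmse_a     rmse_b reduction_pct
1    DBS      BPND 0.03556796 0.07822047     54.528570
4     FC      BPND 0.05146399 0.05233000      1.654893
7     OC      BPND 0.12142869 0.12349373      1.672190
```

`rmse_a` is the hierarchical fit's posterior-mean error, `rmse_b` the
per-TAC NLS error (unreliable conventional fits excluded), and
`reduction_pct = 100*(1 - rmse_a/rmse_b)`: the one-stage model cuts the
BPND error in every region, most strongly (55%) in the small noisy
DBS-like region, which is exactly where partial pooling has the most to
offer. The treatment-minus-placebo contrast
(`extract_contrast(fit, setNames(1, treatment_contrast_name(fit)))`)
prints a posterior mean of 0.064 with SD 0.013 for the simulated +0.04
logBPND effect — within posterior uncertainty at this very small n — and
`effective_parameters(fit)` reports 2.7 effective parameters per TAC
despite the nominal hundreds: the shrinkage at work.

A thin command-line wrapper over the same functions ships at
`inst/cli/refsimba.R` (subcommands `simulate`, `fit-ref`, `fit-nls`,
`fit-simba`, `evaluate`, `power`).

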