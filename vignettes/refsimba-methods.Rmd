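---
title: "Hierarchical multivariate modelling of reference-tissue PET time-activity curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multivariate modelling of reference-tissue PET time-activity curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Conventional PET quantification is a two-stage exercise: fit a
pharmacokinetic model to each time-activity curve (TAC) independently, then
carry the per-region binding estimates into a second-stage statistical
model. Both stages leak efficiency — the per-TAC fits ignore everything the
rest of the sample knows about plausible parameter values, and the
second-stage model ignores the estimation uncertainty of the first.

`refsimba` implements a one-stage alternative for *non-invasive*
(reference-tissue) quantification: all TACs of all regions of all subjects
are modelled simultaneously in a hierarchical, multivariate Bayesian model
whose likelihood is the kinetic model itself. Partial pooling shrinks
region-by-subject (TAC-level) estimates towards what the sample supports,
multivariate priors exploit correlations between the kinetic parameters,
and covariate effects (group, treatment, age, centre) are estimated jointly
with quantification, in the same posterior.

## Kinetic forward models

The package supports the simplified and full reference tissue models. SRTM
is parameterised by the relative delivery $R_1$, the reference-region
clearance $k_2'$ and the binding potential $BP_{ND}$, with derived rates
$k_2 = R_1 k_2'$ and $k_{2a} = k_2 / (1 + BP_{ND})$:

$$C_T(t) = R_1\,C_R(t) + (k_2 - R_1 k_{2a})\,\bigl(C_R \otimes
e^{-k_{2a} t}\bigr)(t).$$

$k_2'$ rather than $k_2$ is the sampled quantity because it is a property
of the shared reference region: pooling it towards a common mean is
biologically defensible. FRTM adds the dissociation rate $k_4$ (with
$k_3 = BP_{ND} k_4$); its two-exponential kernel is derived from the usual
compartmental roots, with the degenerate equal-root case handled by an
exact polynomial-times-exponential limit. FRTM is implemented and tested
but not the default: with four parameters per TAC it is poorly identified
for typical single-tracer designs, and the SRTM posterior is the one the
evaluation framework exercises.

### Analytic convolution

Numerical convolution inside an MCMC likelihood is prohibitively slow, so
every curve lives in a closed family: finite sums of terms
$c\,(t-t_0)^p e^{-\lambda (t-t_0)}$, zero before the onset $t_0$
(`expmix`). This family contains the reference-curve model and is closed
under convolution with single exponentials:

$$c\,u^p e^{-\lambda u} \otimes e^{-\theta u} =
c\,p!\,d^{-(p+1)} e^{-\theta u} - c\,p! \sum_{m=0}^{p}
\frac{d^{m-p-1}}{m!}\,u^m e^{-\lambda u}, \qquad d = \lambda - \theta,$$

with the repeated-root limit $c\,u^{p+1}e^{-\lambda u}/(p+1)$ used when
$|d| < 10^{-6}$ per minute (below that gap the two forms agree to within
floating-point noise for realistic rates; the event itself has measure
zero in any fit). Model predictions therefore evaluate exactly, and the
test suite checks them against a kink-aware trapezoidal numerical
convolution oracle at a relative tolerance of $10^{-4}$.

Predictions are evaluated at frame midpoints by default. Frames average
the activity over their duration, so an exact frame-integral mode
(analytic incomplete-gamma integrals of the same terms) is available via
`frame_average = TRUE`; for the default 93-minute, 38-frame schedule the
two conventions differ by well under the measurement noise except in the
first seconds after onset.

### The reference curve

Reference-tissue models convolve with the measured reference TAC, which is
noisy. The package fits a parametric description first: a Feng-type
tri-exponential input shape with a linear rise, convolved with a
one-tissue impulse response, plus an onset time — nine parameters in
total. None of them is biologically interpretable; the model is a
descriptive basis chosen because it resembles real reference TACs and
convolves analytically. The two tail components of the Feng shape are
exchangeable and are canonically ordered at construction; the linear-rise
component must carry the fastest rate (swapping it with a tail pair would
change the curve, so the constructor rejects that configuration and the
default fitting box keeps the rates separated).

Fitting uses bounded multi-start Levenberg–Marquardt, weighted by frame
duration (frames integrate counts, so long frames carry proportionally
more information; uniform weights are a config switch). Because the model
is linear in its three amplitude coefficients given the rates, each random
restart draws only the five nonlinear parameters (rates log-uniform inside
the bounds) and solves the amplitudes by weighted least squares before
polishing — a variable-projection start that makes restarts far more
productive than naive uniform draws. In place of the visual inspection
such over-parameterised fits normally require, an automated underfit check
flags fits whose duration-weighted $R^2$ falls below 0.98 (strictly-below
convention) or whose longest run of same-sign residuals exceeds 8 frames.
Restarting continues until a passing fit reaches an attainable-RSS floor
estimated from late-frame second differences of the data (with the fitted
curve's own smooth contribution subtracted), so a barely-passing local
optimum cannot pre-empt a near-exact fit; on noiseless curves this drives
recovery to numerical precision, on realistic noise it accepts after one
or two starts.

## The hierarchical model

Each log-scale PK parameter $i$ of subject $j$ and region $k$ has a linear
predictor

$$\theta_{i,j,k} = \alpha_i + X_{j,k}^{\mathsf T}\beta_i + \tau_{i,j} +
\upsilon_{i,k} + \phi_{i,j,k},$$

with multivariate-normal subject, region and TAC deviation vectors (one
$m$-vector per unit, correlated across the $m$ PK parameters; LKJ(2)
priors on the correlation matrices). Working on the log scale makes
deviations proportional: a $+0.3$ subject deviation in $\log BP_{ND}$
multiplies that subject's expected $BP_{ND}$ by $e^{0.3} \approx 1.35$ in
every region. Regional means of $\log R_1$ and $\log BP_{ND}$ are too
heterogeneous to pool and enter as unpooled fixed-effect dummies instead.
The TAC unit is one measured curve — a measurement-by-region cell — so a
subject measured twice contributes two TAC deviations per region while
sharing one subject deviation.

The measurement error model is heteroscedastic and structured:
$\log\sigma$ for each frame is a global intercept plus partially pooled
subject and region deviations (no TAC-level deviations — error magnitude
is driven by measurement- and region-level physics, and freeing it per TAC
would soak up residual misfit), plus centred log frame duration, centred
log region volume and centred log injected dose, plus a low-rank
thin-plate-style spline over frame time (8 basis functions, ridge prior)
capturing the error trend that frame duration alone does not explain.

### Priors

Global intercepts: normal with SD 0.25, centred at analyst-supplied values
(`simba_priors(intercept_mean = ...)`) — required tracer knowledge that
puts initialisation in the right neighbourhood. Subject and region
deviation SDs: half-normal with scale 0.3 for $\log R_1$ and
$\log BP_{ND}$, 0.1 for $\log k_2'$. TAC deviations: prior SD 0.025
**fixed** by default (`tac_sd_fixed = TRUE`), i.e. the deviations
themselves carry zero-centred normal priors with that SD. The alternative
reading — a half-normal hyperprior with scale 0.025 on a learned TAC SD —
is available behind the same switch; we default to the fixed form because
it is the reading under which TAC-level shrinkage is guaranteed
(the posterior SD of every TAC deviation must fall below 0.025), whereas a
learned scale can absorb reference-curve estimation error and drift above
its prior scale. Covariate coefficients: normal, SD 0.1 for age, centre
and centre-by-region terms, 0.05 for diagnosis/treatment-type terms, and
2.5 for the unpooled region dummies (their spread is genuinely large).
Region-by-age random slopes (enabled with `age_slopes = TRUE` for
parameters whose formula includes `age_dec`, age in centred decades) get
half-normal(0.1) scales. The FRTM variant places a normal prior on
$\log k_4$ (mean $\log 0.05$, SD 0.25).

### Sampling

The posterior is sampled with a package-authored adaptive Hamiltonian
Monte Carlo sampler: analytic gradients throughout the hierarchy, sigma
model, transforms and priors; the kinetic-curve Jacobian with respect to
the three log-scale PK parameters uses central finite differences batched
across all TACs (the forward model is fully vectorised, so one
full-dataset prediction is a handful of matrix operations). All deviation
blocks are non-centred (essential at the 0.025 TAC scale). The
unconstrained scales span several orders of magnitude, so the initial
diagonal mass matrix comes from a finite-difference curvature estimate at
the initialisation point, followed by Stan-style expanding adaptation
windows with dual-averaged step size (target acceptance 0.85), a fixed
target trajectory length with jittered leapfrog counts, and divergence
counting (energy error > 1000). Chains initialise from a fast conventional
NLS pass (intercepts and fixed effects from a regression of per-TAC NLS
estimates), the standard practice for these posteriors, with per-chain
jitter. Split-$\hat R$ and a lag-one effective sample size are reported
for every parameter; a divergence rate above the configured threshold
raises a warning, never a silent pass.

At the scaled-down sizes used in the tests and the acceptance script
(8–10 subjects, 3 regions, 2 short chains) the sampler's posterior means
are stable and recover the generating hierarchy within posterior
uncertainty, but split-$\hat R$ for some TAC-level coordinates remains
above 1.1 — posterior *means* converge much faster than full mixing. The
documented study sizes in the field run chains hours-to-days; the
package's defaults (3 chains, 1000 + 1000 iterations) are intended for
real use, while tests deliberately run shorter.

## The simulator

`default_truth_parameters()` defines the study conditions: nine regions
(ACC, AMG, DBS, FC, HIP, INS, OC, THA, VSTR) with fixed regional mean
$\log R_1$ and $\log BP_{ND}$ (regional means span $BP_{ND}$ 0.28–2.8 — an
order of magnitude — with DBS a small, 2.2 mL, medium-to-low-binding
region), a global mean $k_2' = 0.10$ per minute with small fixed regional
offsets, multivariate subject deviations (SDs 0.06/0.10/0.22 with a 0.6
$R_1$–$BP_{ND}$ correlation), independent TAC deviations (SDs
0.020/0.025/0.030), a patient-group offset of $-0.08$ on $\log BP_{ND}$
and an active-treatment offset of $+0.04$ (placebo 0). Healthy volunteers
and patients in equal numbers are each measured twice (pre/post). All
values are synthetic defaults — plausible for a serotonin-receptor tracer
— and every one is configurable.

The noise model is the four-stage layered construction: per-frame
$\log\sigma$ offsets from the frame-duration coefficient and the smooth
over time; a mean noise scale; a PET-to-PET normal deviation in
$\log\sigma$; all summed in log space before drawing per-frame Gaussian
noise. The physically motivated exponents are fixed at $-0.5$ for both
frame duration and region volume (counting statistics), and the global
scale ($\log 0.48$ kBq/mL at centred covariates) was calibrated once, on
a small grid over independent calibration seeds, so that pooled
conventional per-TAC NLS in the DBS-like region operates at the
documented error regime for such designs ($BP_{ND}$–truth correlation
near 0.78, with degenerate ridge fits excluded by the reliability flag);
the calibration grid and its result are fixed and not revisited per run.
What the simulator does *not* emulate: PET image resolution
and partial-volume effects, motion, reconstruction artefacts,
attenuation-correction bias, or non-Gaussian low-count noise — so passing
tests demonstrate statistical behaviour under the stated generative
model, not robustness to scanner physics.

The reference-curve library mirrors real analysis: *true* Feng-1TC
parameter sets are sampled with replacement from a base set, noisy
*measured* curves are generated, and each is refit to give *estimated*
parameters. Target TACs are always generated from the *true* reference
parameters while all downstream fitting receives only the *estimated*
ones — reference-curve estimation error is therefore part of every
evaluation.

## Evaluation framework

Accuracy is assessed on the natural parameter scale (a log-scale switch
exists) as per-region RMSE and Pearson correlation against the truth
table, conventionally restricted to baseline measurements of the control
group; improvements are summarised as percentage RMSE reductions with
unweighted means and medians across regions. The univariate comparator is
a mixed model on per-TAC $\log BP_{ND}$ estimates (group, time,
group-by-time, region fixed effects; subject random intercepts;
Satterthwaite tests), whose group-by-time coefficient is the
treatment-minus-placebo difference-in-differences. Power and
false-positive rates over simulation replicates are estimated by
integrating the tail of a smooth log-density fitted to the per-replicate
decision statistics — a penalised Poisson regression of fine histogram
counts on a spline basis (Lindsey's method) — with the exact rejection
proportion always reported alongside and used as the fallback for
degenerate inputs; confidence intervals come from bootstrapping the
replicates. The decision rule for posterior contrasts is posterior mean
over posterior SD against a two-sided 1.96 threshold; the mixed model uses
$p < 0.05$.

Large replicate counts are made tractable by running the mixed-model
calibration at the estimate level: replicates draw true $\log BP_{ND}$
values from the hierarchy and add independent per-region estimation noise
whose SDs are measured from an actual NLS batch, preserving the estimate
distribution that drives the comparator's operating characteristics
without refitting hundreds of thousands of curves. Full end-to-end
replicates (including per-replicate hierarchical fits, for the posterior
false-positive-rate check at 20 replicates) are provided as the opt-in
long-running script `scripts/full_scale_power.R`; they are far outside a
test suite's budget.

## Problem sizes used by the tests and the acceptance script

The shipped checks run deliberately scaled-down studies: the shared test
fit uses 8 subjects, 3 regions and 2 chains of 500 + 400 iterations; the
acceptance script pools the conventional-NLS accuracy estimate over three
independent 20-curve reference libraries with four simulated datasets
each (12 subjects per group; roughly 570 DBS estimates after excluding
flagged fits — pooling across libraries and datasets averages the
library- and dataset-level noise components, mirroring the pooled
construction of large simulation studies), runs 500 mixed-model null
replicates, and fits the hierarchical model to one 10-subject, 3-region
dataset with 2 chains of 350 + 300. These sizes were chosen as the
smallest at which the qualitative claims (regional RMSE improvement
everywhere, nominal false-positive rate, contrast recovery) are stable
across seeds.

## Known limitations

* The sampler is a straightforward adaptive HMC, not a full tree-building
  NUTS; it mixes slower per gradient evaluation, which the curvature
  initialisation and window adaptation only partly offset.
* FRTM support is structural: with realistic designs its posterior is
  weakly identified, matching the experience reported for this model
  family, and no acceptance check exercises it.
* Effective parameters use the pointwise-variance (information-criterion
  penalty) estimator without Pareto-smoothed importance weighting; a
  diagnostic flags observations whose pointwise variance exceeds 0.4.
* The multi-centre covariate machinery (centre and centre-by-region fixed
  effects) is implemented and design-tested, but no empirical multi-centre
  data ship with the package.
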