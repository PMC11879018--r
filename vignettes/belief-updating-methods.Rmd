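---
title: "Methods: the reduced Bayesian observer and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the reduced Bayesian observer and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helibelief)
```

## The task and its generative model

The predictive inference ("helicopter") task asks for a prediction on
a 0–100 screen scale on every trial. Outcomes are Gaussian around a
hidden mean; the mean relocates abruptly at change points. The default
session mirrors the scanner protocol this package emulates: 280 trials
in 4 runs of 70, outcome noise SD alternating 2.3 / 4.6 / 2.3 / 4.6
screen units across runs, a forced change point at each run start, and
binary reward labels on the bags. A bag counts as caught when the
prediction lies within ±5 screen units of the drop.

Three generator choices deserve comment:

* **Hazard rate.** The true change-point spacing of the original fixed
  trajectory is not publicly documented; we default to `hazard = 0.125`
  (about one change per eight trials), which is typical for this task
  family and yields the episodic structure — two to three changes per
  20-trial stretch — that the normative trajectories are usually
  illustrated with. It is a config field, not a constant.
* **Truncation by rejection.** Outcomes falling off the scale are
  redrawn, not clipped. Clipping would pile probability mass on the
  scale edges and contaminate the cubic edge regressor used in the
  update regression.
* **Mean margin.** New means are drawn uniformly at least 10 units
  from the edges, mirroring the visible landscape and avoiding
  edge-saturated blocks. Reward labels are Bernoulli(0.5): reward is
  non-informative for tracking, and a symmetric rate maximizes the
  variance available to the reward term of the regression.

## The reduced Bayesian observer

The observer approximates exact Bayesian filtering with a Gaussian of
matched mean and variance. Its state is the belief $B_t$ and the
relative uncertainty $\tau_t \in [0,1)$, the share of predictive
variance attributable to uncertainty about the mean
($\tau = \sigma_b^2/(\sigma_b^2+\sigma_n^2)$, hence total predictive
variance $\sigma_n^2/(1-\tau)$). Each trial:

1. **Change-point probability.**
   $\Omega_t$ is the posterior probability that the outcome came from
   a relocated mean (uniform density $1/W$) rather than from noise
   around the belief:
   $\Omega_t = \dfrac{H/W}{H/W + (1-H)\,\mathcal N(\delta_t; 0,
   \sigma_n^2/(1-\tau_t))}$.
2. **Learning rate.** $\alpha_t = \Omega_t + (1-\Omega_t)\tau_t$, and
   (in self mode) $B_{t+1} = B_t + \alpha_t \delta_t$.
3. **Uncertainty update.**
   $\tau_{t+1} = N_t/(N_t+\sigma_n^2)$ with
   $N_t = \Omega_t\sigma_n^2 + (1-\Omega_t)\tau_t\sigma_n^2 +
   \Omega_t(1-\Omega_t)\bigl(\delta_t(1-\tau_t)\bigr)^2$ — a mixture of
   the change and no-change branch variances plus the between-branch
   spread. The closed forms $\tau' = \tau/(\tau+1)$ at $\Omega = 0$ and
   $\tau' = 1/2$ at $\Omega = 1$ anchor the unit tests.

The exact recursion sheet used by the original analysis of this task
family is not available to us; the recursions above are the standard
matched-mean/variance reduction of the full change-point filter, and
the package treats them as its own fixed design. Their adequacy is not
assumed but measured: `full_bayes_oracle()` runs exact grid filtering
(401-point discretization, uniform redraw on change), and the
self-mode belief tracks its posterior mean with a mean absolute
difference well under one screen unit on 70-trial sessions at both
noise regimes, with the oracle agreement asserted in the test suite at
a frozen bound of 2.5 screen units per schedule (mean across seeds
below 1.5), calibrated once from the first oracle comparison and not
revisited.

Further observer conventions:

* $\tau$ resets to `tau_init = 0.5` (and, in self mode, the belief to
  the scale midpoint) at run boundaries — runs are separate scanner
  blocks that restart the helicopter.
* In *empirical* mode the belief is replaced by the participant's
  actual prediction each trial, so CPP/RU are conditioned on the
  individually observed prediction errors; this is the mode used when
  fitting behaviour.
* Missing trials freeze the observer state by default (nothing was
  processed by the participant's update); advancing on the outcome
  alone is available via `missing_advance = TRUE`.
* The observer assumes the true run-wise noise SD is known, as the
  noise regimes are instructed and practised in the task.
* $\tau = 1$ would make predictive variance infinite; it is rejected
  as an invalid state rather than propagated.

## Simulated agents and the synthetic cohort

Agents mirror the update regression generatively. The intended update
is
$w_{PE}\,\delta + w_{CPP}\,\delta\Omega + w_{RU}\,\delta\tau(1-\Omega)
+ w_{reward}\,\delta r + \text{bias} + \text{edge} + \varepsilon$,
with the agent computing $\Omega$ and $\tau$ online from its own
prediction errors. Motor noise, lapses (uniform prediction),
perseveration (zero update) and missing trials complete the
behavioural repertoire. Because the agent's internal recursion and the
empirical-mode observer are the same deterministic function of
predictions and outcomes, the fitting stage sees exactly the
regressors the agent used — the premise of the parameter-recovery
tests, which recover generative weights with median bias below 0.02
over 100 sessions at motor noise SD 2.

The cohort presets are fixed once and anchored to the coefficient
magnitudes this task family reliably produces: the control-like preset
uses $w_{PE} = 0.78$, $w_{CPP} = 0.18$, $w_{RU} = 0.15$,
$w_{reward} = 0.03$ with motor noise 3; the psychosis-spectrum-like
preset down-weights CPP ($0.05$), leans slightly more on RU ($0.20$),
updates more noisily (motor noise 4) and perseverates more (12% versus
5%), with equal 4% missing rates. These choices generate the
qualitative group signature of interest — higher performance error,
slower post-change-point learning, and a negative CPP term in the
group-status logistic — without tuning any analysis stage toward it.
Covariates (age, delusional-ideation and symptom scores, cognitive
domains) are Gaussian sketches with group-specific means and optional
couplings from true agent weights to symptom scores for power studies.

What the synthetic data do **not** emulate: real motor dynamics and
reaction-time structure (response times are a capped lognormal
placeholder), instructed-versus-learned noise calibration, item-level
psychometrics of the questionnaires, and any true neurovascular
physiology. Passing tests therefore demonstrate internal consistency
and statistical calibration of the pipeline, not clinical validity of
the presets.

## Behavioural statistics

* **Empirical learning rate**: the update following a prediction
  error, $U_t/\delta_t$. Rates above 1 are clipped to 1 and negative
  rates to 0 for aggregates; trials with $|\delta| < 1$ screen unit
  are excluded (the ratio is numerically explosive there), and raw
  rates below −0.1 can optionally be excluded as aberrant
  (a sensitivity filter, off by default).
* **Update categories**: non- (< 0.1), moderate- and total-updates
  (≥ 0.9) by default, with the stricter 0.01 non-update bound
  available by configuration.
* **Performance error** defaults to the per-trial mean of
  $|B_t - \mu_t|$ (the scale on which cohort means of 6–8 screen units
  are interpretable); a summed-per-block mode is available.
* **Update regression**: OLS of updates on centred
  $\{\delta,\ \delta\Omega,\ \delta\tau(1-\Omega),\ \delta r,\
  ((B-50)/50)^3\}$ plus an intercept. Reward enters as an interaction
  with the prediction error by default — the effect of interest is a
  scaling of update magnitude after rewarded trials — with main-effect
  coding available. Constant columns (e.g. an all-sand run) are
  dropped with a warning rather than producing a silent rank-deficient
  fit. Residuals are returned on the full trial grid for the fMRI
  stage.
* **Group and symptom models**: Welch t plus Wilcoxon rank-sum on
  every group metric (with an optional >3-MAD outlier sensitivity
  re-test, a concrete rule standing in for ad-hoc outlier removal);
  logistic regression of group status on the four update coefficients,
  reporting Wald and likelihood-ratio p-values — the latter because
  quasi-separation, which a strong group effect readily produces at
  n = 59, collapses Wald statistics; a ridge-penalized fit is attached
  as a flagged fallback. No multiple-testing correction is applied:
  the behavioural statistics are reported uncorrected by design, and
  users should correct downstream as their study demands.

## The first-level fMRI model

The design follows standard event-related practice: bag-drop onsets as
1-s events, parametrically modulated by outcome location, CPP, RU,
reward and the update-regression residual; an error regressor spanning
whole missing trials; six motion nuisance columns; per-run intercepts.
Modulators are standardized **within run** (the noise regime
alternates by run, so session-level standardization would fold regime
offsets into the modulators; session mode is a switch) and are *not*
orthogonalized — the collinearity audit in the tests shows the
convolved modulator columns correlate below |0.2| on default sessions,
and beta recovery is unbiased regardless.

Numerical conventions: convolution at 16 microtime bins per TR
(TR = 0.8 s); the canonical double-gamma HRF (peak ≈ 5 s, undershoot
≈ 15 s, 32-s support) is normalized by its analytic continuous peak so
kernels sampled at different resolutions agree exactly; synthetic BOLD
noise is AR(1) with configurable lag-1 correlation, and estimation
optionally prewhitens with a known or residual-estimated coefficient
(exact scaling of the first sample). High-pass filtering is omitted in
simulation — no drift is simulated by default — since the real
acquisition's filter cutoff is not part of this package's contract.
Volume-of-interest statistics (Spearman correlations with symptom and
cognition scores; group comparison controlling for age) operate on
per-subject scalars and make no spatial claims.

## Problem sizes and runtime envelope

The shipped simulations are sized for a laptop-class single core:
280-trial sessions, 20-seed oracle comparisons, 100-seed parameter
recovery, 250-seed null calibrations, 40-seed power runs and
200-replicate GLM coverage checks. These sizes give Monte-Carlo
standard errors comfortably inside every asserted band; all of them
are arguments, and scale up linearly if tighter calibration is wanted.

## Known limitations

* The observer recursions are one member of the reduced-filter family;
  alternatives (e.g. run-length-weighted variance terms) would change
  CPP/RU trajectories slightly. The oracle comparison bounds, but does
  not eliminate, this approximation.
* The agents' lapse/perseveration machinery is memoryless; real
  perseveration is autocorrelated.
* The group logistic model frequently sits at quasi-separation for
  strong group effects; inference there leans on the likelihood-ratio
  test, and the ridge fallback is descriptive, not inferential.
* The fMRI stage validates design construction and estimation, not
  spatial preprocessing; there is no NIfTI pipeline here.
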