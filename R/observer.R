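# Reduced Bayesian observer: change-point probability (CPP), relative
# uncertainty (RU) and the model learning rate, plus a grid-based fully
# Bayesian filter used as a validation oracle.

#' Observer configuration
#'
#' Settings for the reduced Bayesian observer. The observer tracks a
#' hidden mean on a bounded scale under Gaussian outcome noise and a
#' constant per-trial hazard of an abrupt change point. Its learning
#' rate combines the posterior change-point probability (CPP, \eqn{\Omega})
#' with the relative uncertainty about the current belief (RU, \eqn{\tau}),
#' the share of total predictive variance attributable to uncertainty
#' about the hidden mean.
#'
#' @param hazard Prior per-trial probability of a change point, in (0, 1).
#' @param scale_min,scale_max Bounds of the outcome scale (screen units).
#' @param tau_init Relative uncertainty at the start of each run, in `[0, 1)`.
#' @param belief_init Initial belief at the start of each run (self mode);
#'   defaults to the scale midpoint.
#' @param conditioning `"self"`: the observer propagates its own belief
#'   (`B' = B + alpha * delta`). `"empirical"`: the belief is replaced
#'   each trial by the participant's actual prediction, so CPP/RU
#'   trajectories are conditioned on the individually observed
#'   prediction errors.
#' @param missing_advance If `FALSE` (default) missing trials freeze the
#'   observer state; if `TRUE` the recursions advance on the outcome
#'   alone using the current belief.
#' @return A list of class `observer_config`.
#' @export
observer_config <- function(hazard = 0.125,
                            scale_min = 0, scale_max = 100,
                            tau_init = 0.5,
                            belief_init = NULL,
                            conditioning = c("self", "empirical"),
                            missing_advance = FALSE) {
  check_prob(hazard, "hazard", open = TRUE)
  if (!is.numeric(scale_min) || !is.numeric(scale_max) || scale_min >= scale_max)
    config_error("scale_min/scale_max", "must satisfy scale_min < scale_max")
  if (!is.numeric(tau_init) || tau_init < 0 || tau_init >= 1)
    config_error("tau_init", "must lie in [0, 1)")
  conditioning <- match.arg(conditioning)
  structure(list(
    hazard = hazard,
    scale_min = scale_min, scale_max = scale_max,
    scale_width = scale_max - scale_min,
    tau_init = tau_init,
    belief_init = belief_init %||% ((scale_min + scale_max) / 2),
    conditioning = conditioning,
    missing_advance = missing_advance
  ), class = "observer_config")
}

#' Change-point probability for an observed prediction error
#'
#' Posterior probability that the current outcome was generated by a
#' relocated hidden mean rather than by noise around the current belief.
#' Under a change the outcome is uniform on the scale (density `1/W`);
#' without a change the prediction error is Gaussian with total
#' predictive variance `sigma_n^2 / (1 - tau)` (equal to
#' `sigma_n^2 + sigma_belief^2`, since
#' `tau = sigma_belief^2 / (sigma_belief^2 + sigma_n^2)`):
#' \deqn{\Omega = \frac{H/W}{H/W + (1-H)\,\phi(\delta;\,0,\,\sigma_n^2/(1-\tau))}}
#' CPP peaks when a surprisingly large prediction error is observed that
#' is unlikely under a stable environment.
#'
#' @param pe Signed prediction error(s), screen units.
#' @param tau Relative uncertainty in `[0, 1)`; recycled against `pe`.
#' @param hazard Per-trial change-point hazard, in (0, 1).
#' @param noise_sd Outcome noise SD (screen units), > 0.
#' @param scale_width Width of the outcome scale (screen units).
#' @return Probabilities in (0, 1), same length as `pe`.
#' @export
change_point_probability <- function(pe, tau, hazard, noise_sd,
                                     scale_width = 100) {
  if (any(noise_sd <= 0)) config_error("noise_sd", "must be > 0")
  check_prob(hazard, "hazard", open = TRUE)
  if (any(tau >= 1 | tau < 0))
    stop("invalid observer state: relative uncertainty must lie in [0, 1)")
  total_var <- noise_sd^2 / (1 - tau)
  change <- hazard / scale_width
  stay <- (1 - hazard) * stats::dnorm(pe, mean = 0, sd = sqrt(total_var))
  change / (change + stay)
}

#' Relative uncertainty after an outcome
#'
#' One step of the RU recursion. The posterior variance of the belief
#' mixes the change and no-change branches plus the between-branch
#' spread, and is renormalized against the outcome noise:
#' \deqn{\tau' = \frac{N}{N + \sigma_n^2},\quad
#'   N = \Omega\sigma_n^2 + (1-\Omega)\tau\sigma_n^2 +
#'       \Omega(1-\Omega)\,(\delta(1-\tau))^2}
#' RU peaks on the trial after a change point and decays slowly during
#' stable stretches (`tau' = tau/(tau+1)` when CPP is zero; `tau' = 1/2`
#' when a change is certain).
#'
#' @param pe Signed prediction error(s), screen units.
#' @param tau Current relative uncertainty in `[0, 1)`.
#' @param cpp Change-point probability in `[0, 1]`.
#' @param noise_sd Outcome noise SD, > 0.
#' @return Updated relative uncertainty in `[0, 1)`.
#' @export
relative_uncertainty_update <- function(pe, tau, cpp, noise_sd) {
  if (any(noise_sd <= 0)) config_error("noise_sd", "must be > 0")
  num <- cpp * noise_sd^2 + (1 - cpp) * tau * noise_sd^2 +
    cpp * (1 - cpp) * (pe * (1 - tau))^2
  num / (num + noise_sd^2)
}

#' Model learning rate from CPP and RU
#'
#' The reduced observer's trial-wise learning rate,
#' \eqn{\alpha = \Omega + (1-\Omega)\tau}: full updating when a change
#' point is certain, uncertainty-weighted updating otherwise.
#'
#' @param cpp Change-point probability in `[0, 1]`.
#' @param tau Relative uncertainty in `[0, 1]`.
#' @return Learning rate(s) in `[0, 1]`.
#' @export
model_learning_rate <- function(cpp, tau) {
  cpp + (1 - cpp) * tau
}

#' Run the reduced Bayesian observer over a session
#'
#' Applies the CPP, RU and learning-rate recursions trial by trial. In
#' `self` mode the observer propagates its own belief,
#' `B' = B + alpha * delta`. In `empirical` mode the belief is each
#' trial's supplied prediction, so the trajectories are conditioned on
#' the individually observed prediction errors (as used for fitting the
#' belief-update regression). RU is reset to `tau_init` at every run
#' boundary, and in self mode the belief restarts at `belief_init`.
#' Missing trials carry `NA` in the trace and (by default) freeze the
#' observer state.
#'
#' @param outcomes Numeric vector of observed outcomes (screen units).
#' @param noise_sd Outcome noise SD: a scalar, a per-run vector, or a
#'   per-trial vector.
#' @param runs Integer run index per trial (defaults to a single run).
#' @param cfg An [observer_config()].
#' @param predictions Participant predictions (required in empirical
#'   mode; `NA` on missing trials).
#' @param missing Logical per-trial missing flags (optional).
#' @return A data frame of class `observer_trace` with columns `trial`,
#'   `run`, `belief`, `pe`, `cpp`, `ru`, `lr_model`.
#' @export
run_observer <- function(outcomes, noise_sd, runs = NULL,
                         cfg = observer_config(),
                         predictions = NULL, missing = NULL) {
  stopifnot(inherits(cfg, "observer_config"))
  n <- length(outcomes)
  runs <- runs %||% rep(1L, n)
  if (length(runs) != n) stop("`runs` and `outcomes` length mismatch")
  if (any(!is.finite(outcomes)))
    stop("outcomes must be finite")
  if (any(outcomes < cfg$scale_min | outcomes > cfg$scale_max))
    stop("outcomes must lie on the scale")
  noise_trial <- expand_noise(noise_sd, runs)
  empirical <- cfg$conditioning == "empirical"
  if (empirical) {
    if (is.null(predictions)) stop("empirical mode requires `predictions`")
    if (length(predictions) != n)
      stop("`predictions` and `outcomes` length mismatch")
  }
  missing <- missing %||% (if (empirical) is.na(predictions) else rep(FALSE, n))

  belief <- pe <- cpp <- ru <- lr <- rep(NA_real_, n)
  B <- cfg$belief_init
  tau <- cfg$tau_init
  prev_run <- NA_integer_
  for (t in seq_len(n)) {
    if (!identical(runs[t], prev_run)) {  # run boundary: state reset
      tau <- cfg$tau_init
      if (!empirical) B <- cfg$belief_init
      prev_run <- runs[t]
    }
    if (missing[t]) {
      if (cfg$missing_advance) {
        d <- outcomes[t] - B
        om <- change_point_probability(d, tau, cfg$hazard, noise_trial[t],
                                       cfg$scale_width)
        a <- model_learning_rate(om, tau)
        tau <- relative_uncertainty_update(d, tau, om, noise_trial[t])
        if (!empirical) B <- clip(B + a * d, cfg$scale_min, cfg$scale_max)
      }
      next
    }
    if (empirical) B <- predictions[t]
    d <- outcomes[t] - B
    om <- change_point_probability(d, tau, cfg$hazard, noise_trial[t],
                                   cfg$scale_width)
    a <- model_learning_rate(om, tau)
    belief[t] <- B; pe[t] <- d; cpp[t] <- om; ru[t] <- tau; lr[t] <- a
    tau <- relative_uncertainty_update(d, tau, om, noise_trial[t])
    if (!empirical) B <- clip(B + a * d, cfg$scale_min, cfg$scale_max)
  }
  structure(
    data.frame(trial = seq_len(n), run = runs, belief = belief, pe = pe,
               cpp = cpp, ru = ru, lr_model = lr),
    class = c("observer_trace", "data.frame")
  )
}

expand_noise <- function(noise_sd, runs) {
  n <- length(runs)
  if (length(noise_sd) == n) return(noise_sd)
  if (length(noise_sd) == 1L) return(rep(noise_sd, n))
  run_ids <- sort(unique(runs))
  if (length(noise_sd) == length(run_ids))
    return(noise_sd[match(runs, run_ids)])
  stop("`noise_sd` must be scalar, per-run, or per-trial")
}

#' Grid-based fully Bayesian change-point filter (validation oracle)
#'
#' Exact Bayesian filtering of the hidden mean on a discretized scale:
#' with per-trial hazard `H` the mean redraws uniformly on the scale,
#' otherwise it persists; outcomes are Gaussian around the mean with
#' known noise SD. Returns the filtered posterior mean and the posterior
#' probability that a change occurred on each trial. Used to validate
#' the reduced observer; the first trial of each run restarts from a
#' uniform prior (its change posterior is reported as `NA`).
#'
#' @param outcomes Observed outcomes (screen units).
#' @param noise_sd Scalar, per-run, or per-trial noise SD.
#' @param runs Run index per trial (defaults to one run).
#' @param hazard Per-trial change-point probability.
#' @param grid_resolution Number of grid points (>= 201).
#' @param scale_min,scale_max Scale bounds.
#' @return Data frame with columns `trial`, `run`, `post_mean`,
#'   `change_prob`.
#' @export
full_bayes_oracle <- function(outcomes, noise_sd, runs = NULL,
                              hazard = 0.125, grid_resolution = 401,
                              scale_min = 0, scale_max = 100) {
  if (grid_resolution < 201)
    config_error("grid_resolution", "must be >= 201 grid points")
  check_prob(hazard, "hazard")
  n <- length(outcomes)
  runs <- runs %||% rep(1L, n)
  noise_trial <- expand_noise(noise_sd, runs)
  grid <- seq(scale_min, scale_max, length.out = grid_resolution)
  k <- grid_resolution
  uni <- rep(1 / k, k)
  post_mean <- change_prob <- rep(NA_real_, n)
  p <- uni
  prev_run <- NA_integer_
  for (t in seq_len(n)) {
    new_run <- !identical(runs[t], prev_run)
    if (new_run) {
      p <- uni
      prev_run <- runs[t]
    }
    lik <- stats::dnorm(outcomes[t], mean = grid, sd = noise_trial[t])
    if (new_run) {
      joint <- p * lik
    } else {
      stay <- (1 - hazard) * p * lik
      moved <- hazard * uni * lik
      joint <- stay + moved
      change_prob[t] <- sum(moved) / sum(joint)
    }
    p <- joint / sum(joint)
    post_mean[t] <- sum(p * grid)
  }
  data.frame(trial = seq_len(n), run = runs,
             post_mean = post_mean, change_prob = change_prob)
}
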