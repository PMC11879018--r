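# Task schedule generation and agent simulation for the change-point
# ("helicopter") predictive inference task.

#' Task configuration
#'
#' Parameters of the predictive inference task: a hidden mean on a
#' bounded screen scale that relocates abruptly at change points, noisy
#' outcomes ("bag drops") around it, and binary reward labels. The
#' default session is 280 trials in 4 runs of 70, with outcome noise SD
#' alternating 2.3 / 4.6 / 2.3 / 4.6 screen units across runs. Each run
#' restarts the mean (a forced change point on its first trial).
#'
#' @param n_runs Number of runs (scanner blocks).
#' @param trials_per_run Trials per run (>= 2).
#' @param scale_min,scale_max Screen scale bounds.
#' @param noise_sd_by_run Outcome noise SD per run, screen units.
#' @param hazard Per-trial change-point probability in (0, 1).
#' @param reward_prob Probability a bag is a money (rewarded) bag.
#' @param catch_halfwidth A bag is caught when the prediction is within
#'   this many screen units of the drop location.
#' @param mean_margin New means are drawn uniformly at least this far
#'   from the scale edges, avoiding edge-saturated blocks.
#' @param seed Integer seed; identical config + seed gives a
#'   bit-identical schedule.
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_runs = 4, trials_per_run = 70,
                        scale_min = 0, scale_max = 100,
                        noise_sd_by_run = c(2.3, 4.6, 2.3, 4.6),
                        hazard = 0.125, reward_prob = 0.5,
                        catch_halfwidth = 5, mean_margin = 10,
                        seed = 1L) {
  if (!is.numeric(n_runs) || n_runs < 1) config_error("n_runs", "must be >= 1")
  if (!is.numeric(trials_per_run) || trials_per_run < 2)
    config_error("trials_per_run", "must be >= 2")
  if (scale_min >= scale_max)
    config_error("scale_min/scale_max", "must satisfy scale_min < scale_max")
  if (length(noise_sd_by_run) != n_runs)
    config_error("noise_sd_by_run", "must have one SD per run")
  if (any(noise_sd_by_run <= 0))
    config_error("noise_sd_by_run", "noise SDs must be > 0")
  if (!is.numeric(hazard) || hazard < 0 || hazard >= 1)
    config_error("hazard", "must lie in [0, 1)")  # 0 = no free change points
  check_prob(reward_prob, "reward_prob")
  if (catch_halfwidth < 0) config_error("catch_halfwidth", "must be >= 0")
  if (mean_margin < 0 || 2 * mean_margin >= scale_max - scale_min)
    config_error("mean_margin", "must leave a non-empty mean range")
  structure(list(
    n_runs = as.integer(n_runs), trials_per_run = as.integer(trials_per_run),
    scale_min = scale_min, scale_max = scale_max,
    noise_sd_by_run = noise_sd_by_run, hazard = hazard,
    reward_prob = reward_prob, catch_halfwidth = catch_halfwidth,
    mean_margin = mean_margin, seed = as.integer(seed)
  ), class = "task_config")
}

#' Generate a task schedule
#'
#' Draws the generative truth for one session: the first trial of every
#' run is a forced change point; afterwards change points occur
#' independently with probability `hazard`. On a change point the mean
#' redraws uniformly (with an edge margin); outcomes are Gaussian around
#' the mean and redrawn until they fall on the scale (rejection, not
#' clipping, so no point mass accumulates at the edges). Reward labels
#' are Bernoulli and independent of the trajectory.
#'
#' @param config A [task_config()].
#' @return A data frame of class `task_schedule` with per-trial columns
#'   `trial`, `run`, `trial_in_run`, `is_change_point`, `mean`,
#'   `outcome`, `noise_sd`, `reward`, carrying the config as an
#'   attribute.
#' @export
generate_schedule <- function(config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_runs * config$trials_per_run
  lo <- config$scale_min + config$mean_margin
  hi <- config$scale_max - config$mean_margin
  withr::with_seed(config$seed, {
    run <- rep(seq_len(config$n_runs), each = config$trials_per_run)
    trial_in_run <- rep(seq_len(config$trials_per_run), config$n_runs)
    is_cp <- trial_in_run == 1L
    is_cp[trial_in_run > 1L] <- stats::runif(sum(trial_in_run > 1L)) < config$hazard
    mu <- numeric(n)
    cur <- NA_real_
    for (t in seq_len(n)) {
      if (is_cp[t]) cur <- stats::runif(1, lo, hi)
      mu[t] <- cur
    }
    noise <- config$noise_sd_by_run[run]
    outcome <- rnorm_truncated(mu, noise, config$scale_min, config$scale_max)
    reward <- as.integer(stats::runif(n) < config$reward_prob)
  })
  structure(
    data.frame(trial = seq_len(n), run = run, trial_in_run = trial_in_run,
               is_change_point = is_cp, mean = mu, outcome = outcome,
               noise_sd = noise, reward = reward),
    class = c("task_schedule", "data.frame"),
    config = config
  )
}

# Gaussian draws redrawn until inside [lo, hi].
rnorm_truncated <- function(mean, sd, lo, hi) {
  x <- stats::rnorm(length(mean), mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Agent parameters
#'
#' Generative parameters of a simulated participant. The intended update
#' on each trial mirrors the belief-update regression:
#' `intercept_bias + w_pe*d + w_cpp*d*CPP + w_ru*d*RU*(1-CPP) +
#' w_reward*d*r + edge_weight*((B-mid)/half)^3*half`, plus Gaussian
#' motor noise; with probability `perseveration_prob` the update is
#' suppressed to zero, with probability `lapse_prob` the next prediction
#' is uniform on the scale, and with probability `miss_prob` the trial
#' is missing (no recorded response). `d` is the signed prediction
#' error, `CPP`/`RU` the agent's own online observer estimates.
#'
#' @param w_pe,w_cpp,w_ru,w_reward Unitless update weights.
#' @param intercept_bias Constant left/rightward drift, screen units.
#' @param edge_weight Unitless weight of the cubic edge-avoidance term.
#' @param motor_noise_sd Motor noise SD, screen units (>= 0).
#' @param lapse_prob,perseveration_prob,miss_prob Probabilities in
#'   `[0, 1]`.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(w_pe = 1, w_cpp = 0, w_ru = 0, w_reward = 0,
                         intercept_bias = 0, edge_weight = 0,
                         motor_noise_sd = 0, lapse_prob = 0,
                         perseveration_prob = 0, miss_prob = 0) {
  if (motor_noise_sd < 0) config_error("motor_noise_sd", "must be >= 0")
  check_prob(lapse_prob, "lapse_prob")
  check_prob(perseveration_prob, "perseveration_prob")
  check_prob(miss_prob, "miss_prob")
  structure(list(
    w_pe = w_pe, w_cpp = w_cpp, w_ru = w_ru, w_reward = w_reward,
    intercept_bias = intercept_bias, edge_weight = edge_weight,
    motor_noise_sd = motor_noise_sd, lapse_prob = lapse_prob,
    perseveration_prob = perseveration_prob, miss_prob = miss_prob
  ), class = "agent_params")
}

#' Agent parameter presets
#'
#' `"delta"` is a pure delta-rule learner (LR = 1); `"normative"`
#' applies the reduced observer's learning rate exactly
#' (`w_cpp = w_ru = 1`, `w_pe = 0`); `"hc"` and `"psd"` are the
#' cohort presets: update weights on the scale of the belief-update
#' regression coefficients observed in this task family, with the
#' psychosis-spectrum preset down-weighting CPP, leaning more on RU,
#' and updating more noisily and perseveratively.
#'
#' @param name One of `"delta"`, `"normative"`, `"hc"`, `"psd"`.
#' @param ... Overrides passed to [agent_params()].
#' @return An `agent_params` object.
#' @export
agent_preset <- function(name = c("delta", "normative", "hc", "psd"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    delta = list(w_pe = 1),
    normative = list(w_pe = 0, w_cpp = 1, w_ru = 1),
    hc = list(w_pe = 0.78, w_cpp = 0.18, w_ru = 0.15, w_reward = 0.03,
              motor_noise_sd = 3, lapse_prob = 0.01,
              perseveration_prob = 0.05, miss_prob = 0.04),
    psd = list(w_pe = 0.70, w_cpp = 0.05, w_ru = 0.20, w_reward = 0.03,
               motor_noise_sd = 4, lapse_prob = 0.03,
               perseveration_prob = 0.12, miss_prob = 0.04)
  )
  do.call(agent_params, utils::modifyList(base, list(...)))
}

#' Simulate a behaving agent on a schedule
#'
#' Runs one agent through a schedule. The agent holds a belief (its
#' prediction), observes the outcome, computes its own online CPP and RU
#' via the reduced observer recursions, and updates its belief by the
#' weighted mixture defined in [agent_params()]. Beliefs are clipped to
#' the scale; the belief restarts at the midpoint and RU at `tau_init`
#' on every run. Missing trials carry no prediction and freeze the
#' agent's observer state. Response times and inter-trial intervals are
#' drawn so that events can be laid out on a scanner timeline
#' (decision <= 3 s; ITI jittered around 2 s).
#'
#' @param schedule A [generate_schedule()] result.
#' @param params An [agent_params()] object.
#' @param hazard_belief Hazard rate assumed by the agent's observer.
#' @param seed Integer seed.
#' @param tau_init Initial relative uncertainty per run.
#' @return A data frame of class `behavior_record` with columns `trial`,
#'   `run`, `prediction`, `outcome`, `pe`, `update`, `reward`, `caught`,
#'   `missing`, `rt`, `iti`; update is the difference between
#'   consecutive recorded predictions within a run (`NA` across missing
#'   trials and at run boundaries).
#' @export
simulate_agent <- function(schedule, params, hazard_belief = 0.125,
                           seed = 1L, tau_init = 0.5) {
  stopifnot(inherits(schedule, "task_schedule"), inherits(params, "agent_params"))
  cfg <- attr(schedule, "config")
  lo <- cfg$scale_min; hi <- cfg$scale_max
  mid <- (lo + hi) / 2; half <- (hi - lo) / 2
  n <- nrow(schedule)
  prediction <- pe <- rt <- rep(NA_real_, n)
  caught <- missing <- logical(n)
  iti <- numeric(n)
  withr::with_seed(seed, {
    B <- mid; tau <- tau_init
    prev_run <- NA_integer_
    for (t in seq_len(n)) {
      if (!identical(schedule$run[t], prev_run)) {
        B <- mid; tau <- tau_init
        prev_run <- schedule$run[t]
      }
      iti[t] <- stats::runif(1, 1.5, 2.5)
      if (stats::runif(1) < params$miss_prob) {
        missing[t] <- TRUE
        next  # no response: state frozen
      }
      rt[t] <- min(stats::rlnorm(1, meanlog = log(1.1), sdlog = 0.35), 2.95)
      prediction[t] <- B
      X <- schedule$outcome[t]
      d <- X - B
      pe[t] <- d
      caught[t] <- abs(d) <= cfg$catch_halfwidth
      om <- change_point_probability(d, tau, hazard_belief,
                                     schedule$noise_sd[t], hi - lo)
      intended <- params$intercept_bias +
        params$w_pe * d +
        params$w_cpp * d * om +
        params$w_ru * d * tau * (1 - om) +
        params$w_reward * d * schedule$reward[t] +
        params$edge_weight * ((B - mid) / half)^3 * half +
        stats::rnorm(1, 0, params$motor_noise_sd)
      if (stats::runif(1) < params$perseveration_prob) intended <- 0
      B_next <- clip(B + intended, lo, hi)
      if (stats::runif(1) < params$lapse_prob) B_next <- stats::runif(1, lo, hi)
      tau <- relative_uncertainty_update(d, tau, om, schedule$noise_sd[t])
      B <- B_next
    }
  })
  update <- c(prediction[-1L] - prediction[-n], NA_real_)
  update[which(schedule$run != c(schedule$run[-1L], NA))] <- NA_real_
  structure(
    data.frame(trial = schedule$trial, run = schedule$run,
               prediction = prediction, outcome = schedule$outcome,
               pe = pe, update = update, reward = schedule$reward,
               caught = caught, missing = missing, rt = rt, iti = iti),
    class = c("behavior_record", "data.frame"),
    params = params, hazard_belief = hazard_belief, seed = seed
  )
}

#' Covariate model for synthetic cohorts
#'
#' Distributions of the cohort covariates (age, delusional-ideation
#' score PDI, PANSS symptom scales, BACS cognitive domains) per group,
#' plus optional couplings from a subject's true update weights to a
#' symptom score (`couplings` entries like
#' `list(score = "pdi", weight = "w_ru", slope = 20)` add
#' `slope * (weight - group mean weight)` to the score). `weight_jitter_sd`
#' controls between-subject spread of the update weights around the
#' group preset.
#'
#' @param age_mean,age_sd Named lists (`hc`, `psd`).
#' @param pdi_mean,pdi_sd,panss,bacs Group-wise distribution settings.
#' @param couplings List of score-weight couplings.
#' @param weight_jitter_sd SD of per-subject jitter on each update weight.
#' @return A list of class `covariate_model`.
#' @export
covariate_model <- function(
    age_mean = list(hc = 29.3, psd = 35.8),
    age_sd = list(hc = 11.4, psd = 9.7),
    pdi_mean = list(hc = 2.9, psd = 14.7),
    pdi_sd = list(hc = 3.5, psd = 10.0),
    panss = list(pos = c(16.3, 7.0), neg = c(11.3, 3.2), gen = c(28.6, 6.4)),
    bacs = list(
      verbal_memory = list(hc = c(54.5, 7.6), psd = c(45.2, 11.8)),
      working_memory = list(hc = c(21.3, 3.6), psd = c(19.6, 4.3)),
      motor_speed = list(hc = c(78.7, 13.5), psd = c(76.6, 14.7)),
      verbal_fluency = list(hc = c(28.2, 6.9), psd = c(27.8, 8.0)),
      attention = list(hc = c(36.5, 17.5), psd = c(24.4, 7.3)),
      processing_speed = list(hc = c(65.1, 13.7), psd = c(52.9, 10.3)),
      executive = list(hc = c(18.1, 2.0), psd = c(17.6, 2.5))
    ),
    couplings = list(),
    weight_jitter_sd = 0.05) {
  structure(list(age_mean = age_mean, age_sd = age_sd,
                 pdi_mean = pdi_mean, pdi_sd = pdi_sd, panss = panss,
                 bacs = bacs, couplings = couplings,
                 weight_jitter_sd = weight_jitter_sd),
            class = "covariate_model")
}

#' Simulate a synthetic cohort on a shared schedule
#'
#' Simulates `n_hc + n_psd` agents on one shared task schedule (the real
#' task trajectory was identical for all participants). Each subject's
#' update weights are jittered around the group preset; covariates are
#' drawn from the [covariate_model()] with optional couplings to the
#' true weights. Full provenance (true per-subject parameters) is
#' retained for parameter-recovery checks.
#'
#' @param n_hc,n_psd Group sizes (>= 1).
#' @param schedule Shared [generate_schedule()] result (default
#'   schedule generated from `task_config(seed = seed)` if `NULL`).
#' @param hc_params,psd_params Group-level [agent_params()].
#' @param cov_model A [covariate_model()].
#' @param hazard_belief Hazard assumed by all agents' observers.
#' @param seed Master seed; each subject gets an independent sub-seed.
#' @return A list of class `cohort` with elements `covariates` (data
#'   frame: subject, group, age, pdi, panss_*, bacs_*, true weights),
#'   `records` (list of `behavior_record`), and `schedule`.
#' @export
simulate_cohort <- function(n_hc = 40, n_psd = 19, schedule = NULL,
                            hc_params = agent_preset("hc"),
                            psd_params = agent_preset("psd"),
                            cov_model = covariate_model(),
                            hazard_belief = 0.125, seed = 1L) {
  if (n_hc < 1 || n_psd < 1) config_error("n_hc/n_psd", "group sizes must be >= 1")
  schedule <- schedule %||% generate_schedule(task_config(seed = sub_seed(seed, "schedule")))
  groups <- c(rep("hc", n_hc), rep("psd", n_psd))
  n_sub <- length(groups)
  weight_names <- c("w_pe", "w_cpp", "w_ru", "w_reward")
  records <- vector("list", n_sub)
  cov_rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    base <- if (g == "hc") hc_params else psd_params
    s_par <- sub_seed(seed, "params", i)
    pars <- withr::with_seed(s_par, {
      p <- base
      for (w in weight_names)
        p[[w]] <- p[[w]] + stats::rnorm(1, 0, cov_model$weight_jitter_sd)
      p
    })
    records[[i]] <- simulate_agent(schedule, pars, hazard_belief,
                                   seed = sub_seed(seed, "agent", i))
    cov_rows[[i]] <- withr::with_seed(sub_seed(seed, "covariates", i), {
      age <- clip(stats::rnorm(1, cov_model$age_mean[[g]], cov_model$age_sd[[g]]), 18, 65)
      pdi <- max(0, stats::rnorm(1, cov_model$pdi_mean[[g]], cov_model$pdi_sd[[g]]))
      for (cp in cov_model$couplings) {
        if (identical(cp$score, "pdi"))
          pdi <- max(0, pdi + cp$slope * (pars[[cp$weight]] - base[[cp$weight]]))
      }
      panss <- if (g == "psd") {
        vapply(cov_model$panss, function(ms) max(0, stats::rnorm(1, ms[1], ms[2])),
               numeric(1))
      } else c(pos = NA_real_, neg = NA_real_, gen = NA_real_)
      bacs <- vapply(cov_model$bacs, function(dom)
        stats::rnorm(1, dom[[g]][1], dom[[g]][2]), numeric(1))
      row <- data.frame(subject = i, group = g, age = age, pdi = pdi,
                        panss_pos = panss[["pos"]], panss_neg = panss[["neg"]],
                        panss_gen = panss[["gen"]])
      for (nm in names(bacs)) row[[paste0("bacs_", nm)]] <- bacs[[nm]]
      for (w in weight_names) row[[paste0("true_", w)]] <- pars[[w]]
      row
    })
  }
  structure(list(covariates = do.call(rbind, cov_rows),
                 records = records, schedule = schedule),
            class = "cohort")
}
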