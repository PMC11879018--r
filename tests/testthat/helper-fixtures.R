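# Shared fixture builders: everything is generated in code.

# A small default-geometry schedule (fewer trials for fast tests).
small_schedule <- function(seed = 1L, trials_per_run = 30, hazard = 0.125) {
  generate_schedule(task_config(trials_per_run = trials_per_run,
                                hazard = hazard, seed = seed))
}

# Hand-built behaviour record from explicit predictions/outcomes,
# single run, for exact-value checks of the behavioural statistics.
manual_record <- function(prediction, outcome,
                          reward = rep(0L, length(outcome)),
                          missing = rep(FALSE, length(outcome))) {
  n <- length(outcome)
  pe <- outcome - prediction
  update <- c(prediction[-1L] - prediction[-n], NA_real_)
  structure(
    data.frame(trial = seq_len(n), run = rep(1L, n),
               prediction = prediction, outcome = outcome, pe = pe,
               update = update, reward = reward, caught = abs(pe) <= 5,
               missing = missing,
               rt = rep(1, n), iti = rep(2, n)),
    class = c("behavior_record", "data.frame")
  )
}

# Minimal schedule wrapper around explicit truth, single run.
manual_schedule <- function(mean, outcome, noise_sd = 2.3,
                            is_change_point = NULL) {
  n <- length(outcome)
  cp <- is_change_point %||% c(TRUE, rep(FALSE, n - 1))
  structure(
    data.frame(trial = seq_len(n), run = rep(1L, n),
               trial_in_run = seq_len(n), is_change_point = cp,
               mean = mean, outcome = outcome,
               noise_sd = rep(noise_sd, length.out = n),
               reward = rep(0L, n)),
    class = c("task_schedule", "data.frame"),
    config = task_config(n_runs = 1, trials_per_run = n,
                         noise_sd_by_run = noise_sd[1])
  )
}

empirical_trace <- function(record, schedule, hazard = 0.125) {
  run_observer(record$outcome, schedule$noise_sd, runs = record$run,
               cfg = observer_config(hazard = hazard,
                                     conditioning = "empirical"),
               predictions = record$prediction, missing = record$missing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
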