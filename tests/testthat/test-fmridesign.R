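# Small session used across design tests: one subject on a short
# schedule, empirical trace, residual modulator.
design_fixture <- function(seed = 5, trials_per_run = 25, n_runs = 2,
                           miss_prob = 0.04) {
  sch <- generate_schedule(task_config(n_runs = n_runs,
                                       trials_per_run = trials_per_run,
                                       noise_sd_by_run = rep(c(2.3, 4.6),
                                                             length.out = n_runs),
                                       seed = seed))
  a <- simulate_agent(sch, agent_preset("hc", miss_prob = miss_prob),
                      seed = seed)
  tr <- empirical_trace(a, sch)
  fit <- fit_update_regression(a, tr)
  res <- fit$residuals
  res[is.na(res)] <- 0
  list(schedule = sch, record = a,
       events = build_events(a),
       modulators = data.frame(outcome = a$outcome, cpp = tr$cpp,
                               ru = tr$ru, reward = a$reward,
                               residual = res))
}

test_that("canonical HRF has the expected shape and resampling consistency", {
  h <- canonical_hrf(0.8)
  expect_true(all(is.finite(h)))
  expect_gt(sum(h), 0)
  # peak-normalized against the continuous maximum, which the sampled
  # grid approaches but need not hit exactly
  expect_true(max(h) > 0.98 && max(h) <= 1)
  peak_t <- attr(h, "times")[which.max(h)]
  expect_true(peak_t >= 4 && peak_t <= 7)
  fine <- canonical_hrf(0.1)
  expect_lt(max(abs(h - fine[seq(1, length(fine), by = 8)])), 1e-6)
})

test_that("design matrix has the full column set and is reproducible", {
  fx <- design_fixture()
  cfg <- scan_config()
  n_scans <- sum(sapply(split(fx$events, fx$events$run), function(e)
    ceiling(max(e$trial_start + e$trial_duration) / cfg$tr) + 8))
  motion <- simulate_motion(n_scans, seed = 3)
  d <- build_design_matrix(fx$events, fx$modulators, cfg, motion = motion)
  n_runs <- length(unique(fx$events$run))
  expect_equal(ncol(d$X), 1 + 5 + 1 + 6 + n_runs)
  expect_true(all(c("onset", "mod_cpp", "mod_ru", "error", "motion1",
                    paste0("run", seq_len(n_runs))) %in% colnames(d$X)))
  d2 <- build_design_matrix(fx$events, fx$modulators, cfg, motion = motion)
  expect_identical(d$X, d2$X)
})

test_that("constant modulator series are dropped with a warning", {
  fx <- design_fixture(miss_prob = 0)
  fx$modulators$reward <- 1
  expect_warning(d <- build_design_matrix(fx$events, fx$modulators,
                                          scan_config()),
                 "reward")
  expect_false("mod_reward" %in% colnames(d$X))
  expect_true("reward" %in% d$dropped)
})

test_that("one noiseless event produces a shifted scaled HRF", {
  ev <- data.frame(onset = 4, duration = 1, trial = 1, run = 1,
                   missing = FALSE, trial_start = 0, trial_duration = 20)
  cfg <- scan_config(tr = 0.8, n_scans_per_run = 50)
  d <- suppressWarnings(build_design_matrix(
    ev, data.frame(outcome = 1), cfg))
  y <- simulate_bold(d, c(onset = 2), scan_config(noise_sd = 0), seed = 1)
  onset_col <- d$X[, "onset"]
  expect_equal(y, 2 * onset_col + 0 * y)
  expect_equal(which(onset_col > 0.01 * max(onset_col))[1] * cfg$tr > 4,
               TRUE)  # response begins after the event onset
})

test_that("simulated BOLD noise has the configured AR(1) structure", {
  fx <- design_fixture()
  d <- build_design_matrix(fx$events, fx$modulators, scan_config())
  cfg <- scan_config(noise_sd = 1, ar1_rho = 0.4)
  y0 <- simulate_bold(d, c(onset = 1), scan_config(noise_sd = 0), seed = 2)
  y <- simulate_bold(d, c(onset = 1), cfg, seed = 2)
  noise <- y - y0
  r1 <- cor(noise[-1], noise[-length(noise)])
  expect_lt(abs(r1 - 0.4), 0.1)
  expect_lt(abs(sd(noise) - 1), 0.15)
  # linearity: doubling betas doubles the signal
  y2 <- simulate_bold(d, c(onset = 2), scan_config(noise_sd = 0), seed = 2)
  expect_equal(y2, 2 * y0)
})

test_that("the GLM recovers generating betas exactly without noise", {
  fx <- design_fixture()
  d <- build_design_matrix(fx$events, fx$modulators, scan_config())
  b <- c(onset = 1, mod_outcome = 0.2, mod_cpp = 0.5, mod_ru = 0.3,
         mod_reward = 0.1, mod_residual = 0.1)
  y <- simulate_bold(d, b, scan_config(noise_sd = 0), seed = 1)
  fit <- fit_glm(y, d)
  expect_equal(fit$betas[names(b), 1], b, tolerance = 1e-10)
  # permutation equivariance: permuting scans of y and X together
  perm <- withr::with_seed(9, sample(nrow(d$X)))
  dp <- d; dp$X <- d$X[perm, ]
  expect_equal(fit_glm(y[perm], dp)$betas[, 1], fit$betas[, 1],
               tolerance = 1e-10)
})

test_that("whitened and unwhitened fits agree for white noise", {
  fx <- design_fixture()
  d <- build_design_matrix(fx$events, fx$modulators, scan_config())
  y <- simulate_bold(d, c(onset = 1, mod_cpp = 0.5),
                     scan_config(noise_sd = 1, ar1_rho = 0), seed = 4)
  f0 <- fit_glm(y, d, whitening = "none")
  f1 <- fit_glm(y, d, whitening = "ar1", rho = 0)
  expect_equal(f0$betas, f1$betas, tolerance = 1e-12)
})

test_that("contrasts are linear combinations of betas", {
  fx <- design_fixture()
  d <- build_design_matrix(fx$events, fx$modulators, scan_config())
  y <- simulate_bold(d, c(mod_cpp = 0.5, mod_ru = 0.2),
                     scan_config(noise_sd = 0), seed = 1)
  fit <- fit_glm(y, d, contrasts = list(cpp_vs_ru = c(mod_cpp = 1,
                                                      mod_ru = -1)))
  expect_equal(fit$contrasts$cpp_vs_ru$estimate, 0.3, tolerance = 1e-10)
})

test_that("VOI rank correlations handle monotone, reversed and tied data", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(voi_correlate(x, data.frame(s = x^3))$rho, 1)
  expect_equal(voi_correlate(x, data.frame(s = -x))$rho, -1)
  tied <- voi_correlate(x, data.frame(s = c(1, 1, 2, 2, 3, 3)))
  expect_gt(tied$rho, 0.9)
  expect_error(voi_correlate(rep(1, 6), data.frame(s = x)), "constant")
})

test_that("VOI group model detects an injected shift and not a null", {
  set.seed(10)
  g <- rep(c("hc", "psd"), c(20, 10))
  age <- rnorm(30, 30, 8)
  null_voi <- rnorm(30)
  tab0 <- group_beta_compare(null_voi, g, age)
  shifted <- null_voi - 2 * (g == "psd")
  tab1 <- group_beta_compare(shifted, g, age)
  expect_lt(tab1$p, 0.01)
  expect_lt(tab1$estimate, 0)
  identical_groups <- rep(c(1, 2, 3), 10)
  tab2 <- group_beta_compare(identical_groups, rep(c("hc", "psd"), 15),
                             rep(30, 30) + rnorm(30, 0, 0.1))
  expect_lt(abs(tab2$t), 1.0)
})
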