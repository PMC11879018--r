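test_that("learning-rate clipping follows the update/PE ratio rules", {
  # prediction 40, outcome 60 (pe 20), then three update styles
  rec <- manual_record(prediction = c(40, 50, 45, 75, 60),
                       outcome = c(60, 70, 75, 60, 60))
  lr <- empirical_learning_rates(rec)
  # U=10 after pe=20 -> 0.5; U=-5 after pe=20 -> clip 0; U=30 after pe=30 -> 1
  expect_equal(lr$trials$raw_lr[1], 0.5)
  expect_equal(lr$trials$clipped_lr[1], 0.5)
  expect_equal(lr$trials$raw_lr[2], -0.25)
  expect_equal(lr$trials$clipped_lr[2], 0)
  expect_equal(lr$trials$raw_lr[3], 1)
  rec2 <- manual_record(prediction = c(40, 70), outcome = c(60, 60))
  expect_equal(empirical_learning_rates(rec2)$trials$raw_lr[1], 1.5)
  expect_equal(empirical_learning_rates(rec2)$trials$clipped_lr[1], 1)
})

test_that("small prediction errors are excluded from the LR aggregate", {
  rec <- manual_record(prediction = c(50, 55, 60), outcome = c(50.5, 70, 60))
  lr <- empirical_learning_rates(rec, pe_floor = 1)
  expect_false(lr$trials$used[1])  # |pe| = 0.5 below floor
  expect_true(lr$trials$used[2])
})

test_that("the aberrance filter drops large negative raw LRs on request", {
  rec <- manual_record(prediction = c(40, 30, 35), outcome = c(60, 40, 40))
  # raw LR trial 1 = -10/20 = -0.5 (aberrant)
  plain <- empirical_learning_rates(rec)
  filt <- empirical_learning_rates(rec, exclude_aberrant = TRUE)
  expect_equal(plain$n_aberrant, 1)
  expect_equal(filt$n_used, plain$n_used - 1)
})

test_that("update categories use the 0.1/0.9 bounds and are order-invariant", {
  expect_equal(unname(categorize_updates(0.05)), c(1, 0, 0))
  expect_equal(unname(categorize_updates(0.95)), c(0, 0, 1))
  expect_equal(unname(categorize_updates(c(0, 0.5, 1))), rep(1 / 3, 3))
  x <- withr::with_seed(1, runif(200))
  expect_identical(categorize_updates(x),
                   categorize_updates(sample(x)))
  expect_equal(sum(categorize_updates(x)), 1)
  # body-text variant bound is config-switchable
  expect_equal(unname(categorize_updates(0.05, thresholds = c(0.01, 0.9))[1]),
               0)
})

test_that("performance error measures deviance from the hidden mean", {
  mu <- rep(c(30, 70), each = 10)
  sch <- manual_schedule(mu, mu, is_change_point = c(TRUE, rep(FALSE, 9),
                                                     TRUE, rep(FALSE, 9)))
  rec <- manual_record(prediction = mu, outcome = mu)
  expect_equal(performance_error(rec, sch), 0)
  rec3 <- manual_record(prediction = mu + 3, outcome = mu)
  expect_equal(performance_error(rec3, sch), 3)
  expect_equal(performance_error(rec3, sch, mode = "sum"), 60)
  expect_error(performance_error(rec3[1:5, ], sch), "misaligned")
})

test_that("post-change-point learning isolates the change-trial updates", {
  sch <- small_schedule(seed = 12)
  delta <- simulate_agent(sch, agent_params(w_pe = 1), seed = 1)
  expect_equal(post_changepoint_learning(delta, sch), 1)
  frozen <- simulate_agent(sch, agent_params(w_pe = 0), seed = 1)
  expect_equal(post_changepoint_learning(frozen, sch), 0)
  # the normative agent updates faster at change points than on average
  norm <- simulate_agent(sch, agent_preset("normative"), seed = 1)
  lr <- empirical_learning_rates(norm)
  expect_gt(post_changepoint_learning(norm, sch), lr$mean_lr)
})

test_that("noiseless delta-rule updates are explained exactly by PE", {
  sch <- small_schedule(seed = 3)
  a <- simulate_agent(sch, agent_params(w_pe = 1), seed = 2)
  tr <- empirical_trace(a, sch)
  fit <- suppressWarnings(fit_update_regression(a, tr))  # perfect fit
  expect_equal(unname(fit$coefficients["pe"]), 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  for (term in c("cpp", "ru", "reward", "edge"))
    expect_lt(abs(fit$coefficients[[term]]), 1e-8)
  expect_lt(abs(mean(fit$residuals, na.rm = TRUE)), 1e-10)
})

test_that("regression residuals are orthogonal to every design column", {
  sch <- small_schedule(seed = 9)
  a <- simulate_agent(sch, agent_preset("hc"), seed = 4)
  tr <- empirical_trace(a, sch)
  fit <- fit_update_regression(a, tr)
  ok <- !is.na(fit$residuals)
  cols <- cbind(pe = a$pe, cpp = a$pe * tr$cpp,
                ru = a$pe * tr$ru * (1 - tr$cpp),
                reward = a$pe * a$reward,
                edge = ((a$prediction - 50) / 50)^3)[ok, ]
  for (j in seq_len(ncol(cols)))
    expect_lt(abs(cor(fit$residuals[ok], cols[, j])), 1e-8)
})

test_that("constant regressors are dropped with a warning", {
  sch <- small_schedule(seed = 3)
  a <- simulate_agent(sch, agent_params(w_pe = 0.8, motor_noise_sd = 1),
                      seed = 2)
  a$reward <- 0L  # constant reward column
  tr <- empirical_trace(a, sch)
  expect_warning(fit <- fit_update_regression(a, tr), "reward")
  expect_true(is.na(fit$coefficients[["reward"]]))
  expect_false(is.na(fit$coefficients[["pe"]]))
})

test_that("generative update weights are recovered without bias", {
  sch <- generate_schedule(task_config(seed = 1))
  p <- agent_params(w_pe = 0.5, w_cpp = 0.3, w_ru = 0.2, w_reward = 0.1,
                    motor_noise_sd = 2)
  est <- t(sapply(1:30, function(s) {
    a <- simulate_agent(sch, p, seed = 400 + s)
    fit_update_regression(a, empirical_trace(a, sch))$coefficients[
      c("pe", "cpp", "ru", "reward")]
  }))
  bias <- apply(est, 2, median) - c(0.5, 0.3, 0.2, 0.1)
  expect_true(all(abs(bias) < 0.05))
})

test_that("exclusion screen flags excessive missingness and degenerate play", {
  sch <- generate_schedule(task_config(seed = 2))
  a <- simulate_agent(sch, agent_preset("normative"), seed = 1)
  # 71 of 280 missing crosses the 25% rule
  a_miss <- a
  a_miss$missing[1:71] <- TRUE
  a_miss$prediction[1:71] <- NA
  expect_true(exclusion_screen(a_miss)[["missing_excess"]])
  expect_false(exclusion_screen(a)[["missing_excess"]])
  a_flat <- a
  a_flat$prediction[] <- 50
  expect_true(exclusion_screen(a_flat)[["repetitive"]])
  expect_false(any(exclusion_screen(a)))
})

test_that("group comparison reports both tests and handles outliers", {
  x <- c(1:10, 1:10)  # identical value sets in both groups
  g <- rep(c("a", "b"), each = 10)
  gc0 <- group_compare(x, g)
  expect_lt(abs(gc0$t_test$statistic), 1e-10)
  expect_gt(gc0$t_test$p.value, 0.99)
  # clear shift with trivial within-group noise
  y <- c(rnorm(10, 0, 1e-3), rnorm(10, 10, 1e-3))
  expect_lt(group_compare(y, g)$t_test$p.value, 1e-10)
  # MAD rule removes a planted outlier
  z <- c(rnorm(19, 0, 1), 50)
  gz <- group_compare(c(z, rnorm(20, 1, 1)), rep(c("a", "b"), each = 20),
                      outlier_rule = "mad")
  expect_true(20 %in% gz$excluded)
})

test_that("group comparison rejection rate matches Welch power", {
  # metric ~ N(shift of 1 SD), n = 40 vs 19: analytic power from the
  # noncentral t distribution
  n1 <- 40; n2 <- 19; d <- 1
  se <- sqrt(1 / n1 + 1 / n2)
  df <- (1 / n1 + 1 / n2)^2 / ((1 / n1)^2 / (n1 - 1) + (1 / n2)^2 / (n2 - 1))
  tc <- qt(0.975, df)
  power <- 1 - pt(tc, df, ncp = d / se) + pt(-tc, df, ncp = d / se)
  rej <- withr::with_seed(77, mean(sapply(1:400, function(s) {
    m <- c(rnorm(n1, 0, 1), rnorm(n2, d, 1))
    group_compare(m, rep(c("a", "b"), c(n1, n2)))$t_test$p.value < 0.05
  })))
  expect_lt(abs(rej - power), 3 * sqrt(power * (1 - power) / 400))
})

test_that("perfectly balanced label-flipped subjects give null logistic", {
  co <- withr::with_seed(5, data.frame(
    pe = rnorm(30), cpp = rnorm(30), ru = rnorm(30), reward = rnorm(30)))
  co2 <- rbind(co, co)
  g <- c(rep("a", 30), rep("b", 30))
  fit <- fit_group_logistic(co2, g)
  expect_true(all(abs(fit$table$estimate) < 1e-6))
})

test_that("logistic regression rejects constant predictors", {
  co <- data.frame(pe = rnorm(20), cpp = rep(1, 20),
                   ru = rnorm(20), reward = rnorm(20))
  expect_error(fit_group_logistic(co, rep(c("a", "b"), 10)), "constant")
})

test_that("symptom regression recovers a noiseless linear construction", {
  pred <- withr::with_seed(8, data.frame(ru = rnorm(30), pe = rnorm(30)))
  scores <- 2 + 3 * pred$ru - 1 * pred$pe
  fit <- suppressWarnings(fit_symptom_regression(scores, pred))  # perfect fit
  expect_equal(fit$table$estimate[fit$table$term == "ru"], 3,
               tolerance = 1e-10)
  expect_equal(fit$table$estimate[fit$table$term == "pe"], -1,
               tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("symptom regression detects a weight-coupled score", {
  hits <- withr::with_seed(21, sapply(1:40, function(s) {
    w_ru <- rnorm(40, 0.2, 0.1)
    score <- 10 + 30 * w_ru + rnorm(40, 0, 1)
    tab <- fit_symptom_regression(score, data.frame(ru = w_ru))$table
    tab$estimate[tab$term == "ru"] > 0 & tab$p[tab$term == "ru"] < 0.05
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("cognitive composite averages domain z-scores", {
  expect_equal(bacs_composite(c(50, 20), c(50, 20), c(10, 5)), 0)
  expect_equal(bacs_composite(c(60, 25), c(50, 20), c(10, 5)), 1)
  expect_equal(bacs_composite(c(60, 15), c(50, 20), c(10, 5)), 0)
  df <- data.frame(a = c(50, 60), b = c(20, 25))
  expect_equal(bacs_composite(df, c(50, 20), c(10, 5)), c(0, 1))
  expect_error(bacs_composite(c(50, 20), c(50, 20), c(10, 0)), "SD")
})
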