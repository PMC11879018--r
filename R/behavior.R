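# Behavioural statistics: empirical learning rates, update categories,
# performance error, the belief-update regression, exclusion screening,
# and group / symptom models.

#' Empirical trial-wise learning rates
#'
#' The raw learning rate on trial `t` is the belief update following the
#' prediction error, `LR_t = U_t / d_t` with `U_t = B_{t+1} - B_t` and
#' `d_t = X_t - B_t`. For aggregate statistics, rates above one are set
#' to one and negative rates to zero (updates far beyond, or opposite
#' to, the previous observation mostly reflect lapses or aberrant hand
#' movements). Trials with `|d_t|` below `pe_floor` are excluded (the
#' ratio is unstable near a zero prediction error); raw values are
#' retained for the aberrance screen. Optionally trials with raw
#' `LR < aberrant_floor` are excluded from the aggregates (follow-up
#' sensitivity filter).
#'
#' @param record A `behavior_record`.
#' @param pe_floor Minimum `|PE|` (screen units) for a defined LR.
#' @param thresholds Category bounds `c(non, total)`: clipped
#'   `LR < thresholds[1]` is a non-update, `LR >= thresholds[2]` a total
#'   update, in between a moderate update.
#' @param exclude_aberrant If `TRUE`, drop trials with raw
#'   `LR < aberrant_floor` from the aggregates.
#' @param aberrant_floor Raw-LR floor for the aberrance screen.
#' @return A list of class `lr_summary`: `trials` (data frame with
#'   `trial`, `raw_lr`, `clipped_lr`, `used`), `mean_lr`, `mean_raw_lr`,
#'   `fractions` (non/moderate/total), `n_used`, `n_aberrant`.
#' @export
empirical_learning_rates <- function(record, pe_floor = 1,
                                     thresholds = c(0.1, 0.9),
                                     exclude_aberrant = FALSE,
                                     aberrant_floor = -0.1) {
  stopifnot(is.data.frame(record))
  raw <- record$update / record$pe
  defined <- !is.na(raw) & abs(record$pe) >= pe_floor
  if (!any(defined))
    stop(structure(class = c("helibelief_empty_summary", "error", "condition"),
                   list(message = "no trials with a defined learning rate",
                        call = sys.call())))
  used <- defined
  n_aberrant <- sum(defined & raw < aberrant_floor, na.rm = TRUE)
  if (exclude_aberrant) used <- used & !(raw < aberrant_floor)
  clipped <- clip(raw, 0, 1)
  structure(list(
    trials = data.frame(trial = record$trial, raw_lr = raw,
                        clipped_lr = ifelse(defined, clipped, NA_real_),
                        used = used),
    mean_lr = mean(clipped[used]),
    mean_raw_lr = mean(raw[used]),
    fractions = categorize_updates(clipped[used], thresholds),
    n_used = sum(used),
    n_aberrant = n_aberrant,
    thresholds = thresholds
  ), class = "lr_summary")
}

#' Categorize clipped learning rates into update classes
#'
#' Non-updates (`LR < lower`), moderate updates
#' (`lower <= LR < upper`) and total updates (`LR >= upper`), defaults
#' 0.1 and 0.9. The fractions are proportions over the categorized
#' trials and sum to one.
#'
#' @param clipped_lr Clipped learning rates in `[0, 1]`.
#' @param thresholds `c(lower, upper)` category bounds.
#' @return Named numeric vector `non`, `moderate`, `total`.
#' @export
categorize_updates <- function(clipped_lr, thresholds = c(0.1, 0.9)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  x <- clipped_lr[!is.na(clipped_lr)]
  if (any(x < 0 | x > 1)) stop("clipped learning rates must lie in [0, 1]")
  n <- length(x)
  if (n == 0) return(c(non = NA_real_, moderate = NA_real_, total = NA_real_))
  c(non = sum(x < thresholds[1]) / n,
    moderate = sum(x >= thresholds[1] & x < thresholds[2]) / n,
    total = sum(x >= thresholds[2]) / n)
}

#' Performance error against the hidden mean
#'
#' Absolute deviance between the prediction and the true underlying
#' mean, the task's accuracy metric: lower is better. `mode = "mean"`
#' (default) averages per trial across the session; `mode = "sum"`
#' sums the deviance within each block (stable stretch between change
#' points) and totals across blocks. Missing trials are excluded.
#'
#' @param record A `behavior_record`.
#' @param schedule The aligned `task_schedule`.
#' @param mode `"mean"` or `"sum"`.
#' @return Performance error in screen units.
#' @export
performance_error <- function(record, schedule, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (nrow(record) != nrow(schedule))
    stop("record and schedule are misaligned (length mismatch)")
  dev <- abs(record$prediction - schedule$mean)
  ok <- !is.na(dev)
  if (mode == "mean") mean(dev[ok]) else sum(dev[ok])
}

#' Learning rate on trials following change points
#'
#' Mean clipped learning rate on change-point trials, i.e. the updates
#' enacted after the first outcome from a relocated mean — where fast
#' updating is optimal. `window` extends the average over the first
#' `window` trials from each change point.
#'
#' @param record A `behavior_record`.
#' @param schedule The aligned `task_schedule` (true change-point
#'   flags; run-start forced change points are excluded since no
#'   prediction error precedes a run).
#' @param window Number of trials from each change point to include.
#' @param pe_floor Minimum `|PE|` for a defined LR.
#' @return Mean clipped LR on the selected trials.
#' @export
post_changepoint_learning <- function(record, schedule, window = 1,
                                      pe_floor = 1) {
  cps <- which(schedule$is_change_point & schedule$trial_in_run > 1L)
  if (!length(cps)) stop("schedule contains no change points beyond run starts")
  idx <- unique(unlist(lapply(cps, function(t) t + seq_len(window) - 1L)))
  idx <- idx[idx <= nrow(schedule)]
  raw <- record$update[idx] / record$pe[idx]
  ok <- !is.na(raw) & abs(record$pe[idx]) >= pe_floor
  mean(clip(raw[ok], 0, 1))
}

#' Fit the trial-wise belief-update regression
#'
#' Ordinary least squares of the signed belief update on the observer's
#' trial-wise quantities: an intercept (left/rightward tendency), the
#' signed prediction error, its interactions with CPP and with
#' `RU * (1 - CPP)` (isolating each factor's unique contribution), a
#' reward term, and a cubic edge-avoidance term in the current belief
#' location. All regressors are centred before entering the regression
#' (slopes are unaffected; the intercept absorbs the means). The
#' per-trial residuals quantify updating beyond what the model predicts
#' and feed the fMRI design as a parametric modulator.
#'
#' @param record A `behavior_record`.
#' @param trace The subject's `observer_trace` computed in empirical
#'   mode on this record.
#' @param reward_coding `"interaction"` (default): reward scales the
#'   prediction error, `d * r`; `"main"`: plain binary regressor.
#' @param scale_min,scale_max Screen scale bounds for the edge term.
#' @return A list of class `update_fit`: `coefficients` and `se`
#'   (named: intercept, pe, cpp, ru, reward, edge; `NA` for dropped
#'   columns), `r_squared`, `residuals` (full-length, `NA` on unused
#'   trials), `n_trials`, `dropped`.
#' @export
fit_update_regression <- function(record, trace,
                                  reward_coding = c("interaction", "main"),
                                  scale_min = 0, scale_max = 100) {
  reward_coding <- match.arg(reward_coding)
  if (nrow(record) != nrow(trace))
    stop("record and trace are misaligned (length mismatch)")
  mid <- (scale_min + scale_max) / 2
  half <- (scale_max - scale_min) / 2
  reward_term <- if (reward_coding == "interaction")
    record$pe * record$reward else record$reward
  X <- cbind(
    pe = record$pe,
    cpp = record$pe * trace$cpp,
    ru = record$pe * trace$ru * (1 - trace$cpp),
    reward = reward_term,
    edge = ((record$prediction - mid) / half)^3
  )
  y <- record$update
  ok <- stats::complete.cases(X) & !is.na(y)
  Xc <- scale(X[ok, , drop = FALSE], center = TRUE, scale = FALSE)
  yok <- y[ok]
  keep <- apply(Xc, 2, function(col) stats::sd(col) > 1e-12)
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    warning("dropping constant regressor(s): ", paste(dropped, collapse = ", "))
  fit <- stats::lm(yok ~ Xc[, keep, drop = FALSE])
  cf <- se <- rep(NA_real_, ncol(X) + 1)
  names(cf) <- names(se) <- c("intercept", colnames(X))
  cf["intercept"] <- stats::coef(fit)[1]
  cf[colnames(X)[keep]] <- stats::coef(fit)[-1]
  sm_se <- summary(fit)$coefficients[, "Std. Error"]
  se["intercept"] <- sm_se[1]
  se[colnames(X)[keep]] <- sm_se[-1]
  res <- rep(NA_real_, nrow(record))
  res[ok] <- stats::residuals(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((yok - mean(yok))^2)
  structure(list(
    coefficients = cf,
    se = se,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    residuals = res,
    n_trials = sum(ok),
    dropped = dropped
  ), class = "update_fit")
}

#' Screen a subject for exclusion
#'
#' Advisory flags mirroring the study's screening: exclusion when more
#' than `missing_max` of trials are missing; a "random prediction" proxy
#' (correlation between predictions and outcomes below `cor_floor`,
#' i.e. predictions that do not follow the outcome trajectory); a
#' "repetitive behaviour" proxy (prediction SD below `sd_floor`, e.g.
#' the same prediction on every trial). Flags never silently drop data.
#'
#' @param record A `behavior_record`.
#' @param missing_max Maximum tolerated missing fraction.
#' @param cor_floor Minimum prediction-outcome correlation.
#' @param sd_floor Minimum prediction SD (screen units).
#' @return Named logical vector `missing_excess`, `random_prediction`,
#'   `repetitive`, plus attribute `missing_fraction`.
#' @export
exclusion_screen <- function(record, missing_max = 0.25,
                             cor_floor = 0.2, sd_floor = 1) {
  miss_frac <- mean(record$missing)
  pred <- record$prediction[!record$missing]
  out <- record$outcome[!record$missing]
  pred_sd <- stats::sd(pred)
  repetitive <- is.na(pred_sd) || pred_sd < sd_floor
  random_pred <- if (repetitive) FALSE else
    stats::cor(pred, out) < cor_floor
  structure(
    c(missing_excess = miss_frac > missing_max,
      random_prediction = isTRUE(random_pred),
      repetitive = isTRUE(repetitive)),
    missing_fraction = miss_frac
  )
}

#' Compare a per-subject metric between groups
#'
#' Welch t-test and Wilcoxon rank-sum test on the same metric, with an
#' optional sensitivity re-test after excluding outliers (default rule:
#' more than `mad_mult` MADs from the group median).
#'
#' @param metric Numeric per-subject values.
#' @param group Two-level factor or character group labels.
#' @param outlier_rule `"none"` or `"mad"`.
#' @param mad_mult MAD multiplier for the outlier rule.
#' @return A list of class `group_comparison`: `t_test`, `wilcoxon`,
#'   group means/SDs, and (if requested) `t_test_no_outliers` plus the
#'   excluded indices.
#' @export
group_compare <- function(metric, group, outlier_rule = c("none", "mad"),
                          mad_mult = 3) {
  outlier_rule <- match.arg(outlier_rule)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("`group` must have exactly two levels")
  if (any(table(group) < 2)) stop("each group needs at least two subjects")
  tt <- stats::t.test(metric ~ group)
  wt <- stats::wilcox.test(metric ~ group, exact = FALSE)
  out <- list(
    t_test = tt, wilcoxon = wt,
    means = tapply(metric, group, mean, na.rm = TRUE),
    sds = tapply(metric, group, stats::sd, na.rm = TRUE)
  )
  if (outlier_rule == "mad") {
    keep <- rep(TRUE, length(metric))
    for (g in levels(group)) {
      i <- which(group == g)
      med <- stats::median(metric[i], na.rm = TRUE)
      md <- stats::mad(metric[i], na.rm = TRUE)
      if (is.finite(md) && md > 0)
        keep[i] <- abs(metric[i] - med) <= mad_mult * md
    }
    out$excluded <- which(!keep)
    if (all(tapply(keep, group, sum) >= 2))
      out$t_test_no_outliers <- stats::t.test(metric[keep] ~ group[keep])
  }
  structure(out, class = "group_comparison")
}

#' Logistic regression of group status on update-regression coefficients
#'
#' Predicts group membership from the per-subject belief-update
#' coefficients (PE, CPP, RU, reward), optionally with covariates (age,
#' cognitive scores). Reports Wald z and p per predictor plus
#' likelihood-ratio p-values (more robust when fitted probabilities
#' approach 0/1). Under (quasi-)separation the Wald statistics collapse;
#' a ridge-penalized fallback fit is then reported alongside, flagged in
#' the result.
#'
#' @param coefs Data frame of per-subject coefficients (columns used:
#'   `pe`, `cpp`, `ru`, `reward`; extra columns ignored).
#' @param group Two-level group labels; the second factor level is the
#'   modelled outcome.
#' @param covariates Optional data frame of additional predictors.
#' @return A list of class `group_logistic`: `table` (term, estimate,
#'   z, p_wald, p_lrt), `separation`, and `penalized` (ridge estimates,
#'   only when separation was detected and glmnet is available).
#' @export
fit_group_logistic <- function(coefs, group, covariates = NULL) {
  terms <- intersect(c("pe", "cpp", "ru", "reward"), colnames(coefs))
  if (!length(terms)) stop("no usable coefficient columns")
  X <- coefs[, terms, drop = FALSE]
  if (!is.null(covariates)) X <- cbind(X, covariates)
  if (any(vapply(X, function(col) stats::sd(col, na.rm = TRUE), 1) < 1e-12))
    stop("a predictor column is constant")
  y <- as.integer(as.factor(group)) - 1L
  dat <- cbind(data.frame(.group = y), X)
  fit <- suppressWarnings(
    stats::glm(.group ~ ., data = dat, family = stats::binomial())
  )
  p_hat <- stats::fitted(fit)
  separation <- any(p_hat < 1e-8 | p_hat > 1 - 1e-8) || !fit$converged
  sm <- summary(fit)$coefficients
  lrt <- suppressWarnings(stats::drop1(fit, test = "Chisq"))
  tab <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    z = sm[, "z value"],
    p_wald = sm[, "Pr(>|z|)"],
    p_lrt = c(NA, lrt[rownames(lrt) != "<none>", "Pr(>Chi)"]),
    row.names = NULL
  )
  penalized <- NULL
  if (separation && requireNamespace("glmnet", quietly = TRUE)) {
    Xm <- as.matrix(X)
    pen <- suppressWarnings(
      glmnet::glmnet(Xm, y, family = "binomial", alpha = 0, lambda = 0.05))
    penalized <- stats::setNames(
      as.numeric(stats::coef(pen)), rownames(stats::coef(pen)))
  }
  structure(list(table = tab, separation = separation,
                 penalized = penalized, fit = fit),
            class = "group_logistic")
}

#' Linear regressions of symptom scores on behavioural measures
#'
#' Ordinary least squares predicting a symptom score (e.g. total PDI
#' across the whole sample, or PANSS scales within the clinical group)
#' from per-subject predictors (update-regression coefficients or task
#' performance), with optional covariates such as verbal memory and
#' processing speed.
#'
#' @param scores Numeric symptom scores per subject.
#' @param predictors Data frame of predictors.
#' @param covariates Optional data frame of control covariates.
#' @return A list of class `symptom_fit`: `table` (term, estimate, t,
#'   p), `r_squared`, and the underlying `lm` fit.
#' @export
fit_symptom_regression <- function(scores, predictors, covariates = NULL) {
  X <- as.data.frame(predictors)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  if (length(scores) <= ncol(X) + 1)
    stop("need more subjects than predictors")
  dat <- cbind(data.frame(.score = scores), X)
  fit <- stats::lm(.score ~ ., data = dat)
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    estimate = sm$coefficients[, "Estimate"],
                    t = sm$coefficients[, "t value"],
                    p = sm$coefficients[, "Pr(>|t|)"],
                    row.names = NULL)
  structure(list(table = tab, r_squared = sm$r.squared, fit = fit),
            class = "symptom_fit")
}

#' Cognitive composite z-score
#'
#' Averages per-domain z-scores of a cognitive battery against
#' reference (control-group) means and SDs — the standard composite for
#' batteries like the BACS.
#'
#' @param domains Numeric vector (one subject) or data frame (subjects
#'   in rows) of domain scores.
#' @param ref_mean,ref_sd Reference means and SDs, aligned with the
#'   domain columns.
#' @return Composite z-score(s).
#' @export
bacs_composite <- function(domains, ref_mean, ref_sd) {
  if (any(ref_sd <= 0)) stop("reference SDs must be > 0")
  if (is.data.frame(domains) || is.matrix(domains)) {
    z <- sweep(sweep(as.matrix(domains), 2, ref_mean), 2, ref_sd, "/")
    rowMeans(z, na.rm = TRUE)
  } else {
    mean((domains - ref_mean) / ref_sd, na.rm = TRUE)
  }
}
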