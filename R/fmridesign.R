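# First-level model-based fMRI: canonical HRF, design matrix with
# standardized (non-orthogonalized) parametric modulators, synthetic
# BOLD simulation, GLM estimation, and VOI-level statistics.

#' Scan configuration
#'
#' Acquisition and simulation settings for the first-level model.
#'
#' @param tr Repetition time in seconds (default 0.8).
#' @param n_scans_per_run Scans per run; if `NULL`, derived from the
#'   event timeline with a short post-session buffer.
#' @param microtime Temporal oversampling bins per TR used for
#'   convolution before downsampling to the scan grid.
#' @param ar1_rho Lag-1 autocorrelation of simulated BOLD noise.
#' @param noise_sd Stationary SD of simulated BOLD noise (signal units).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(tr = 0.8, n_scans_per_run = NULL, microtime = 16,
                        ar1_rho = 0.3, noise_sd = 1) {
  if (tr <= 0) config_error("tr", "must be > 0")
  if (abs(ar1_rho) >= 1) config_error("ar1_rho", "must satisfy |rho| < 1")
  if (microtime < 1) config_error("microtime", "must be >= 1")
  if (noise_sd < 0) config_error("noise_sd", "must be >= 0")
  structure(list(tr = tr, n_scans_per_run = n_scans_per_run,
                 microtime = as.integer(microtime),
                 ar1_rho = ar1_rho, noise_sd = noise_sd),
            class = "scan_config")
}

# Continuous canonical double-gamma response (peak ~5 s, undershoot
# ~15 s), normalized to unit peak via its analytic maximum.
hrf_shape <- function(t) {
  stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
}

#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical HRF (gamma response peaking near 5 s minus a
#' 1/6-weighted undershoot gamma peaking near 15 s, 32 s support) on a
#' regular grid. The kernel is normalized by the analytic peak of the
#' continuous shape, so sampling at different resolutions yields
#' mutually consistent kernels.
#'
#' @param dt Sampling interval in seconds (e.g. the TR, or the
#'   microtime resolution).
#' @param duration Kernel support in seconds.
#' @return Numeric kernel sampled at `0, dt, 2*dt, ...`, with the time
#'   grid attached as attribute `times`.
#' @export
canonical_hrf <- function(dt, duration = 32) {
  if (dt <= 0) config_error("dt", "must be > 0")
  times <- seq(0, duration, by = dt)
  peak <- stats::optimize(hrf_shape, c(0, 10), maximum = TRUE)$objective
  structure(hrf_shape(times) / peak, times = times)
}

#' Build the first-level design matrix
#'
#' Constructs the event-related design: one onset regressor for the
#' bag-drop events (1 s duration), five parametric modulators (outcome
#' location, CPP, RU, reward, and the belief-update regression
#' residual), an error-trial regressor spanning each whole missing
#' trial, optional motion nuisance columns, and per-run intercepts.
#' Modulator trial series are standardized (zero mean, unit SD) within
#' run — not orthogonalized — multiplied into the event boxcar at
#' microtime resolution, convolved with the canonical HRF, and
#' downsampled to the scan grid. Constant modulator series degenerate
#' under standardization and are dropped with a warning.
#'
#' @param events Events table (the [build_events()] dialect): columns
#'   `onset` (bag drop, run-relative seconds), `duration`, `run`,
#'   `missing`, `trial_start`, `trial_duration`.
#' @param modulators Data frame of per-trial modulator series aligned
#'   with `events` rows (standard columns: `outcome`, `cpp`, `ru`,
#'   `reward`, `residual`); values on missing trials are ignored.
#' @param cfg A [scan_config()].
#' @param motion Optional matrix (total scans x 6) of motion nuisance
#'   regressors; see [simulate_motion()].
#' @param standardize `"run"` (default) or `"session"`.
#' @return A list of class `design_matrix`: `X` (scans x columns),
#'   `scan_run` (run index per scan), `n_scans`, `dropped`, `cfg`.
#' @export
build_design_matrix <- function(events, modulators, cfg = scan_config(),
                                motion = NULL,
                                standardize = c("run", "session")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(cfg, "scan_config"))
  mod_names <- colnames(modulators)
  if (any(!is.finite(as.matrix(modulators)[!events$missing, ])))
    stop("NaN/NA modulator value on a non-missing trial")
  runs <- sort(unique(events$run))
  dt <- cfg$tr / cfg$microtime
  h <- canonical_hrf(dt)

  # standardize modulator trial series over non-missing trials
  Z <- as.matrix(modulators)
  dropped <- character(0)
  groups <- if (standardize == "run") events$run else rep(1L, nrow(events))
  for (j in seq_along(mod_names)) {
    for (g in unique(groups)) {
      i <- which(groups == g & !events$missing)
      s <- stats::sd(Z[i, j])
      if (is.na(s) || s < 1e-12) {
        dropped <- union(dropped, mod_names[j])
      } else {
        Z[i, j] <- (Z[i, j] - mean(Z[i, j])) / s
      }
    }
  }
  keep_mods <- setdiff(mod_names, dropped)
  if (length(dropped))
    warning("dropping constant modulator(s): ", paste(dropped, collapse = ", "))

  per_run <- lapply(runs, function(r) {
    ev <- events[events$run == r, , drop = FALSE]
    zr <- Z[events$run == r, , drop = FALSE]
    run_end <- max(ev$trial_start + ev$trial_duration)
    n_scans <- cfg$n_scans_per_run %||% (ceiling(run_end / cfg$tr) + 8L)
    L <- ceiling((n_scans - 1) * cfg$tr / dt) + 1L
    grid_col <- function(onsets, durations, amps) {
      x <- numeric(L + length(h))
      for (k in seq_along(onsets)) {
        i0 <- floor(onsets[k] / dt) + 1L
        i1 <- min(L, floor((onsets[k] + durations[k]) / dt))
        if (i1 >= i0) x[i0:i1] <- x[i0:i1] + amps[k]
      }
      conv <- stats::convolve(x, rev(h), type = "open")[seq_len(L)]
      conv[round(seq(0, n_scans - 1) * cfg$tr / dt) + 1L]
    }
    ok <- !ev$missing
    cols <- list(onset = grid_col(ev$onset[ok], ev$duration[ok],
                                  rep(1, sum(ok))))
    for (m in keep_mods)
      cols[[paste0("mod_", m)]] <-
        grid_col(ev$onset[ok], ev$duration[ok], zr[ok, m])
    cols$error <- if (any(ev$missing))
      grid_col(ev$trial_start[ev$missing], ev$trial_duration[ev$missing],
               rep(1, sum(ev$missing)))
    else numeric(n_scans)
    list(cols = do.call(cbind, cols), n_scans = n_scans)
  })

  task <- do.call(rbind, lapply(per_run, `[[`, "cols"))
  n_scans <- as.integer(vapply(per_run, function(p) as.numeric(p$n_scans),
                               numeric(1)))
  if (all(task[, "error"] == 0)) {  # no missing trials anywhere
    task <- task[, colnames(task) != "error", drop = FALSE]
    dropped <- union(dropped, "error")
  }
  scan_run <- rep(runs, n_scans)
  blocks <- vapply(runs, function(r) as.numeric(scan_run == r),
                   numeric(length(scan_run)))
  colnames(blocks) <- paste0("run", runs)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != sum(n_scans))
      stop("motion regressors do not match the total scan count")
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    X <- cbind(task, motion, blocks)
  } else {
    X <- cbind(task, blocks)
  }
  structure(list(X = X, scan_run = scan_run, n_scans = n_scans,
                 dropped = dropped, cfg = cfg),
            class = "design_matrix")
}

#' Simulate smooth head-motion nuisance regressors
#'
#' Random-walk translations/rotations (cumulative small Gaussian steps,
#' demeaned), six columns as in standard realignment output.
#'
#' @param n_scans Total number of scans.
#' @param seed Integer seed.
#' @param step_sd SD of per-scan increments.
#' @return A `n_scans` x 6 matrix.
#' @export
simulate_motion <- function(n_scans, seed = 1L, step_sd = 0.02) {
  withr::with_seed(seed, {
    m <- vapply(seq_len(6), function(j)
      cumsum(stats::rnorm(n_scans, 0, step_sd)), numeric(n_scans))
  })
  sweep(m, 2, colMeans(m))
}

#' Simulate BOLD time series from a design
#'
#' `y = X beta + AR(1) noise`, with the innovation variance chosen so
#' the stationary noise SD equals `cfg$noise_sd`. Multi-voxel mode
#' replicates with voxel-wise beta maps.
#'
#' @param design A [build_design_matrix()] result.
#' @param betas Named vector (single voxel) or matrix
#'   (columns = voxels, rows named by design columns) of true effects;
#'   unnamed design columns default to 0.
#' @param cfg A [scan_config()] (noise settings).
#' @param seed Integer seed.
#' @return Numeric vector (one voxel) or scans x voxels matrix.
#' @export
simulate_bold <- function(design, betas, cfg = design$cfg, seed = 1L) {
  X <- design$X
  B <- as.matrix(betas)
  full <- matrix(0, ncol(X), ncol(B),
                 dimnames = list(colnames(X), colnames(B)))
  rn <- if (is.null(rownames(B))) names(betas) else rownames(B)
  if (is.null(rn)) stop("`betas` must be named by design column")
  miss <- setdiff(rn, colnames(X))
  if (length(miss)) stop("unknown design column(s): ", paste(miss, collapse = ", "))
  full[rn, ] <- B
  signal <- X %*% full
  n <- nrow(X)
  withr::with_seed(seed, {
    noise <- vapply(seq_len(ncol(full)), function(v) {
      if (cfg$noise_sd == 0) return(numeric(n))
      innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1_rho^2)
      as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                               cfg$ar1_rho, method = "recursive"))
    }, numeric(n))
  })
  y <- signal + noise
  if (ncol(y) == 1L) as.numeric(y) else y
}

#' Fit the first-level GLM
#'
#' Massively univariate least squares of BOLD time series on the design,
#' optionally with AR(1) prewhitening (known or residual-estimated rho).
#' Contrasts are linear combinations of the betas with classical t
#' statistics.
#'
#' @param y Numeric vector or scans x voxels matrix.
#' @param design A [build_design_matrix()] result.
#' @param whitening `"none"` or `"ar1"`.
#' @param rho AR(1) coefficient for whitening; estimated from OLS
#'   residuals (lag-1 autocorrelation) when `NULL`.
#' @param contrasts Optional named list of contrast weight vectors
#'   (named by design column; unnamed columns get weight 0).
#' @return A list of class `glm_fit`: `betas` (columns x voxels), `se`,
#'   `t`, `df`, `sigma2`, `rho`, `contrasts` (estimate/se/t per
#'   contrast).
#' @export
fit_glm <- function(y, design, whitening = c("none", "ar1"), rho = NULL,
                    contrasts = NULL) {
  whitening <- match.arg(whitening)
  X <- design$X
  Y <- as.matrix(y)
  if (nrow(Y) != nrow(X)) stop("time series and design length mismatch")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (whitening == "ar1") {
    if (is.null(rho)) {
      r0 <- stats::lm.fit(X, Y)$residuals
      r0 <- as.matrix(r0)
      rho <- mean(vapply(seq_len(ncol(r0)), function(v) {
        e <- r0[, v]
        sum(e[-1] * e[-length(e)]) / sum(e^2)
      }, numeric(1)))
    }
    # Cochrane-Orcutt transform with exact first-row scaling
    w <- function(M) {
      M <- as.matrix(M)
      out <- M
      out[1, ] <- M[1, ] * sqrt(1 - rho^2)
      out[-1, ] <- M[-1, ] - rho * M[-nrow(M), ]
      out
    }
    Xw <- w(X); Yw <- w(Y)
  } else {
    rho <- 0; Xw <- X; Yw <- Y
  }
  fit <- stats::lm.fit(Xw, Yw)
  betas <- as.matrix(fit$coefficients)
  res <- as.matrix(fit$residuals)
  df <- nrow(Xw) - ncol(Xw)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(Xw)))
  var_diag <- diag(XtXinv)
  se <- sqrt(outer(var_diag, sigma2))
  rownames(betas) <- rownames(se) <- colnames(X)
  ct <- NULL
  if (!is.null(contrasts)) {
    ct <- lapply(contrasts, function(wts) {
      cvec <- stats::setNames(numeric(ncol(X)), colnames(X))
      cvec[names(wts)] <- wts
      est <- drop(crossprod(cvec, betas))
      cse <- sqrt(drop(crossprod(cvec, XtXinv %*% cvec)) * sigma2)
      list(estimate = est, se = cse, t = est / cse)
    })
  }
  structure(list(betas = betas, se = se, t = betas / se, df = df,
                 sigma2 = sigma2, rho = rho, contrasts = ct),
            class = "glm_fit")
}

#' Rank correlations between VOI effect sizes and outcome scores
#'
#' Spearman correlations (average ranks for ties) between per-subject
#' volume-of-interest effect sizes and clinical/cognitive scores.
#'
#' @param voi_values Numeric per-subject VOI values.
#' @param scores Data frame (or named list) of score vectors.
#' @return Data frame with columns `score`, `rho`, `p`, `n`.
#' @export
voi_correlate <- function(voi_values, scores) {
  scores <- as.data.frame(scores)
  if (stats::sd(voi_values, na.rm = TRUE) == 0)
    stop("VOI values are constant")
  rows <- lapply(names(scores), function(nm) {
    ok <- stats::complete.cases(voi_values, scores[[nm]])
    if (sum(ok) < 5) stop("need at least 5 complete pairs for ", nm)
    ct <- suppressWarnings(
      stats::cor.test(voi_values[ok], scores[[nm]][ok], method = "spearman"))
    data.frame(score = nm, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Group comparison of VOI effect sizes controlling for age
#'
#' Per-VOI linear model `beta ~ group + age`, reporting the group
#' effect.
#'
#' @param voi_values Numeric per-subject VOI effect sizes.
#' @param group Two-level group labels.
#' @param age Numeric age covariate.
#' @return Data frame with the group term's estimate, t and p.
#' @export
group_beta_compare <- function(voi_values, group, age) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("`group` must have two levels")
  if (length(voi_values) < 6) stop("too few subjects")
  fit <- stats::lm(voi_values ~ group + age)
  sm <- summary(fit)$coefficients
  grow <- grep("^group", rownames(sm))
  data.frame(term = rownames(sm)[grow],
             estimate = sm[grow, "Estimate"],
             t = sm[grow, "t value"],
             p = sm[grow, "Pr(>|t|)"],
             row.names = NULL)
}
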