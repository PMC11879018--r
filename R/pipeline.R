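# End-to-end orchestration: config-driven synthetic-cohort study
# mirroring the behavioural and first-level fMRI analysis sequence.

#' Study configuration
#'
#' Assembles and validates the nested configuration for a full
#' synthetic study: task schedule, observer settings, cohort
#' composition, analysis switches, and the optional fMRI stage. The
#' master seed fixes every stage (each stage and subject derives its
#' own sub-seed, so adding subjects never perturbs existing ones).
#'
#' @param task Named list of [task_config()] overrides.
#' @param observer Named list: `hazard`, `tau_init`.
#' @param n_hc,n_psd Group sizes.
#' @param hc_params,psd_params Named lists of [agent_params()]
#'   overrides applied to the `"hc"` / `"psd"` presets.
#' @param covariates Named list of [covariate_model()] overrides.
#' @param analysis Named list: `category_thresholds` (c(lower, upper)),
#'   `reward_coding` (`"interaction"`/`"main"`), `pe_floor`,
#'   `exclude_aberrant`.
#' @param fmri Named list: `enable` (logical), plus [scan_config()]
#'   overrides and `betas` (named true effects for the simulated
#'   subject) and `n_voxels`.
#' @param seed Master seed.
#' @return A list of class `study_config`.
#' @export
study_config <- function(task = list(), observer = list(),
                         n_hc = 40, n_psd = 19,
                         hc_params = list(), psd_params = list(),
                         covariates = list(),
                         analysis = list(), fmri = list(), seed = 1L) {
  known <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      config_error(paste0(where, ".", bad[1]), "unknown configuration key")
    x
  }
  known(observer, c("hazard", "tau_init"), "observer")
  known(analysis, c("category_thresholds", "reward_coding", "pe_floor",
                    "exclude_aberrant"), "analysis")
  known(fmri, c("enable", "tr", "n_scans_per_run", "microtime", "ar1_rho",
                "noise_sd", "betas", "n_voxels"), "fmri")
  task_cfg <- do.call(task_config, utils::modifyList(
    list(seed = sub_seed(seed, "schedule")), task))
  hazard <- observer$hazard %||% task_cfg$hazard
  check_prob(hazard, "observer.hazard", open = TRUE)
  tau_init <- observer$tau_init %||% 0.5
  if (tau_init < 0 || tau_init >= 1)
    config_error("observer.tau_init", "must lie in [0, 1)")
  hc <- do.call(agent_preset, c(list(name = "hc"), hc_params))
  psd <- do.call(agent_preset, c(list(name = "psd"), psd_params))
  cov_model <- do.call(covariate_model, covariates)
  analysis <- utils::modifyList(
    list(category_thresholds = c(0.1, 0.9), reward_coding = "interaction",
         pe_floor = 1, exclude_aberrant = FALSE), analysis)
  fmri_defaults <- list(enable = FALSE, tr = 0.8, microtime = 16,
                        ar1_rho = 0.3, noise_sd = 1, n_voxels = 1,
                        betas = c(onset = 1, mod_outcome = 0.2,
                                  mod_cpp = 0.5, mod_ru = 0.3,
                                  mod_reward = 0.1, mod_residual = 0.1))
  fmri <- utils::modifyList(fmri_defaults, fmri)
  if (n_hc < 1 || n_psd < 1)
    config_error("n_hc/n_psd", "group sizes must be >= 1")
  structure(list(task = task_cfg, hazard = hazard, tau_init = tau_init,
                 n_hc = n_hc, n_psd = n_psd,
                 hc_params = hc, psd_params = psd, cov_model = cov_model,
                 analysis = analysis, fmri = fmri,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Load a study configuration from YAML
#'
#' Reads a YAML file whose top-level keys match the arguments of
#' [study_config()]; unknown keys are rejected with the offending field
#' path. An empty file yields the defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `study_config`.
#' @export
load_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- setdiff(names(formals(study_config)), "...")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) config_error(bad[1], "unknown top-level configuration key")
  for (nm in c("task", "observer", "hc_params", "psd_params",
               "covariates", "analysis", "fmri"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.list(raw[[nm]])
  do.call(study_config, raw)
}

#' Per-subject behavioural analysis
#'
#' Runs the empirical-mode observer on one behaviour record and derives
#' the full per-subject battery: learning-rate summary, update
#' categories, performance error, post-change-point learning, the
#' belief-update regression, and exclusion flags.
#'
#' @param record A `behavior_record`.
#' @param schedule The shared `task_schedule`.
#' @param hazard,tau_init Observer settings.
#' @param analysis Analysis switches (see [study_config()]).
#' @return A list: `trace`, `fit`, `lr`, and a one-row `stats` data
#'   frame.
#' @export
analyze_subject <- function(record, schedule, hazard = 0.125,
                            tau_init = 0.5,
                            analysis = list(category_thresholds = c(0.1, 0.9),
                                            reward_coding = "interaction",
                                            pe_floor = 1,
                                            exclude_aberrant = FALSE)) {
  cfg <- observer_config(hazard = hazard, tau_init = tau_init,
                         conditioning = "empirical")
  trace <- run_observer(record$outcome, schedule$noise_sd,
                        runs = record$run, cfg = cfg,
                        predictions = record$prediction,
                        missing = record$missing)
  fit <- fit_update_regression(record, trace,
                               reward_coding = analysis$reward_coding)
  lr <- empirical_learning_rates(record, pe_floor = analysis$pe_floor,
                                 thresholds = analysis$category_thresholds,
                                 exclude_aberrant = analysis$exclude_aberrant)
  flags <- exclusion_screen(record)
  stats_row <- data.frame(
    performance = performance_error(record, schedule),
    mean_lr = lr$mean_lr,
    lr_post_cp = post_changepoint_learning(record, schedule,
                                           pe_floor = analysis$pe_floor),
    frac_non = lr$fractions[["non"]],
    frac_moderate = lr$fractions[["moderate"]],
    frac_total = lr$fractions[["total"]],
    n_aberrant = lr$n_aberrant,
    missing_fraction = mean(record$missing),
    r_squared = fit$r_squared,
    beta_intercept = fit$coefficients[["intercept"]],
    beta_pe = fit$coefficients[["pe"]],
    beta_cpp = fit$coefficients[["cpp"]],
    beta_ru = fit$coefficients[["ru"]],
    beta_reward = fit$coefficients[["reward"]],
    beta_edge = fit$coefficients[["edge"]],
    excluded = any(flags)
  )
  list(trace = trace, fit = fit, lr = lr, stats = stats_row)
}

#' Run a full synthetic study
#'
#' Executes the analysis sequence end to end: shared schedule, cohort
#' simulation, per-subject empirical-mode observer traces and
#' belief-update regressions, behavioural summaries, group comparisons,
#' the group-status logistic model, symptom regressions, and (when
#' enabled) the first-level fMRI simulation/recovery stage. Reruns with
#' the same configuration are bit-identical. When `out_dir` is given,
#' all intermediates are persisted (schedule, covariates, events,
#' traces, subject statistics, report JSON).
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory for persisted intermediates.
#' @return A list of class `study_report`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  schedule <- generate_schedule(config$task)
  cohort <- simulate_cohort(config$n_hc, config$n_psd, schedule = schedule,
                            hc_params = config$hc_params,
                            psd_params = config$psd_params,
                            cov_model = config$cov_model,
                            hazard_belief = config$hazard,
                            seed = config$seed)
  analyses <- lapply(cohort$records, analyze_subject, schedule = schedule,
                     hazard = config$hazard, tau_init = config$tau_init,
                     analysis = config$analysis)
  stats <- do.call(rbind, lapply(analyses, `[[`, "stats"))
  stats <- cbind(cohort$covariates[, c("subject", "group")], stats)
  covs <- cohort$covariates
  group <- factor(covs$group, levels = c("hc", "psd"))

  behaviour <- list(
    performance = group_compare(stats$performance, group, outlier_rule = "mad"),
    mean_lr = group_compare(stats$mean_lr, group),
    lr_post_cp = group_compare(stats$lr_post_cp, group),
    frac_non = group_compare(stats$frac_non, group),
    r_squared = group_compare(stats$r_squared, group)
  )

  coefs <- data.frame(pe = stats$beta_pe, cpp = stats$beta_cpp,
                      ru = stats$beta_ru, reward = stats$beta_reward)
  logistic <- fit_group_logistic(coefs, group)
  ref <- covs[covs$group == "hc", ]
  bacs_cols <- grep("^bacs_", colnames(covs), value = TRUE)
  bacs_z <- bacs_composite(covs[, bacs_cols],
                           colMeans(ref[, bacs_cols]),
                           apply(ref[, bacs_cols], 2, stats::sd))
  symptoms <- list(
    pdi_coefs = fit_symptom_regression(covs$pdi, coefs),
    pdi_performance = fit_symptom_regression(
      covs$pdi, data.frame(performance = stats$performance),
      covariates = data.frame(verbal_memory = covs$bacs_verbal_memory,
                              processing_speed = covs$bacs_processing_speed)),
    panss_gen = if (sum(covs$group == "psd") > 6)
      fit_symptom_regression(covs$panss_gen[covs$group == "psd"],
                             coefs[covs$group == "psd", ]) else NULL
  )

  fmri <- NULL
  if (isTRUE(config$fmri$enable)) {
    fmri <- run_fmri_stage(cohort, analyses, config)
  }

  report <- structure(list(
    config = config,
    schedule = schedule,
    covariates = covs,
    subject_stats = stats,
    bacs_composite = bacs_z,
    behaviour = behaviour,
    logistic = logistic,
    symptoms = symptoms,
    fmri = fmri,
    analyses = analyses
  ), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(schedule, file.path(out_dir, "schedule.csv"),
                     row.names = FALSE)
    utils::write.csv(covs, file.path(out_dir, "covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(out_dir, "subject_stats.csv"),
                     row.names = FALSE)
    traces <- do.call(rbind, lapply(seq_along(analyses), function(i)
      cbind(subject = i, analyses[[i]]$trace)))
    write_trace_csv(traces, file.path(out_dir, "traces.csv"))
    events <- do.call(rbind, lapply(seq_along(cohort$records), function(i)
      cbind(subject = i, build_events(cohort$records[[i]]))))
    utils::write.table(events, file.path(out_dir, "events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "n/a")
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$files <- tools::md5sum(list.files(out_dir, full.names = TRUE))
  }
  report
}

# fMRI stage: first-level recovery on one simulated subject plus
# cohort-level VOI statistics on simulated effect sizes.
run_fmri_stage <- function(cohort, analyses, config) {
  fc <- config$fmri
  cfg <- scan_config(tr = fc$tr, n_scans_per_run = fc$n_scans_per_run,
                     microtime = fc$microtime, ar1_rho = fc$ar1_rho,
                     noise_sd = fc$noise_sd)
  record <- cohort$records[[1]]
  trace <- analyses[[1]]$trace
  events <- build_events(record)
  resid <- analyses[[1]]$fit$residuals
  resid[is.na(resid)] <- 0  # trials with no defined update: model-consistent
  modulators <- data.frame(outcome = record$outcome, cpp = trace$cpp,
                           ru = trace$ru, reward = record$reward,
                           residual = resid)
  design <- build_design_matrix(events, modulators, cfg,
                                motion = simulate_motion(
                                  sum_scans(events, cfg),
                                  seed = sub_seed(config$seed, "motion")))
  betas <- fc$betas[setdiff(names(fc$betas),
                            paste0("mod_", design$dropped))]
  y <- simulate_bold(design, betas, cfg,
                     seed = sub_seed(config$seed, "bold"))
  fit <- fit_glm(y, design, whitening = "ar1", rho = cfg$ar1_rho)
  common <- intersect(names(betas), rownames(fit$betas))
  recovery <- data.frame(column = common,
                         truth = as.numeric(betas[common]),
                         estimate = fit$betas[common, 1])
  recovery$error <- recovery$estimate - recovery$truth

  # cohort-level VOI: simulated effect sizes coupled to CPP weighting
  covs <- cohort$covariates
  voi <- withr::with_seed(sub_seed(config$seed, "voi"), {
    3 * covs$true_w_cpp + stats::rnorm(nrow(covs), 0, 0.3)
  })
  list(design = design, recovery = recovery,
       modulator_correlation = stats::cor(
         design$X[, grep("^mod_", colnames(design$X)), drop = FALSE]),
       voi_group = group_beta_compare(voi, covs$group, covs$age),
       voi_scores = voi_correlate(voi, data.frame(pdi = covs$pdi)))
}

sum_scans <- function(events, cfg) {
  if (!is.null(cfg$n_scans_per_run))
    return(cfg$n_scans_per_run * length(unique(events$run)))
  sum(vapply(unique(events$run), function(r) {
    ev <- events[events$run == r, ]
    ceiling(max(ev$trial_start + ev$trial_duration) / cfg$tr) + 8L
  }, numeric(1)))
}

#' Condense a study report into plain summaries
#'
#' Flattens a [run_study()] report into a JSON-serializable list of the
#' headline statistics (group means, test statistics, model
#' coefficients, fMRI recovery errors).
#'
#' @param report A `study_report`.
#' @return A named list of plain vectors and tables.
#' @export
report_summary <- function(report) {
  gc_row <- function(g) list(
    hc_mean = unname(g$means[["hc"]]), psd_mean = unname(g$means[["psd"]]),
    t = unname(g$t_test$statistic), p_t = g$t_test$p.value,
    p_wilcoxon = g$wilcoxon$p.value)
  out <- list(
    n_hc = sum(report$covariates$group == "hc"),
    n_psd = sum(report$covariates$group == "psd"),
    behaviour = lapply(report$behaviour, gc_row),
    coefficients = list(
      beta_pe_median = stats::median(report$subject_stats$beta_pe),
      beta_cpp_median = stats::median(report$subject_stats$beta_cpp),
      beta_ru_median = stats::median(report$subject_stats$beta_ru),
      beta_reward_median = stats::median(report$subject_stats$beta_reward),
      r_squared_mean = mean(report$subject_stats$r_squared)),
    logistic = report$logistic$table,
    seed = report$config$seed
  )
  if (!is.null(report$fmri)) {
    out$fmri <- list(recovery = report$fmri$recovery,
                     voi_group = report$fmri$voi_group)
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  s <- report_summary(x)
  cat("Synthetic belief-updating study\n")
  cat(sprintf("  subjects: %d HC, %d PSD; seed %d\n",
              s$n_hc, s$n_psd, s$seed))
  cat(sprintf("  performance error: HC %.2f vs PSD %.2f (t = %.2f, p = %.3g)\n",
              s$behaviour$performance$hc_mean,
              s$behaviour$performance$psd_mean,
              s$behaviour$performance$t, s$behaviour$performance$p_t))
  cat(sprintf("  LR after change point: HC %.2f vs PSD %.2f (p = %.3g)\n",
              s$behaviour$lr_post_cp$hc_mean, s$behaviour$lr_post_cp$psd_mean,
              s$behaviour$lr_post_cp$p_t))
  cat(sprintf("  median betas: PE %.2f, CPP %.2f, RU %.2f, reward %.2f\n",
              s$coefficients$beta_pe_median, s$coefficients$beta_cpp_median,
              s$coefficients$beta_ru_median,
              s$coefficients$beta_reward_median))
  cpp_row <- s$logistic[s$logistic$term == "cpp", ]
  if (nrow(cpp_row)) {
    if (x$logistic$separation && !is.null(x$logistic$penalized)) {
      cat(sprintf(
        "  group logistic CPP term: %.2f ridge [quasi-separated] (p_lrt = %.3g)\n",
        x$logistic$penalized[["cpp"]], cpp_row$p_lrt))
    } else {
      cat(sprintf("  group logistic CPP term: %.2f (p_lrt = %.3g)\n",
                  cpp_row$estimate, cpp_row$p_lrt))
    }
  }
  invisible(x)
}
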