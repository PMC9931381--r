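#' Run configuration for the end-to-end experiment
#'
#' Flat key/value configuration covering the study design, the effort model,
#' the split/training specification and output control. Unknown keys are
#' rejected before any computation. Defaults reproduce the full study scale
#' (54 subjects, 648 records); `smoke = TRUE` switches to a 6-subject
#' miniature for quick checks.
#'
#' @param ... Named overrides of the defaults listed in Details.
#' @param config_file Optional YAML file of overrides (applied before
#'   `...`).
#' @details Keys and defaults: study design `n_subjects` (54), `n_males`
#'   (25), `n_right_handed` (52), `sessions` (2),
#'   `trials_per_hand_per_session` (3), `age_min` (19), `age_max` (53);
#'   cohort `subject_concentration` (400), `asymmetry_sd` (1),
#'   `trial_concentration` (1500); effort model `force_fraction_low` (0.5),
#'   `force_fraction_high` (0.75), `delta_I` (2.5), `delta_II` (1.5),
#'   `delta_III` (-0.5), `delta_IV` (-0.5), `delta_V` (-0.5), `delta_TH`
#'   (-1.5), `delta_HY` (-1), `delta_jitter_sd` (0.5), `trial_force_cv`
#'   (0.05); harness `train_fraction` (0.8), `group_by_subject` (FALSE),
#'   `cv_folds` (5), `algorithms` ("xgb,svml,gbm,rf"), `include_thumb`
#'   (FALSE), `threshold_pp` (3); run control `out_dir` ("manugrip_run"),
#'   `seed` (1), `verbose` (TRUE), `smoke` (FALSE), `write_figures`
#'   (FALSE).
#' @return A validated named list of class `run_config`.
#' @export
run_config <- function(..., config_file = NULL) {
  defaults <- list(
    n_subjects = 54, n_males = 25, n_right_handed = 52, sessions = 2,
    trials_per_hand_per_session = 3, age_min = 19, age_max = 53,
    subject_concentration = 400, asymmetry_sd = 1, trial_concentration = 1500,
    force_fraction_low = 0.5, force_fraction_high = 0.75,
    delta_I = 2.5, delta_II = 1.5, delta_III = -0.5, delta_IV = -0.5,
    delta_V = -0.5, delta_TH = -1.5, delta_HY = -1.0,
    delta_jitter_sd = 0.5, trial_force_cv = 0.05,
    train_fraction = 0.8, group_by_subject = FALSE, cv_folds = 5,
    algorithms = "xgb,svml,gbm,rf", include_thumb = FALSE, threshold_pp = 3,
    out_dir = "manugrip_run", seed = 1, verbose = TRUE, smoke = FALSE,
    write_figures = FALSE)
  overrides <- list()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    overrides <- yaml::read_yaml(config_file)
  }
  overrides <- utils::modifyList(overrides, list(...))
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  if (isTRUE(cfg$smoke)) {
    cfg$n_subjects <- 6; cfg$n_males <- 3; cfg$n_right_handed <- 6
  }
  stopifnot(cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$cv_folds >= 2, cfg$threshold_pp > 0)
  structure(cfg, class = "run_config")
}

.cfg_design <- function(cfg) {
  study_design(n_subjects = cfg$n_subjects, n_males = cfg$n_males,
               n_right_handed = cfg$n_right_handed, sessions = cfg$sessions,
               trials_per_hand_per_session = cfg$trials_per_hand_per_session,
               age_range = c(cfg$age_min, cfg$age_max), seed = cfg$seed)
}

.cfg_model <- function(cfg) {
  effort_model(force_fraction_low = cfg$force_fraction_low,
               force_fraction_high = cfg$force_fraction_high,
               redistribution_delta = c(I = cfg$delta_I, II = cfg$delta_II,
                                        III = cfg$delta_III,
                                        IV = cfg$delta_IV, V = cfg$delta_V,
                                        TH = cfg$delta_TH,
                                        HY = cfg$delta_HY),
               delta_jitter_sd = cfg$delta_jitter_sd,
               trial_force_cv = cfg$trial_force_cv)
}

.cfg_algos <- function(cfg) {
  a <- cfg$algorithms
  if (length(a) == 1) a <- strsplit(a, ",")[[1]]
  a <- trimws(a)
  if (identical(a, "all")) a <- c("xgb", "svml", "gbm", "rf")
  vapply(a, .algo_canon, character(1))
}

.method_display <- c(extreme_gradient_boosting = "XGBoost",
                     linear_svm = "svmlinear",
                     gradient_boosting = "gbm",
                     random_forest = "Random Forest")

#' Threshold-method performance report at the chosen cutoff
#'
#' Fits the cutoff ROC on labelled pairs, classifies every pair at the
#' Youden-optimal cutoff, and reports sensitivity/specificity/accuracy with
#' a Clopper-Pearson interval plus the AUC (exceedance counts as scores)
#' with its DeLong interval.
#'
#' @param pairs Output of [build_pairs()].
#' @param threshold Significance threshold in percentage points (default 3).
#' @param cutoff Operating point; defaults to the Youden-optimal one.
#' @return A list with the `cutoff_roc` fit and a [metrics_report()].
#' @export
threshold_report <- function(pairs, threshold = 3.0, cutoff = NULL) {
  roc <- cutoff_roc(pairs, threshold)
  if (is.null(cutoff)) cutoff <- roc$chosen_cutoff
  counts <- pair_counts(pairs, threshold)
  pred <- ifelse(counts >= cutoff, "insincere", "sincere")
  rep <- metrics_report(pairs$truth, scores = counts, predicted = pred,
                        method_label = "Thresholds")
  list(roc = roc, report = rep, cutoff = cutoff)
}

#' Run the full experiment: simulate, threshold method, ML harness, report
#'
#' Simulates the study, writes the trials table, runs the conventional
#' exceedance-count analysis and the cross-validated ML harness, and writes
#' a side-by-side comparison of all methods. Identical configuration and
#' seed produce byte-identical CSV outputs. Stages communicate only through
#' the documented file formats, so the pipeline can be re-run stage by stage
#' from files.
#'
#' Output files under `config$out_dir`: `trials.csv`, `pairs.csv`,
#' `cutoff_roc.csv`, `group_area_comparison.csv`, `ml_metrics.csv`,
#' `comparison.csv`, `comparison.txt`, `manifest.json` (+ `roc.pdf` when
#' `write_figures`).
#'
#' @param config A [run_config()] (or a list of overrides passed to it).
#' @return Invisibly, a list with the simulated trials, the threshold
#'   result, the per-algorithm reports, the comparison table and the output
#'   paths.
#' @export
run_experiment <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  t0 <- Sys.time()
  say <- function(stage, ...) if (isTRUE(config$verbose))
    message(sprintf("[%s seed=%d] ", stage, config$seed), ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  stage <- "simulate"
  out <- tryCatch({
    say(stage, "simulating study")
    trials <- simulate_study(.cfg_design(config), .cfg_model(config),
                             subject_concentration =
                               config$subject_concentration,
                             asymmetry_sd = config$asymmetry_sd,
                             trial_concentration = config$trial_concentration)
    write_trials(trials, path("trials.csv"))

    stage <- "threshold"
    say(stage, "bimanual exceedance-count analysis")
    pairs <- build_pairs(trials)
    thr <- threshold_report(pairs, threshold = config$threshold_pp)
    pairs_out <- pairs
    pairs_out$count_exceeding <- pair_counts(pairs, config$threshold_pp)
    utils::write.csv(pairs_out, path("pairs.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(thr$roc$points, path("cutoff_roc.csv"),
                     row.names = FALSE, quote = FALSE)
    gc_tab <- group_area_comparison(trials)
    utils::write.csv(gc_tab, path("group_area_comparison.csv"),
                     row.names = FALSE, quote = FALSE)

    stage <- "ml"
    say(stage, "training ", config$algorithms)
    feats <- build_features(trials, include_thumb = config$include_thumb)
    split <- split_data(feats, train_fraction = config$train_fraction,
                        group_by_subject = config$group_by_subject,
                        seed = config$seed)
    algos <- .cfg_algos(config)
    reports <- list()
    fits <- list()
    for (a in algos) {
      say(stage, "  ", a)
      fit <- train_model(split$train, a, cv_folds = config$cv_folds,
                         seed = config$seed)
      rep <- evaluate_model(fit, split$validation)
      rep$method_label <- .method_display[[a]]
      fits[[a]] <- fit
      reports[[a]] <- rep
    }
    ml_rows <- do.call(rbind, lapply(reports, function(r)
      data.frame(method = r$method_label, sensitivity = r$sensitivity,
                 specificity = r$specificity, accuracy = r$accuracy,
                 accuracy_ci_lo = r$accuracy_ci[1],
                 accuracy_ci_hi = r$accuracy_ci[2], auc = r$auc,
                 auc_ci_lo = r$auc_ci[1], auc_ci_hi = r$auc_ci[2],
                 n_validation = r$n_pos + r$n_neg,
                 split_mode = if (split$grouped) "grouped_by_subject"
                              else "record_stratified")))
    utils::write.csv(ml_rows, path("ml_metrics.csv"), row.names = FALSE,
                     quote = FALSE)

    stage <- "compare"
    tab <- comparison_table(c(reports, list(thr$report)))
    write_comparison(tab, path("comparison.csv"), path("comparison.txt"))
    if (isTRUE(config$write_figures)) {
      grDevices::pdf(path("roc.pdf"), width = 5, height = 5)
      plot(thr$roc)
      grDevices::dev.off()
    }
    manifest <- list(config = unclass(config), seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("manugrip")),
                     r_version = as.character(getRversion()),
                     wall_clock_s =
                       as.numeric(difftime(Sys.time(), t0, units = "secs")),
                     split_mode = if (split$grouped) "grouped_by_subject"
                                  else "record_stratified",
                     encodings = list(sex = "female=0, male=1",
                                      handedness = "right=0, left=1"))
    jsonlite::write_json(manifest, path("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(trials = trials, pairs = pairs, threshold = thr,
         reports = reports, fits = fits, comparison = tab,
         out_dir = config$out_dir)
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  say("done", sprintf("outputs in %s", config$out_dir))
  invisible(out)
}
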