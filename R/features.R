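#' Build the per-record feature matrix for classification
#'
#' Constructs, from each trial record, the feature set used by the ML
#' harness: age, sex, handedness, total grip force, the percent load of the
#' index, middle, ring and little fingers and of the hypothenar and thenar,
#' the sample variance of the seven area percents, and the natural logarithm
#' of the summed area loads (i.e. of the total contact load). Grip force is
#' log-transformed because grip data are right-skewed. The thumb's percent
#' load is available behind `include_thumb` and is off by default; which
#' additional feature, if any, completes the canonical set is ambiguous and
#' is discussed in the package vignette. Feature construction never inspects
#' the effort label.
#'
#' Encodings: `sex` female = 0, male = 1; `handedness` right = 0, left = 1.
#'
#' @param records Trials `data.frame` (see [read_trials()]).
#' @param include_thumb Include `pct_I` as a feature (default `FALSE`).
#' @param log_base Base of the logarithm for `log_load_sum` (default
#'   `exp(1)`).
#' @return A `data.frame` of numeric features plus a `label` column
#'   (`"submaximal"` / `"maximal"` / `"unknown"`) and `subject_id` carried
#'   through for grouped splitting; neither is a feature.
#' @export
build_features <- function(records, include_thumb = FALSE,
                           log_base = exp(1)) {
  records <- validate_trials(records)
  if (any(records$total_force <= 0))
    stop("total_force must be positive to build features")
  pm <- as.matrix(records[paste0("pct_", hand_areas())])
  out <- data.frame(
    age = as.numeric(records$age),
    sex = as.numeric(records$sex == "male"),
    handedness = as.numeric(records$handedness == "left"),
    total_force = records$total_force,
    pct_II = records$pct_II, pct_III = records$pct_III,
    pct_IV = records$pct_IV, pct_V = records$pct_V,
    pct_HY = records$pct_HY, pct_TH = records$pct_TH,
    load_variance = apply(pm, 1, stats::var),
    log_load_sum = log(records$total_force, base = log_base))
  if (include_thumb) out$pct_I <- records$pct_I
  out$label <- records$effort
  out$subject_id <- records$subject_id
  out
}

#' Names of the feature columns in a [build_features()] frame
#' @param features Output of [build_features()].
#' @return Character vector of feature column names.
#' @export
feature_names <- function(features) {
  setdiff(names(features), c("label", "subject_id"))
}

#' Stratified (optionally subject-grouped) train/validation split
#'
#' Splits records into disjoint, exhaustive training and validation parts.
#' The default split is record-level and stratified by effort label, so both
#' parts have class proportions within one record of the stratified ideal;
#' this mirrors common practice but allows the same subject in both parts
#' (subject leakage), which inflates apparent performance. With
#' `group_by_subject = TRUE`, whole subjects are assigned to one part and
#' the subject sets are disjoint. Deterministic given `seed`.
#'
#' @param features Output of [build_features()] (any data frame with
#'   `label`, and `subject_id` when grouping).
#' @param train_fraction Fraction of records for training (default 0.8).
#' @param group_by_subject Keep each subject wholly in one part (default
#'   `FALSE`).
#' @param seed Integer seed.
#' @return List with elements `train`, `validation` (row subsets) and
#'   `grouped` (flag naming the mode used).
#' @export
split_data <- function(features, train_fraction = 0.8,
                       group_by_subject = FALSE, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  lab <- features$label
  if (length(unique(lab)) < 2)
    stop("split_data needs records of both classes")
  if (min(table(lab)) < 2)
    stop("need at least 2 records per class")
  set.seed(seed)
  if (group_by_subject) {
    subs <- unique(features$subject_id)
    n_train <- max(1, round(train_fraction * length(subs)))
    if (n_train >= length(subs)) n_train <- length(subs) - 1
    train_subs <- sample(subs, n_train)
    idx <- features$subject_id %in% train_subs
  } else {
    idx <- rep(FALSE, nrow(features))
    for (cl in unique(lab)) {
      rows <- which(lab == cl)
      k <- round(train_fraction * length(rows))
      k <- min(max(k, 1), length(rows) - 1)
      idx[sample(rows, k)] <- TRUE
    }
  }
  train <- features[idx, , drop = FALSE]
  validation <- features[!idx, , drop = FALSE]
  if (length(unique(train$label)) < 2 ||
      length(unique(validation$label)) < 2)
    stop("split left a part with a single class; adjust train_fraction")
  list(train = train, validation = validation, grouped = group_by_subject)
}
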