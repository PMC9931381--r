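# Internal: coerce a truth vector to logical "is positive"
# (positive class = submaximal / insincere effort, everywhere).
.is_positive <- function(truth) {
  if (is.logical(truth)) return(truth)
  if (is.numeric(truth)) {
    stopifnot(all(truth %in% c(0, 1)))
    return(truth == 1)
  }
  pos_labels <- c("submaximal", "insincere", "positive", "1", "TRUE")
  neg_labels <- c("maximal", "sincere", "negative", "0", "FALSE")
  truth <- as.character(truth)
  if (!all(truth %in% c(pos_labels, neg_labels)))
    stop("labels must be binary; unrecognized: ",
         paste(setdiff(unique(truth), c(pos_labels, neg_labels)),
               collapse = ", "))
  truth %in% pos_labels
}

#' Confusion matrix for binary effort classification
#'
#' The positive class is submaximal/insincere effort: sensitivity always
#' means the probability of detecting a submaximal record.
#'
#' @param truth,predicted Equal-length binary label vectors. Accepted
#'   labels: `maximal`/`submaximal`, `sincere`/`insincere`, logical, or 0/1.
#' @return An object of class `confusion_matrix`: list with counts
#'   `tp, fn, tn, fp`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 1)
    stop("truth and predicted must have equal positive length")
  t <- .is_positive(truth); p <- .is_positive(predicted)
  structure(list(tp = sum(t & p), fn = sum(t & !p),
                 tn = sum(!t & !p), fp = sum(!t & p)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              truth = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)` via beta quantiles; `lo = 0` when `k = 0`
#'   and `hi = 1` when `k = n`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n, level > 0, level < 1)
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo, hi)
}

#' ROC curve from continuous scores
#'
#' Builds the empirical ROC, one operating point per distinct score value
#' (ties grouped into a single threshold step), with endpoints (0,0) and
#' (1,1), and the trapezoidal AUC. Higher scores indicate the positive
#' (submaximal) class. The trapezoidal AUC equals the Mann-Whitney
#' probability that a random positive outscores a random negative, ties
#' counted one half.
#'
#' @param scores Finite numeric scores.
#' @param truth Binary labels (see [confusion()]); both classes required.
#' @return An object of class `roc_curve`: `thresholds`, `points` (data
#'   frame `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_from_scores <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  pos <- .is_positive(truth)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC requires both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) mean(scores[pos] >= th), numeric(1))
  fpr <- vapply(thr, function(th) mean(scores[!pos] >= th), numeric(1))
  x <- c(0, fpr, 1); y <- c(0, tpr, 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(thresholds = thr,
                 points = data.frame(fpr = x, tpr = y),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC %.4f (%d pos / %d neg)\n",
              length(x$thresholds), x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the empirical AUC via DeLong's placement-value
#' estimator: for each positive its mean win-rate over the negatives (and
#' vice versa, ties counted one half); the AUC variance is the sum of the
#' two placement-value sample variances divided by their class sizes. The
#' normal-approximation interval is clipped to [0, 1]. With perfectly
#' separated scores the variance is exactly zero and the interval collapses
#' onto the AUC; the result is then flagged degenerate.
#'
#' @param scores Finite numeric scores (higher = positive class).
#' @param truth Binary labels; at least 2 per class.
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `lo`, `hi`, `variance`, `degenerate`.
#' @export
delong_ci <- function(scores, truth, level = 0.95) {
  pos <- .is_positive(truth)
  x <- scores[pos]; y <- scores[!pos]
  m <- length(x); n <- length(y)
  if (m < 2 || n < 2) stop("DeLong CI needs at least 2 scores per class")
  stopifnot(all(is.finite(scores)), level > 0, level < 1)
  # placement values via pairwise comparison (fixtures here are small)
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)   # one per positive
  v01 <- colMeans(cmp)   # one per negative
  auc <- mean(cmp)
  variance <- stats::var(v10) / m + stats::var(v01) / n
  degenerate <- variance <= 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(max(variance, 0))
  list(auc = auc, lo = max(0, auc - half), hi = min(1, auc + half),
       variance = variance, degenerate = degenerate)
}

#' Diagnostic performance report
#'
#' Bundles the confusion-matrix rates with their intervals: sensitivity,
#' specificity, accuracy with an exact (Clopper-Pearson) 95% binomial
#' interval, and the AUC with its DeLong interval — the machine-readable
#' form of a sensitivity/specificity comparison table.
#'
#' @param truth Binary truth labels.
#' @param scores Continuous scores aligned with `truth` (higher =
#'   submaximal); used for the ROC/AUC.
#' @param predicted Hard labels aligned with `truth`; if missing, scores are
#'   thresholded at `score_threshold`.
#' @param score_threshold Threshold for deriving hard labels from scores
#'   when `predicted` is missing (default 0.5, for probability scores).
#' @param method_label Free-text name of the method being evaluated.
#' @param level Confidence level (default 0.95).
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(truth, scores, predicted = NULL,
                           score_threshold = 0.5, method_label = "method",
                           level = 0.95) {
  pos <- .is_positive(truth)
  if (sum(pos) == 0 || sum(!pos) == 0)
    stop("metrics need both classes in the truth labels")
  if (is.null(predicted)) predicted <- scores > score_threshold
  cm <- confusion(truth, predicted)
  n <- cm$tp + cm$fn + cm$tn + cm$fp
  acc_k <- cm$tp + cm$tn
  roc <- roc_from_scores(scores, truth)
  dl <- delong_ci(scores, truth, level)
  structure(list(method_label = method_label,
                 confusion = cm,
                 sensitivity = cm$tp / (cm$tp + cm$fn),
                 specificity = cm$tn / (cm$tn + cm$fp),
                 accuracy = acc_k / n,
                 accuracy_ci = clopper_pearson(acc_k, n, level),
                 auc = roc$auc, auc_ci = c(dl$lo, dl$hi),
                 auc_ci_degenerate = dl$degenerate,
                 roc = roc, level = level,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Method: %s  (n = %d positive / %d negative)\n",
              x$method_label, x$n_pos, x$n_neg))
  cat(sprintf("  Sensitivity     %.4f\n", x$sensitivity))
  cat(sprintf("  Specificity     %.4f\n", x$specificity))
  cat(sprintf("  Accuracy        %.4f  (%d%% CI %.4f-%.4f, Clopper-Pearson)\n",
              x$accuracy, round(100 * x$level),
              x$accuracy_ci[1], x$accuracy_ci[2]))
  cat(sprintf("  AUC             %.4f  (%d%% CI %.4f-%.4f, DeLong%s)\n",
              x$auc, round(100 * x$level), x$auc_ci[1], x$auc_ci[2],
              if (x$auc_ci_degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Side-by-side comparison table of several methods
#'
#' Lays out one column per method and the rows Sensitivity / Specificity /
#' Accuracy / (95% CI) / AUC / (95% CI deLong), proportions formatted to 4
#' decimals.
#'
#' @param reports List of [metrics_report()] objects.
#' @return A character `data.frame` with `metric` plus one column per
#'   method.
#' @export
comparison_table <- function(reports) {
  stopifnot(length(reports) >= 1)
  fmt <- function(v) sprintf("%.4f", v)
  cols <- lapply(reports, function(r) c(
    fmt(r$sensitivity), fmt(r$specificity), fmt(r$accuracy),
    sprintf("(%.4f, %.4f)", r$accuracy_ci[1], r$accuracy_ci[2]),
    fmt(r$auc),
    sprintf("(%.4f, %.4f)", r$auc_ci[1], r$auc_ci[2])))
  out <- data.frame(metric = c("Sensitivity", "Specificity", "Accuracy",
                               "(95% CI)", "AUC", "(95% CI deLong)"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(reports))
    out[[reports[[i]]$method_label]] <- cols[[i]]
  out
}

#' Write a comparison table as CSV and aligned text
#'
#' @param table Output of [comparison_table()].
#' @param csv_path,txt_path Output paths (either may be `NULL` to skip).
#' @return `invisible(table)`.
#' @export
write_comparison <- function(table, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(table, csv_path, row.names = FALSE, quote = TRUE)
  if (!is.null(txt_path)) {
    widths <- vapply(names(table), function(nm)
      max(nchar(c(nm, table[[nm]]))), numeric(1))
    lines <- vapply(seq_len(nrow(table) + 1), function(i) {
      vals <- if (i == 1) names(table) else
        vapply(table[i - 1, ], as.character, character(1))
      paste(mapply(formatC, vals, width = widths, flag = "-"),
            collapse = "  ")
    }, character(1))
    writeLines(lines, txt_path)
  }
  invisible(table)
}
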