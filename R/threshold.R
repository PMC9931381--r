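#' Bimanual difference profile of a hand pair
#'
#' Computes the absolute percentage-point difference of each corresponding
#' anatomical area between the two hands of a pair, and the number of areas
#' whose difference strictly exceeds the significance threshold. The
#' conventional analysis considers bimanual differences of more than 3
#' percentage points significant, because physiological performance
#' differences between a subject's hands rarely exceed that.
#'
#' @param left,right [area_loads()] objects (or named length-7 percent
#'   vectors) for the two hands.
#' @param threshold Significance threshold in percentage points (default 3).
#'   Exceedance is strict (`> threshold`); ties at the threshold do not
#'   count.
#' @return An object of class `diff_profile`: list with `diff` (named
#'   absolute differences), `exceeding` (logical per area),
#'   `count_exceeding` and `threshold`.
#' @export
#' @examples
#' d <- diff_profile(c(I = 24, II = 17, III = 15, IV = 19, V = 15,
#'                     TH = 6.5, HY = 3.5),
#'                   c(I = 20, II = 12, III = 16, IV = 13, V = 8,
#'                     TH = 10, HY = 20.5))
#' d$count_exceeding
diff_profile <- function(left, right, threshold = 3.0) {
  stopifnot(threshold > 0)
  pl <- if (inherits(left, "area_loads")) left$percent else left[hand_areas()]
  pr <- if (inherits(right, "area_loads")) right$percent else
    right[hand_areas()]
  stopifnot(length(pl) == 7, length(pr) == 7)
  d <- abs(as.numeric(pl) - as.numeric(pr))
  names(d) <- hand_areas()
  exceeding <- d > threshold
  structure(list(diff = d, exceeding = exceeding,
                 count_exceeding = sum(exceeding), threshold = threshold),
            class = "diff_profile")
}

#' @export
print.diff_profile <- function(x, ...) {
  cat(sprintf("Bimanual area differences (threshold %.1f pp): %d of 7 exceed\n",
              x$threshold, x$count_exceeding))
  print(round(x$diff, 2))
  invisible(x)
}

#' Classify a hand pair from its exceedance count
#'
#' The conventional rule labels a pair insincere when at least `cutoff` of
#' the seven corresponding areas differ by more than the threshold.
#'
#' @param profile A [diff_profile()] (or a bare exceedance count).
#' @param cutoff Integer operating point in 0..8. Cutoff 0 labels everything
#'   insincere; cutoff 8 labels nothing insincere.
#' @return `"insincere"` or `"sincere"`.
#' @export
classify_pair <- function(profile, cutoff) {
  stopifnot(length(cutoff) == 1, cutoff >= 0, cutoff <= 8)
  count <- if (inherits(profile, "diff_profile")) profile$count_exceeding
           else profile
  if (count >= cutoff) "insincere" else "sincere"
}

#' Build labelled hand pairs from trial records
#'
#' Constructs the pairs the conventional bimanual comparison operates on.
#' Insincere (positive) pairs take, within a subject, session and trial
#' index, the maximal-effort hand versus the submaximal-effort hand.
#' Sincere (negative) pairs take, within a subject and trial index, the
#' maximal-effort hand of session 1 versus the maximal-effort hand of
#' session 2 — both sincere, opposite hands. This negative-class
#' construction is a package decision: the study this package models never
#' states how its sincere pairs were formed, so its reported specificity is
#' not reconstructable by design and the pairing here should be treated as
#' one reasonable choice, not a ground truth.
#'
#' @param records Trials `data.frame` (see [read_trials()]), with known
#'   effort labels.
#' @return A `data.frame` with one row per pair: `pair_id`, `truth`
#'   (`"insincere"`/`"sincere"`), the two hands' percent columns prefixed
#'   `left_` / `right_`, per-area absolute differences `d_*`, and subject /
#'   trial bookkeeping.
#' @export
build_pairs <- function(records) {
  stopifnot(all(c("subject_id", "session", "trial", "hand", "effort")
                %in% names(records)))
  pct_cols <- paste0("pct_", hand_areas())
  pairs <- list()
  k <- 0L
  one_row <- function(sub, tr, truth, row_l, row_r, tag) {
    p_l <- as.numeric(row_l[pct_cols]); p_r <- as.numeric(row_r[pct_cols])
    d <- abs(p_l - p_r)
    out <- data.frame(pair_id = tag, subject_id = sub, trial = tr,
                      truth = truth, stringsAsFactors = FALSE)
    out[paste0("left_", hand_areas())] <- as.list(p_l)
    out[paste0("right_", hand_areas())] <- as.list(p_r)
    out[paste0("d_", hand_areas())] <- as.list(d)
    out
  }
  for (sub in unique(records$subject_id)) {
    rs <- records[records$subject_id == sub, ]
    # insincere pairs: within session and trial, maximal vs submaximal hand
    for (s in sort(unique(rs$session))) {
      for (t in sort(unique(rs$trial[rs$session == s]))) {
        st <- rs[rs$session == s & rs$trial == t, ]
        mx <- st[st$effort == "maximal", ]
        sx <- st[st$effort == "submaximal", ]
        if (nrow(mx) == 1 && nrow(sx) == 1) {
          row_l <- if (mx$hand == "left") mx else sx
          row_r <- if (mx$hand == "left") sx else mx
          k <- k + 1L
          pairs[[k]] <- one_row(sub, t, "insincere", row_l, row_r,
                                sprintf("%s_s%d_t%d_ins", sub, s, t))
        }
      }
    }
    # sincere pairs: maximal hand of session 1 vs maximal hand of session 2
    sess <- sort(unique(rs$session))
    if (length(sess) >= 2) {
      for (t in sort(unique(rs$trial))) {
        m1 <- rs[rs$session == sess[1] & rs$trial == t &
                   rs$effort == "maximal", ]
        m2 <- rs[rs$session == sess[2] & rs$trial == t &
                   rs$effort == "maximal", ]
        if (nrow(m1) == 1 && nrow(m2) == 1 && m1$hand != m2$hand) {
          row_l <- if (m1$hand == "left") m1 else m2
          row_r <- if (m1$hand == "left") m2 else m1
          k <- k + 1L
          pairs[[k]] <- one_row(sub, t, "sincere", row_l, row_r,
                                sprintf("%s_t%d_sin", sub, t))
        }
      }
    }
  }
  if (k == 0L) stop("no pairable records found")
  out <- do.call(rbind, pairs)
  if (!any(out$truth == "sincere"))
    warning("no sincere pairs could be formed (need maximal efforts in two sessions)")
  rownames(out) <- NULL
  out
}

#' Exceedance counts for a pairs table
#'
#' @param pairs Output of [build_pairs()].
#' @param threshold Significance threshold in percentage points (default 3).
#' @return Integer vector of per-pair exceedance counts (0-7).
#' @export
pair_counts <- function(pairs, threshold = 3.0) {
  d <- as.matrix(pairs[paste0("d_", hand_areas())])
  as.integer(rowSums(d > threshold))
}

#' ROC over the integer exceedance-count cutoff
#'
#' Evaluates the conventional classifier at every cutoff `c` in 0..8
#' ("insincere iff at least `c` areas differ by more than the threshold"),
#' computing sensitivity and specificity against the pairs' truth labels,
#' the trapezoidal AUC over the resulting operating points (including
#' endpoints (0,0) and (1,1)), and the Youden-optimal cutoff. Ties in
#' Youden's J are broken toward the higher cutoff, i.e. toward higher
#' specificity: misclassifying a sincere subject as insincere is the more
#' harmful error in this application.
#'
#' @param pairs Output of [build_pairs()] with known truth labels.
#' @param threshold Significance threshold in percentage points (default 3).
#' @return An object of class `cutoff_roc`: list with `points` (data frame
#'   of cutoff, sensitivity, specificity), `auc`, `chosen_cutoff`,
#'   `chosen_sensitivity`, `chosen_specificity`, `n_pos`, `n_neg`.
#' @export
cutoff_roc <- function(pairs, threshold = 3.0) {
  counts <- pair_counts(pairs, threshold)
  truth <- pairs$truth
  n_pos <- sum(truth == "insincere")
  n_neg <- sum(truth == "sincere")
  if (n_pos == 0 || n_neg == 0)
    stop("cutoff_roc needs at least one sincere and one insincere pair")
  cutoffs <- 0:8
  sens <- vapply(cutoffs, function(co)
    mean(counts[truth == "insincere"] >= co), numeric(1))
  spec <- vapply(cutoffs, function(co)
    mean(counts[truth == "sincere"] < co), numeric(1))
  pts <- data.frame(cutoff = cutoffs, sensitivity = sens, specificity = spec)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  x <- c(0, fpr[ord], 1)
  y <- c(0, sens[ord], 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  j <- sens + spec - 1
  best <- max(which(j == max(j)))  # ties -> higher cutoff -> higher specificity
  structure(list(points = pts, auc = auc,
                 chosen_cutoff = cutoffs[best],
                 chosen_sensitivity = sens[best],
                 chosen_specificity = spec[best],
                 threshold = threshold, n_pos = n_pos, n_neg = n_neg,
                 counts = counts, truth = truth),
            class = "cutoff_roc")
}

#' @export
print.cutoff_roc <- function(x, ...) {
  cat(sprintf("Exceedance-count ROC (>%g pp rule) on %d insincere / %d sincere pairs\n",
              x$threshold, x$n_pos, x$n_neg))
  cat(sprintf("AUC %.4f; chosen cutoff %d areas (sens %.4f, spec %.4f)\n",
              x$auc, x$chosen_cutoff, x$chosen_sensitivity,
              x$chosen_specificity))
  invisible(x)
}

#' @export
summary.cutoff_roc <- function(object, ...) {
  print(object)
  cat("\nOperating points:\n")
  print(object$points, row.names = FALSE)
  invisible(object$points)
}

#' @export
plot.cutoff_roc <- function(x, ...) {
  fpr <- 1 - x$points$specificity
  ord <- order(fpr, x$points$sensitivity)
  graphics::plot(c(0, fpr[ord], 1), c(0, x$points$sensitivity[ord], 1),
                 type = "b", xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("Cutoff ROC (AUC %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Predict sincerity for new pairs at the chosen cutoff
#'
#' @param object A [cutoff_roc()] fit.
#' @param newdata A pairs data frame (see [build_pairs()]).
#' @param cutoff Operating point; defaults to the fit's Youden-optimal one.
#' @param ... Unused.
#' @return Character vector of `"insincere"` / `"sincere"`.
#' @export
predict.cutoff_roc <- function(object, newdata,
                               cutoff = object$chosen_cutoff, ...) {
  counts <- pair_counts(newdata, object$threshold)
  ifelse(counts >= cutoff, "insincere", "sincere")
}

#' Group-level paired area-to-area comparison
#'
#' For each anatomical area, compares the percent contribution under maximal
#' effort with the corresponding area of the opposite hand under submaximal
#' effort, paired within subject, session and trial: mean difference
#' (maximal minus submaximal), minimum, maximum, standard deviation, and a
#' two-sided paired Wilcoxon signed-rank p-value.
#'
#' @param max_records,submax_records Trials data frames containing only
#'   maximal / submaximal records; rows are paired by subject, session and
#'   trial. Alternatively pass the full study to `max_records` and leave
#'   `submax_records` `NULL`.
#' @return A `data.frame` with one row per area: `area, mean_diff, min_diff,
#'   max_diff, sd_diff, p_value, n`.
#' @export
group_area_comparison <- function(max_records, submax_records = NULL) {
  if (is.null(submax_records)) {
    all <- max_records
    max_records <- all[all$effort == "maximal", ]
    submax_records <- all[all$effort == "submaximal", ]
  }
  key <- function(df) paste(df$subject_id, df$session, df$trial, sep = "|")
  km <- key(max_records); ks <- key(submax_records)
  common <- intersect(km, ks)
  if (length(common) < 2)
    stop("need at least 2 paired maximal/submaximal trials")
  mx <- max_records[match(common, km), ]
  sx <- submax_records[match(common, ks), ]
  out <- lapply(hand_areas(), function(a) {
    d <- mx[[paste0("pct_", a)]] - sx[[paste0("pct_", a)]]
    p <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
    data.frame(area = a, mean_diff = mean(d), min_diff = min(d),
               max_diff = max(d), sd_diff = stats::sd(d), p_value = p,
               n = length(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
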