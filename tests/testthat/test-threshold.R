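test_that("diff_profile: identity, a worked five-area case, strict exceedance", {
  p <- random_percent()
  d0 <- diff_profile(p, p)
  expect_equal(unname(d0$diff), rep(0, 7))
  expect_equal(d0$count_exceeding, 0)

  # five of seven corresponding areas exceed 3 points: the set
  # {I, II, IV, V, TH}, with III and HY inside the physiological band
  left <- c(I = 20, II = 12, III = 16, IV = 13, V = 8, TH = 16, HY = 15)
  right <- c(I = 16, II = 7, III = 18.5, IV = 19, V = 1, TH = 21, HY = 17.5)
  d <- diff_profile(left, right)
  expect_equal(unname(d$diff), c(4, 5, 2.5, 6, 7, 5, 2.5))
  expect_equal(d$count_exceeding, 5)
  expect_setequal(names(which(d$exceeding)), c("I", "II", "IV", "V", "TH"))

  # ties at exactly the threshold do not count
  l2 <- c(I = 23, II = 12, III = 16, IV = 13, V = 8, TH = 16, HY = 12)
  r2 <- c(I = 20, II = 12, III = 16, IV = 13, V = 8, TH = 16, HY = 15)
  expect_equal(diff_profile(l2, r2)$count_exceeding, 0)
  expect_equal(diff_profile(l2, r2, threshold = 2.9)$count_exceeding, 2)
})

test_that("diff_profile is symmetric and matches a brute-force tally", {
  set.seed(19)
  for (rep in 1:20) {
    a <- random_percent(); b <- random_percent()
    d <- diff_profile(a, b)
    expect_equal(d$diff, diff_profile(b, a)$diff)
    tally <- sum(vapply(hand_areas(), function(ar)
      abs(a[[ar]] - b[[ar]]) > 3, logical(1)))
    expect_equal(d$count_exceeding, tally)
  }
})

test_that("classify_pair agrees with exhaustive enumeration over patterns and cutoffs", {
  expect_equal(classify_pair(5, 4), "insincere")
  expect_equal(classify_pair(0, 0), "insincere")  # degenerate all-positive rule
  expect_equal(classify_pair(7, 8), "sincere")    # cutoff 8 labels nothing
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  for (i in seq_len(nrow(patterns))) {
    count <- sum(unlist(patterns[i, ]))
    for (cutoff in 0:8) {
      expect_identical(classify_pair(count, cutoff),
                       if (count >= cutoff) "insincere" else "sincere")
    }
  }
})

test_that("classify_pair is monotone in any single area difference", {
  set.seed(23)
  a <- random_percent(); b <- random_percent()
  for (cutoff in 0:8) {
    base <- classify_pair(diff_profile(a, b)$count_exceeding, cutoff)
    for (ar in hand_areas()) {
      b2 <- b
      b2[[ar]] <- b2[[ar]] + 10  # widen one difference
      grown <- classify_pair(diff_profile(a, b2)$count_exceeding, cutoff)
      expect_false(base == "insincere" && grown == "sincere")
    }
  }
})

test_that("build_pairs yields the designed pair counts and one hand per side", {
  trials <- simulate_study(study_design(seed = 9))
  pairs <- build_pairs(trials)
  expect_equal(sum(pairs$truth == "insincere"), 324)  # 54 x 2 x 3
  expect_equal(sum(pairs$truth == "sincere"), 162)    # 54 x 3
  # columns left_* and right_* each hold a full composition
  lm <- as.matrix(pairs[paste0("left_", hand_areas())])
  rm <- as.matrix(pairs[paste0("right_", hand_areas())])
  expect_equal(unname(rowSums(lm)), rep(100, nrow(pairs)), tolerance = 1e-9)
  expect_equal(unname(rowSums(rm)), rep(100, nrow(pairs)), tolerance = 1e-9)
})

test_that("build_pairs warns when no sincere pairs can be formed", {
  trials <- simulate_study(study_design(n_subjects = 1, n_males = 0,
                                        n_right_handed = 1, sessions = 1,
                                        seed = 2))
  expect_warning(pairs <- build_pairs(trials), "no sincere pairs")
  expect_equal(unique(pairs$truth), "insincere")
})

test_that("cutoff_roc: perfect separation, null labels, and the U-statistic", {
  mk_pairs <- function(counts, truth) {
    # minimal synthetic pairs table with the stated exceedance counts:
    # put `count` areas at a 10-point difference, the rest at 0
    rows <- lapply(seq_along(counts), function(i) {
      d <- c(rep(10, counts[i]), rep(0, 7 - counts[i]))
      out <- data.frame(pair_id = i, truth = truth[i])
      out[paste0("left_", hand_areas())] <- as.list(rep(100 / 7, 7))
      out[paste0("right_", hand_areas())] <- as.list(rep(100 / 7, 7))
      out[paste0("d_", hand_areas())] <- as.list(d)
      out
    })
    do.call(rbind, rows)
  }
  sep <- mk_pairs(c(rep(7, 10), rep(0, 10)),
                  c(rep("insincere", 10), rep("sincere", 10)))
  expect_equal(cutoff_roc(sep)$auc, 1.0)

  set.seed(37)
  counts <- sample(0:7, 400, replace = TRUE)
  truth <- sample(c("insincere", "sincere"), 400, replace = TRUE)
  if (length(unique(truth)) == 1) truth[1] <- "sincere"
  roc <- cutoff_roc(mk_pairs(counts, truth))
  expect_lt(abs(roc$auc - 0.5), 0.08)

  # AUC equals the Mann-Whitney formulation on small labelled sets
  for (rep in 1:5) {
    n <- 40
    counts <- sample(0:7, n, replace = TRUE)
    truth <- c("insincere", "sincere",
               sample(c("insincere", "sincere"), n - 2, replace = TRUE))
    roc <- cutoff_roc(mk_pairs(counts, truth))
    expect_equal(roc$auc, u_auc(counts, truth == "insincere"),
                 tolerance = 1e-12)
  }
})

test_that("cutoff_roc staircase is monotone with the stated endpoints", {
  trials <- tiny_study(n = 8, seed = 15)
  roc <- cutoff_roc(build_pairs(trials))
  pts <- roc$points
  expect_equal(pts$sensitivity[pts$cutoff == 0], 1)
  expect_equal(pts$specificity[pts$cutoff == 0], 0)
  expect_equal(pts$sensitivity[pts$cutoff == 8], 0)
  expect_equal(pts$specificity[pts$cutoff == 8], 1)
  expect_true(all(diff(pts$sensitivity) <= 1e-12))
  expect_true(all(diff(pts$specificity) >= -1e-12))
})

test_that("Youden ties break toward the higher-specificity cutoff", {
  # counts where cutoffs 1 and 2 give identical J
  mk <- function(counts, truth) {
    rows <- lapply(seq_along(counts), function(i) {
      out <- data.frame(pair_id = i, truth = truth[i])
      out[paste0("d_", hand_areas())] <-
        as.list(c(rep(10, counts[i]), rep(0, 7 - counts[i])))
      out
    })
    do.call(rbind, rows)
  }
  pairs <- mk(c(2, 2, 0, 0), c("insincere", "insincere", "sincere", "sincere"))
  roc <- cutoff_roc(pairs)
  # J = 1 at cutoffs 1 and 2; the tie resolves to cutoff 2
  expect_equal(roc$chosen_cutoff, 2)
  expect_equal(roc$chosen_specificity, 1)
})

test_that("predict.cutoff_roc applies the chosen operating point", {
  trials <- tiny_study(n = 8, seed = 25)
  pairs <- build_pairs(trials)
  roc <- cutoff_roc(pairs)
  pred <- predict(roc, pairs)
  counts <- pair_counts(pairs)
  expect_identical(pred, ifelse(counts >= roc$chosen_cutoff,
                                "insincere", "sincere"))
})

test_that("group_area_comparison: identity, forced shift, and summary stats", {
  trials <- tiny_study(n = 8, seed = 33)
  mx <- trials[trials$effort == "maximal", ]
  # identical paired samples: zero differences everywhere
  sx <- mx
  sx$effort <- "submaximal"
  rep0 <- group_area_comparison(mx, sx)
  expect_equal(rep0$mean_diff, rep(0, 7))

  # constant +5 shift in area I
  sx2 <- sx
  sx2$pct_I <- sx2$pct_I - 5
  rep5 <- group_area_comparison(mx, sx2)
  expect_equal(rep5$mean_diff[rep5$area == "I"], 5)
  expect_lt(rep5$p_value[rep5$area == "I"], 0.05)

  # summary stats match direct computation on the paired differences
  full <- group_area_comparison(trials)
  sxr <- trials[trials$effort == "submaximal", ]
  key <- function(df) paste(df$subject_id, df$session, df$trial)
  d_I <- mx$pct_I[order(key(mx))] - sxr$pct_I[order(key(sxr))]
  row_I <- full[full$area == "I", ]
  expect_equal(row_I$mean_diff, mean(d_I))
  expect_equal(row_I$sd_diff, stats::sd(d_I))
  expect_equal(row_I$min_diff, min(d_I))
  expect_equal(row_I$max_diff, max(d_I))
  # p-value agrees with the paired signed-rank reference
  ref <- suppressWarnings(stats::wilcox.test(
    mx$pct_I[order(key(mx))], sxr$pct_I[order(key(sxr))],
    paired = TRUE, exact = FALSE)$p.value)
  expect_equal(row_I$p_value, ref, tolerance = 1e-9)
})
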