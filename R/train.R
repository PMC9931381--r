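# ---- small gradient-boosting machine (logistic loss, rpart base learners) --
#
# Boosted regression trees on the binomial deviance: each round fits an
# rpart tree to the current pseudo-residuals (y - p) and replaces the leaf
# values with a single Newton step sum(r)/sum(p(1-p)), damped by the
# shrinkage factor. This is the classic two-class gradient boosting recipe.

gbm_fit <- function(x, y01, n_trees = 100, depth = 2, shrinkage = 0.1,
                    minbucket = 10) {
  stopifnot(all(y01 %in% c(0, 1)), n_trees >= 1, depth >= 1)
  p0 <- min(max(mean(y01), 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, length(y01))
  df <- as.data.frame(x)
  trees <- vector("list", n_trees)
  ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0,
                               minbucket = minbucket, xval = 0,
                               maxsurrogate = 0, maxcompete = 0)
  for (t in seq_len(n_trees)) {
    p <- stats::plogis(f)
    df$.r <- y01 - p
    w <- pmax(p * (1 - p), 1e-6)
    tree <- rpart::rpart(.r ~ ., data = df, method = "anova",
                         control = ctrl)
    leaves <- which(tree$frame$var == "<leaf>")
    for (l in leaves) {
      idx <- tree$where == l
      gamma <- sum(df$.r[idx]) / sum(w[idx])
      tree$frame$yval[l] <- max(-4, min(4, gamma))
    }
    step <- predict(tree, df)
    f <- f + shrinkage * step
    trees[[t]] <- tree
  }
  structure(list(f0 = f0, shrinkage = shrinkage, trees = trees),
            class = "manugrip_gbm")
}

#' @export
predict.manugrip_gbm <- function(object, newdata, type = c("prob", "link"),
                                 ...) {
  type <- match.arg(type)
  df <- as.data.frame(newdata)
  f <- rep(object$f0, nrow(df))
  for (tree in object$trees) f <- f + object$shrinkage * predict(tree, df)
  if (type == "link") f else stats::plogis(f)
}

# ---- algorithm registry ----------------------------------------------------

.algo_canon <- function(algorithm) {
  map <- c(rf = "random_forest", random_forest = "random_forest",
           svml = "linear_svm", linear_svm = "linear_svm",
           svm = "linear_svm",
           gbm = "gradient_boosting", gradient_boosting = "gradient_boosting",
           xgb = "extreme_gradient_boosting",
           xgboost = "extreme_gradient_boosting",
           extreme_gradient_boosting = "extreme_gradient_boosting")
  out <- map[tolower(algorithm)]
  if (is.na(out)) stop("unknown algorithm: ", algorithm)
  unname(out)
}

#' Default hyperparameter grids
#'
#' Small, seed-stable grids per algorithm family, searched by mean
#' cross-validated AUC: trees x depth for the boosted families, `mtry` for
#' the random forest, and regularisation cost for the linear-kernel SVM.
#'
#' @param algorithm One of `random_forest`, `linear_svm`,
#'   `gradient_boosting`, `extreme_gradient_boosting` (aliases `rf`,
#'   `svml`, `gbm`, `xgb`).
#' @return A `data.frame`, one row per hyperparameter combination.
#' @export
default_grid <- function(algorithm) {
  switch(.algo_canon(algorithm),
    random_forest = expand.grid(ntree = 300, mtry = c(2, 3, 4)),
    linear_svm = expand.grid(cost = c(0.1, 1, 10)),
    gradient_boosting = expand.grid(n_trees = c(60, 120), depth = c(2, 3),
                                    shrinkage = 0.1),
    extreme_gradient_boosting = expand.grid(nrounds = c(60, 120),
                                            max_depth = c(2, 4), eta = 0.3))
}

# Fit one algorithm with fixed hyperparameters; returns a scoring closure
# bundle. Scores are class-probability estimates where the algorithm
# provides them and signed decision values for the linear SVM (oriented so
# larger = more likely submaximal).
.fit_one <- function(algorithm, x, y01, params, seed) {
  set.seed(seed)
  if (algorithm == "random_forest") {
    yf <- factor(ifelse(y01 == 1, "submaximal", "maximal"),
                 levels = c("maximal", "submaximal"))
    m <- randomForest::randomForest(x, yf, ntree = params$ntree,
                                    mtry = min(params$mtry, ncol(x)))
    list(model = m, score_type = "probability", threshold = 0.5, flip = 1)
  } else if (algorithm == "linear_svm") {
    yf <- factor(ifelse(y01 == 1, "submaximal", "maximal"),
                 levels = c("maximal", "submaximal"))
    m <- e1071::svm(x, yf, kernel = "linear", cost = params$cost,
                    scale = TRUE)
    dv <- as.numeric(attr(predict(m, x, decision.values = TRUE),
                          "decision.values"))
    # orient decision values so larger means submaximal
    flip <- if (mean(dv[y01 == 1]) >= mean(dv[y01 == 0])) 1 else -1
    list(model = m, score_type = "decision_value", threshold = 0,
         flip = flip)
  } else if (algorithm == "gradient_boosting") {
    m <- gbm_fit(x, y01, n_trees = params$n_trees, depth = params$depth,
                 shrinkage = params$shrinkage)
    list(model = m, score_type = "probability", threshold = 0.5, flip = 1)
  } else { # extreme_gradient_boosting
    d <- xgboost::xgb.DMatrix(x, label = y01, nthread = 1)
    m <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                          max_depth = params$max_depth,
                                          eta = params$eta, nthread = 1,
                                          seed = seed),
                            data = d, nrounds = params$nrounds, verbose = 0)
    list(model = m, score_type = "probability", threshold = 0.5, flip = 1)
  }
}

.score_one <- function(algorithm, fitted, x) {
  if (algorithm == "random_forest") {
    predict(fitted$model, x, type = "prob")[, "submaximal"]
  } else if (algorithm == "linear_svm") {
    dv <- as.numeric(attr(predict(fitted$model, x, decision.values = TRUE),
                          "decision.values"))
    fitted$flip * dv
  } else if (algorithm == "gradient_boosting") {
    predict(fitted$model, x, type = "prob")
  } else {
    predict(fitted$model, xgboost::xgb.DMatrix(x, nthread = 1))
  }
}

# stratified fold assignment, deterministic given the RNG state
.make_folds <- function(y01, k) {
  fold <- integer(length(y01))
  for (cl in c(0, 1)) {
    rows <- sample(which(y01 == cl))
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

#' Train one classifier family with cross-validated grid search
#'
#' Runs stratified k-fold cross-validation over a hyperparameter grid,
#' selects the combination with the highest mean out-of-fold AUC, and refits
#' it on all training records. The fitted object exposes a continuous score
#' (larger = more likely submaximal) and a hard label at a documented
#' threshold (0.5 for probability scores, 0 for the SVM's decision values).
#'
#' @param train Training part from [split_data()] (a [build_features()]
#'   frame).
#' @param algorithm One of `random_forest`, `linear_svm`,
#'   `gradient_boosting`, `extreme_gradient_boosting` (aliases `rf`, `svml`,
#'   `gbm`, `xgb`).
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param grid Hyperparameter grid; defaults to [default_grid()].
#' @param seed Integer seed; the whole search is deterministic given it.
#' @return An object of class `effort_fit`.
#' @export
train_model <- function(train, algorithm, cv_folds = 5, grid = NULL,
                        seed = 1L) {
  algorithm <- .algo_canon(algorithm)
  stopifnot(cv_folds >= 2)
  if (is.null(grid)) grid <- default_grid(algorithm)
  stopifnot(nrow(grid) >= 1)
  feats <- feature_names(train)
  x <- as.matrix(train[feats])
  if (any(apply(x, 2, stats::sd) == 0) && algorithm == "linear_svm")
    x <- x[, apply(x, 2, stats::sd) > 0, drop = FALSE]
  y01 <- as.integer(.is_positive(train$label))
  if (length(unique(y01)) < 2) stop("training labels are constant")
  if (ncol(x) == 0 || all(apply(x, 2, stats::sd) == 0))
    stop("degenerate training data: all features constant")
  set.seed(seed)
  fold <- .make_folds(y01, cv_folds)
  cv_auc <- matrix(NA_real_, nrow(grid), cv_folds)
  for (g in seq_len(nrow(grid))) {
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      if (length(unique(y01[tr])) < 2 || length(unique(y01[!tr])) < 2) next
      fit <- .fit_one(algorithm, x[tr, , drop = FALSE], y01[tr],
                      grid[g, , drop = FALSE], seed = seed + 101L * g + f)
      sc <- .score_one(algorithm, fit, x[!tr, , drop = FALSE])
      cv_auc[g, f] <- roc_from_scores(sc, y01[!tr])$auc
    }
  }
  mean_auc <- rowMeans(cv_auc, na.rm = TRUE)
  best <- which.max(mean_auc)
  final <- .fit_one(algorithm, x, y01, grid[best, , drop = FALSE],
                    seed = seed)
  structure(list(algorithm = algorithm,
                 fitted = final,
                 best_params = grid[best, , drop = FALSE],
                 cv_results = data.frame(grid, mean_cv_auc = mean_auc),
                 features = colnames(x), cv_folds = cv_folds, seed = seed,
                 n_train = nrow(x)),
            class = "effort_fit")
}

#' @export
print.effort_fit <- function(x, ...) {
  cat(sprintf("Effort classifier: %s (trained on %d records, %d-fold CV)\n",
              x$algorithm, x$n_train, x$cv_folds))
  cat("Selected hyperparameters:",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "), "\n")
  cat(sprintf("Mean CV AUC at selection: %.4f\n",
              max(x$cv_results$mean_cv_auc)))
  invisible(x)
}

#' @export
summary.effort_fit <- function(object, ...) {
  print(object)
  cat("\nGrid search results:\n")
  print(object$cv_results, row.names = FALSE)
  invisible(object$cv_results)
}

#' Predict effort scores or labels for new records
#'
#' @param object An `effort_fit` from [train_model()].
#' @param newdata A [build_features()] frame (or matrix with the model's
#'   feature columns).
#' @param type `"score"` for the continuous score (larger = more likely
#'   submaximal) or `"label"` for hard `"submaximal"`/`"maximal"` labels at
#'   the model's documented threshold.
#' @param ... Unused.
#' @return Numeric scores or character labels.
#' @export
predict.effort_fit <- function(object, newdata, type = c("score", "label"),
                               ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[object$features])
  sc <- .score_one(object$algorithm, object$fitted, x)
  sc <- as.numeric(sc)
  if (type == "score") sc
  else ifelse(sc > object$fitted$threshold, "submaximal", "maximal")
}

#' Evaluate a fitted classifier on held-out records
#'
#' @param model An `effort_fit`.
#' @param validation Validation part from [split_data()]; must contain both
#'   classes.
#' @return A [metrics_report()] labelled with the algorithm name.
#' @export
evaluate_model <- function(model, validation) {
  if (length(unique(validation$label)) < 2)
    stop("validation set must contain both classes (AUC undefined otherwise)")
  sc <- predict(model, validation, type = "score")
  pred <- predict(model, validation, type = "label")
  metrics_report(validation$label, sc, predicted = pred,
                 method_label = model$algorithm)
}
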