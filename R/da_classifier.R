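# Linear discriminant classification of selected features under stratified
# k-fold cross-validation, reporting the pooled out-of-fold confusion-matrix
# metrics and the ROC of the combined predicted probability.

#' Stratified k-fold assignment
#'
#' Partitions indices into k folds whose class proportions match the global
#' proportions within one member. Deterministic given (labels, k, seed).
#'
#' @param labels binary outcome vector
#' @param k number of folds
#' @param seed RNG seed for the within-class shuffle
#' @return list of k disjoint index vectors covering all observations
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  y <- as_binary_label(labels)
  if (min(table(y)) < k) {
    stop("each class needs at least k members for stratified k-fold",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}

# ridge-regularized pooled-covariance Gaussian discriminant, used when
# MASS::lda cannot be fit (singular pooled covariance with p ~ n)
rlda_fit <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  means <- matrix(unlist(lapply(classes, function(c) {
    colMeans(x[y == c, , drop = FALSE])
  })), nrow = length(classes), byrow = TRUE)
  n <- nrow(x)
  sw <- matrix(0, ncol(x), ncol(x))
  for (ci in seq_along(classes)) {
    xc <- scale(x[y == classes[ci], , drop = FALSE], center = means[ci, ],
                scale = FALSE)
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (n - length(classes))
  sw <- sw + diag(ridge * sum(diag(sw)) / ncol(x) + 1e-12, ncol(x))
  si <- tryCatch(solve(sw), error = function(e) MASS::ginv(sw))
  priors <- as.numeric(table(factor(y, classes)) / n)
  list(classes = classes, means = means, si = si, priors = priors)
}

rlda_posterior <- function(fit, x) {
  x <- as.matrix(x)
  sc <- vapply(seq_along(fit$classes), function(ci) {
    mu <- fit$means[ci, ]
    drop(x %*% (fit$si %*% mu)) - 0.5 * drop(t(mu) %*% fit$si %*% mu) +
      log(fit$priors[ci])
  }, numeric(nrow(x)))
  sc <- sc - apply(sc, 1, max)
  e <- exp(sc)
  e[, 2] / rowSums(e)   # posterior of the positive (second) class
}

#' Fit a linear discriminant on a training table
#'
#' MASS::lda with empirical priors is the engine; when the pooled covariance
#' is singular (small cohorts with many features) a ridge-regularized
#' pooled-covariance Gaussian discriminant is used instead and flagged in
#' the result.
#'
#' @param x data.frame/matrix of features (training rows)
#' @param y binary labels
#' @return an `lda_model`
#' @export
lda_fit <- function(x, y) {
  y <- as_binary_label(y)
  if (min(table(y)) < 2) stop("need at least 2 samples per class", call. = FALSE)
  x <- as.matrix(x)
  fit <- tryCatch(
    suppressWarnings(MASS::lda(x, grouping = factor(y, levels = c(0, 1)))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- rlda_fit(x, y)
    return(structure(list(fit = fit, engine = "ridge"), class = "lda_model"))
  }
  structure(list(fit = fit, engine = "mass"), class = "lda_model")
}

#' Posterior probability of the positive class for new rows
#'
#' @param model an `lda_model` from [lda_fit()]
#' @param x new feature rows
#' @return list with `posterior` (probability of class 1) and `class`
#'   (0/1 at the 0.5 threshold)
#' @export
lda_predict <- function(model, x) {
  x <- as.matrix(x)
  post <- if (model$engine == "mass") {
    as.numeric(stats::predict(model$fit, x)$posterior[, "1"])
  } else {
    rlda_posterior(model$fit, x)
  }
  list(posterior = post, class = as.integer(post >= 0.5))
}

confusion_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  pct <- function(num, den) if (den > 0) 100 * num / den else NaN
  acc <- pct(tp + tn, tp + tn + fp + fn)
  c(sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
    precision = pct(tp, tp + fp), npv = pct(tn, tn + fn),
    error = 100 - acc, accuracy = acc)
}

#' Cross-validated discriminant classification
#'
#' Fits the discriminant on k-1 folds and predicts the held-out fold, for
#' every fold; out-of-fold predictions are pooled into a single confusion
#' matrix (threshold 0.5) from which sensitivity, specificity, precision,
#' negative predictive value, error and accuracy are computed (percent), and
#' into a single ROC of the combined predicted probability with its AUC and
#' DeLong confidence interval. Per-fold metrics are also reported.
#'
#' @param table data.frame with feature columns and a binary label column
#' @param features character vector of feature columns to use
#' @param k folds (default 5)
#' @param seed fold-assignment seed
#' @param label_col outcome column name
#' @return a `classification_report`
#' @export
cross_validate <- function(table, features = setdiff(names(table), label_col),
                           k = 5L, seed = 1L, label_col = "label") {
  y <- as_binary_label(table[[label_col]])
  stopifnot(all(features %in% names(table)))
  folds <- stratified_folds(y, k, seed)
  post <- rep(NA_real_, length(y))
  fold_metrics <- list()
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_along(y), test)
    model <- lda_fit(table[train, features, drop = FALSE], y[train])
    pr <- lda_predict(model, table[test, features, drop = FALSE])
    post[test] <- pr$posterior
    fold_metrics[[f]] <- confusion_metrics(y[test], pr$class)
  }
  pred <- as.integer(post >= 0.5)
  metrics <- confusion_metrics(y, pred)
  roc <- pROC::roc(y, post, quiet = TRUE, direction = "<")
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
  structure(list(
    metrics = metrics,
    auc = as.numeric(pROC::auc(roc)), auc_ci = c(ci[1], ci[3]),
    roc = data.frame(fpr = 1 - roc$specificities, tpr = roc$sensitivities),
    posterior = post, truth = y,
    per_fold = do.call(rbind, fold_metrics),
    k = k, seed = seed, features = features
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d-fold CV on %d features\n",
              x$k, length(x$features)))
  print(round(x$metrics, 2))
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Compare two feature sets under identical folds
#'
#' Runs [cross_validate()] for both sets with the same fold assignment, for
#' selected-versus-all-features contrasts.
#'
#' @param table feature table with labels
#' @param set_a,set_b character vectors of feature columns
#' @inheritParams cross_validate
#' @return list with reports `a` and `b`
#' @export
compare_feature_sets <- function(table, set_a, set_b, k = 5L, seed = 1L,
                                 label_col = "label") {
  list(a = cross_validate(table, set_a, k, seed, label_col),
       b = cross_validate(table, set_b, k, seed, label_col))
}
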