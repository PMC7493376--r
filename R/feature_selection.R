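# Two-step feature reduction and selection against a binary outcome:
#   1. correlation de-duplication: among each group of highly correlated
#      features (|Pearson r| > 0.9) keep the one with the largest
#      |point-biserial| correlation with the outcome, delete the rest,
#      repeating until stable;
#   2. threshold selection: recompute the point-biserial coefficient for the
#      survivors and keep |r_pb| > 0.25, reporting each survivor's ROC AUC
#      with a DeLong 95% confidence interval.
# Absolute correlations are used throughout so anti-correlated duplicates
# are de-duplicated and inversely associated features are selectable.

#' Point-biserial correlation of a feature with a binary outcome
#'
#' Identical to the Pearson correlation of `x` with the 0/1 coding of `y`.
#'
#' @param x numeric vector
#' @param y binary vector (0/1, logical, or 2-level factor)
#' @return correlation in [-1, 1]; NA for a constant feature
#' @export
point_biserial <- function(x, y) {
  y <- as_binary_label(y)
  if (length(unique(y)) < 2) stop("both outcome classes must be present", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  if (stats::sd(x[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

as_binary_label <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  y
}

#' Selection configuration
#'
#' @param corr_threshold pairwise |Pearson r| above which features are
#'   considered duplicates (default 0.9)
#' @param rpb_threshold minimum |point-biserial r| with the outcome for a
#'   feature to be selected (default 0.25)
#' @param ci_level confidence level for the per-feature AUC interval
#' @param max_missing features with a larger fraction of missing values are
#'   dropped before selection
#' @export
selection_config <- function(corr_threshold = 0.9, rpb_threshold = 0.25,
                             ci_level = 0.95, max_missing = 0.2) {
  stopifnot(corr_threshold > 0, corr_threshold < 1,
            rpb_threshold > 0, rpb_threshold < 1)
  list(corr_threshold = corr_threshold, rpb_threshold = rpb_threshold,
       ci_level = ci_level, max_missing = max_missing)
}

# drop unusable columns (too many NAs, zero variance); returns names kept
usable_features <- function(x, cfg) {
  miss <- vapply(x, function(c) mean(!is.finite(c)), numeric(1))
  const <- vapply(x, function(c) stats::sd(c[is.finite(c)]) == 0, logical(1))
  dropped <- names(x)[miss > cfg$max_missing | const]
  list(kept = setdiff(names(x), dropped), dropped = dropped)
}

#' Correlation-matrix de-duplication of a feature table
#'
#' Iterates over features in table (registry) order; for each not-yet-deleted
#' feature, the group of features whose pairwise |Pearson r| with it exceeds
#' the threshold is formed, the member with the largest |point-biserial|
#' versus the outcome is kept (ties go to the earlier column), and the rest
#' are deleted. The sweep repeats until stable, so survivors have pairwise
#' |r| below the threshold.
#'
#' @param table data.frame of features plus a binary label column
#' @param cfg a [selection_config()]
#' @param label_col name of the outcome column
#' @return list with `table` (reduced), `audit` (data.frame of eliminated
#'   features and who displaced them), `dropped` (unusable columns)
#' @export
correlation_dedupe <- function(table, cfg = selection_config(),
                               label_col = "label") {
  y <- as_binary_label(table[[label_col]])
  x <- table[setdiff(names(table), label_col)]
  use <- usable_features(x, cfg)
  x <- x[use$kept]
  rpb <- vapply(x, function(c) abs(point_biserial(c, y)), numeric(1))
  audit <- data.frame(feature = character(0), displaced_by = character(0),
                      abs_r = numeric(0))
  if (ncol(x) >= 2) {
    cm <- abs(stats::cor(as.matrix(x), use = "pairwise.complete.obs"))
    alive <- rep(TRUE, ncol(x))
    repeat {
      changed <- FALSE
      for (i in seq_len(ncol(x))) {
        if (!alive[i]) next
        grp <- which(alive & cm[i, ] > cfg$corr_threshold)
        grp <- union(i, grp)
        if (length(grp) < 2) next
        keep <- grp[which.max(rpb[grp])]   # which.max -> earliest on ties
        kill <- setdiff(grp, keep)
        alive[kill] <- FALSE
        audit <- rbind(audit, data.frame(
          feature = names(x)[kill], displaced_by = names(x)[keep],
          abs_r = cm[keep, kill]))
        changed <- TRUE
      }
      if (!changed) break
    }
    x <- x[alive]
  }
  out <- cbind(x, stats::setNames(data.frame(y), label_col))
  list(table = out, audit = audit, dropped = use$dropped)
}

#' Threshold selection with per-feature AUC
#'
#' Recomputes the point-biserial coefficient for every surviving feature and
#' keeps those with |r_pb| above the threshold; each survivor's univariate
#' ROC AUC and DeLong confidence interval are reported.
#'
#' @param table de-duplicated feature table (from [correlation_dedupe()])
#' @param cfg a [selection_config()]
#' @param label_col outcome column name
#' @return a `selection_result`: list with `selected` (names), `stats`
#'   (data.frame of r_pb, AUC, CI for all candidates), `config`
#' @export
threshold_select <- function(table, cfg = selection_config(),
                             label_col = "label") {
  y <- as_binary_label(table[[label_col]])
  feats <- setdiff(names(table), label_col)
  st <- lapply(feats, function(f) {
    r <- point_biserial(table[[f]], y)
    roc <- pROC::roc(y, table[[f]], quiet = TRUE, direction = "<")
    ci <- suppressWarnings(as.numeric(
      pROC::ci.auc(roc, conf.level = cfg$ci_level, method = "delong")))
    data.frame(feature = f, r_pb = r, auc = as.numeric(pROC::auc(roc)),
               auc_lo = ci[1], auc_hi = ci[3])
  })
  st <- do.call(rbind, st)
  sel <- st$feature[!is.na(st$r_pb) & abs(st$r_pb) > cfg$rpb_threshold]
  if (length(sel) == 0) {
    warning("no feature passes the point-biserial threshold", call. = FALSE)
  }
  structure(list(selected = sel, stats = st, config = cfg),
            class = "selection_result")
}

#' Full two-step selection
#'
#' [correlation_dedupe()] followed by [threshold_select()].
#' @inheritParams correlation_dedupe
#' @return a `selection_result` with the de-duplication `audit` attached
#' @export
select_features <- function(table, cfg = selection_config(),
                            label_col = "label") {
  dd <- correlation_dedupe(table, cfg, label_col)
  res <- threshold_select(dd$table, cfg, label_col)
  res$audit <- dd$audit
  res$dropped <- dd$dropped
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d selected of %d candidates\n",
              length(x$selected), nrow(x$stats)))
  if (length(x$selected) > 0) {
    print(x$stats[x$stats$feature %in% x$selected, ], row.names = FALSE)
  }
  invisible(x)
}
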