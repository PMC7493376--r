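test_that("point-biserial equals Pearson on 0/1 coding", {
  expect_equal(point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1)),
               stats::cor(c(1, 2, 3, 4), c(0, 0, 1, 1)))
  expect_equal(point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1)), 0.8944272,
               tolerance = 1e-6)
  # maximal case: two distinct within-class constants
  expect_equal(abs(point_biserial(c(1, 1, 5, 5), c(0, 0, 1, 1))), 1)
  # equal class means give zero correlation
  expect_equal(point_biserial(c(2, 4, 2, 4), c(0, 0, 1, 1)), 0)
  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(40); y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(point_biserial(x, y), stats::cor(x, y), tolerance = 1e-12)
  }
  expect_error(point_biserial(rnorm(5), rep(1, 5)), "both")
})

test_that("correlation de-duplication keeps the best-correlated group member", {
  set.seed(10)
  n <- 60
  y <- rep(0:1, each = n / 2)
  f1 <- rnorm(n) + 0.9 * y
  f2 <- 2 * f1 + rnorm(n, sd = 0.01)   # near-duplicate, weaker r_pb by noise
  f3 <- rnorm(n)
  tab <- data.frame(f1 = f1, f2 = f2, f3 = f3, label = y)
  # make f1 the better of the pair explicitly
  if (abs(point_biserial(f2, y)) > abs(point_biserial(f1, y))) {
    tab[c("f1", "f2")] <- tab[c("f2", "f1")]
  }
  dd <- correlation_dedupe(tab)
  expect_true("f1" %in% names(dd$table))
  expect_false("f2" %in% names(dd$table))
  expect_true("f3" %in% names(dd$table))
  expect_equal(dd$audit$feature, "f2")

  # uncorrelated features are untouched
  set.seed(11)
  tab2 <- data.frame(matrix(rnorm(60 * 5), 60), label = rep(0:1, 30))
  dd2 <- correlation_dedupe(tab2)
  expect_equal(ncol(dd2$table), 6)
})

test_that("chained correlations resolve to the fixed point of the stated rule", {
  set.seed(12)
  n <- 400
  y <- rep(0:1, each = n / 2)
  z1 <- rnorm(n); z2 <- rnorm(n)
  a <- sqrt(0.92)
  f1 <- a * z1 + sqrt(1 - a^2) * rnorm(n)
  f2 <- z1
  f3 <- a * z1 + sqrt(1 - a^2) * rnorm(n)
  tab <- data.frame(f1 = f1, f2 = f2, f3 = f3, label = y)
  cm <- abs(stats::cor(tab[1:3]))
  # only run the chain scenario if the draw produced one (f1~f2, f2~f3, f1!~f3)
  if (cm[1, 2] > 0.9 && cm[2, 3] > 0.9 && cm[1, 3] <= 0.9) {
    dd <- correlation_dedupe(tab)
    # exhaustive fixed point: first sweep examines f1's group {f1,f2}
    rpb <- sapply(tab[1:3], function(x) abs(point_biserial(x, y)))
    keep12 <- c("f1", "f2")[which.max(rpb[1:2])]
    expect_true(keep12 %in% names(dd$table))
    # survivors decorrelated
    surv <- setdiff(names(dd$table), "label")
    if (length(surv) > 1) {
      cs <- abs(stats::cor(dd$table[surv]))
      expect_true(all(cs[upper.tri(cs)] <= 0.9))
    }
  }
  # idempotence on any table
  dd1 <- correlation_dedupe(tab)
  dd2 <- correlation_dedupe(dd1$table)
  expect_identical(names(dd1$table), names(dd2$table))
})

test_that("threshold selection recovers planted informative features", {
  hits <- 0; recovered_all <- 0
  for (s in 1:10) {
    tab <- make_feature_cohort(n_per_class = 30, n_features = 108,
                               informative = c(5, 40, 90),
                               effect_size = 1.5, seed = s)
    res <- select_features(tab)
    planted <- attr(tab, "informative")
    recovered_all <- recovered_all + all(planted %in% res$selected)
    hits <- hits + sum(planted %in% res$selected)
    # invariant: survivors pass the threshold
    st <- res$stats[res$stats$feature %in% res$selected, ]
    expect_true(all(abs(st$r_pb) > 0.25))
    expect_true(all(st$auc >= 0 & st$auc <= 1))
    expect_true(all(st$auc_lo <= st$auc & st$auc <= st$auc_hi))
  }
  expect_gte(recovered_all / 10, 0.8)
  expect_gte(hits / 30, 0.9)
})

test_that("a perfectly separating feature is selected with AUC 1", {
  tab <- data.frame(good = c(rnorm(20, 0), rnorm(20, 10)),
                    noise = rnorm(40), label = rep(0:1, each = 20))
  res <- select_features(tab)
  expect_true("good" %in% res$selected)
  expect_equal(res$stats$auc[res$stats$feature == "good"], 1)
})

test_that("selection status is sign-invariant and row-order-invariant", {
  tab <- make_feature_cohort(n_per_class = 30, n_features = 20,
                             informative = c(2, 7), effect_size = 1.5,
                             seed = 3)
  res1 <- select_features(tab)
  neg <- tab
  neg[[2]] <- -neg[[2]]
  res2 <- select_features(neg)
  expect_identical(res1$selected, res2$selected)
  perm <- tab[sample(nrow(tab)), ]
  res3 <- select_features(perm)
  expect_identical(res1$selected, res3$selected)
})

test_that("null tables yield survivor counts near the theoretical tail rate", {
  n <- 60
  survivors <- vapply(1:15, function(s) {
    tab <- make_feature_cohort(n_per_class = n / 2, n_features = 40, seed = s)
    res <- suppressWarnings(threshold_select(tab))
    length(res$selected)
  }, numeric(1))
  # P(|r| > 0.25) at n = 60 for a null feature ~ 0.054
  t_stat <- 0.25 * sqrt((n - 2) / (1 - 0.25^2))
  p_tail <- 2 * stats::pt(-t_stat, n - 2)
  expected <- 40 * p_tail
  se <- sqrt(40 * p_tail * (1 - p_tail) / 15)
  expect_lt(abs(mean(survivors) - expected), 4 * se + 0.5)
})
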