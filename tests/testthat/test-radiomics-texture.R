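test_that("quantization bins equal-width with max at top level", {
  vals <- array(NA_real_, c(64, 1, 1))
  vals[, 1, 1] <- 1:64
  vol <- suv_volume(array(1:64, c(64, 1, 1)), c(1, 1, 1))
  mask <- btv_mask(array(TRUE, c(64, 1, 1)), c(1, 1, 1))
  q <- quantize(vol, mask, 64)
  expect_identical(as.vector(q$levels), 1:64)

  cvol <- suv_volume(array(3.7, c(4, 4, 2)), c(1, 1, 1))
  cmask <- btv_mask(array(TRUE, c(4, 4, 2)), c(1, 1, 1))
  expect_true(all(quantize(cvol, cmask)$levels == 1L))

  set.seed(8)
  rv <- array(runif(125, 2, 9), c(5, 5, 5))
  m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
  q2 <- quantize(suv_volume(rv, c(1, 1, 1)), btv_mask(m, c(1, 1, 1)), 64)
  v <- rv[m]; lo <- min(v); hi <- max(v)
  oracle <- pmin(64L, 1L + as.integer(floor((v - lo) / (hi - lo) * 64)))
  expect_identical(q2$levels[m], oracle)
  expect_true(all(is.na(q2$levels[!m])))
})

test_that("co-occurrence features match hand enumeration and brute force", {
  q <- q_fixture(array(c(1L, 1L, 2L, 2L), c(1, 1, 4)), 2)
  f <- cooccurrence_features(q)
  # ordered pairs along the line: (1,1),(1,2),(2,2) each both ways = 6
  expect_equal(unname(f["second_angular_moment"]), 10 / 36, tolerance = 1e-12)
  expect_equal(unname(f["contrast"]), 2 / 6, tolerance = 1e-12)

  qc <- q_fixture(array(1L, c(3, 3, 2)), 1)
  fc <- cooccurrence_features(qc)
  expect_equal(unname(fc[c("second_angular_moment", "entropy", "contrast",
                           "homogeneity")]), c(1, 0, 0, 1))

  for (seed in c(42, 7)) {
    qr <- random_q(c(4, 4, 3), n_levels = 3, seed = seed)
    C <- oracle_glcm(qr)
    P <- C / sum(C)
    o <- haralick_oracle(P)
    f <- cooccurrence_features(qr)
    expect_equal(unname(f), unname(o[c("sam", "contrast", "entropy",
                                       "homogeneity", "dissimilarity",
                                       "idm", "correlation")]),
                 tolerance = 1e-9)
  }

  single <- q_fixture(array(1L, c(1, 1, 1)), 1)
  expect_true(all(is.nan(cooccurrence_features(single))))
})

test_that("normalized co-occurrence uses row-conditional probabilities", {
  qc <- q_fixture(array(1L, c(2, 2, 2)), 1)
  fc <- normalized_cooccurrence_features(qc)
  expect_equal(unname(fc["second_angular_moment"]), 1)
  expect_equal(unname(fc["entropy"]), 0)

  q <- q_fixture(array(c(1L, 1L, 2L, 2L), c(1, 1, 4)), 2)
  C <- oracle_glcm(q)
  Cn <- C / rowSums(C)
  o <- haralick_oracle(Cn / sum(Cn))
  f <- normalized_cooccurrence_features(q)
  expect_equal(unname(f), unname(o[c("sam", "contrast", "entropy",
                                     "homogeneity", "idm", "dissimilarity")]),
               tolerance = 1e-12)

  qr <- random_q(c(4, 3, 3), n_levels = 4, seed = 13)
  expect_gt(normalized_cooccurrence_features(qr)["homogeneity"], 0)
  expect_lte(normalized_cooccurrence_features(qr)["homogeneity"], 1)
})

test_that("run-length features match hand counts and the run-scanner oracle", {
  dz <- matrix(c(0, 0, 1), 1)
  q <- q_fixture(array(c(1L, 1L, 2L, 2L, 2L), c(1, 1, 5)), 2)
  f <- voxel_alignment_features(q, directions = dz)
  expect_equal(unname(f["short_run_emphasis"]), (1 / 4 + 1 / 9) / 2,
               tolerance = 1e-12)

  qn <- q_fixture(array(1L, c(1, 1, 6)), 1)
  fn <- voxel_alignment_features(qn, directions = dz)
  expect_equal(unname(fn["long_run_emphasis"]), 36)
  expect_equal(unname(fn["run_percentage"]), 1 / 6)

  qr <- random_q(c(4, 4, 3), n_levels = 3, seed = 21)
  o <- oracle_run_features(qr, petrad:::offsets13())
  expect_equal(unname(voxel_alignment_features(qr)), o, tolerance = 1e-9)
})

test_that("size-zone features match connected-component oracle", {
  q <- q_fixture(array(c(1L, 1L, 1L, 1L, 2L, 2L), c(1, 1, 6)), 2)
  f <- size_zone_features(q)
  expect_equal(unname(f["zone_percentage"]), 2 / 6, tolerance = 1e-12)

  qc <- q_fixture(array(1L, c(2, 3, 2)), 1)
  expect_equal(unname(size_zone_features(qc)["large_zone_emphasis"]), 144)

  qr <- random_q(c(5, 4, 3), n_levels = 3, seed = 33)
  expect_equal(unname(size_zone_features(qr)), oracle_zone_features(qr),
               tolerance = 1e-9)
})

test_that("neighbourhood intensity-difference features match direct summation", {
  qc <- q_fixture(array(2L, c(3, 3, 3)), 2)
  fc <- nid_features(qc)
  expect_equal(unname(fc["contrast"]), 0)
  expect_equal(unname(fc["busyness"]), 0)
  expect_equal(unname(fc["complexity"]), 0)
  expect_equal(unname(fc["coarseness"]), 1e6)

  q <- q_fixture(matrix(c(1L, 2L, 1L, 2L, 3L, 2L, 1L, 2L, 1L), 3, 3), 3)
  expect_equal(unname(nid_features(q)), oracle_nid_features(q),
               tolerance = 1e-9)

  qr <- random_q(c(4, 4, 3), n_levels = 4, seed = 17)
  expect_equal(unname(nid_features(qr)), oracle_nid_features(qr),
               tolerance = 1e-9)
  # a uniform level shift preserves neighbour differences, hence contrast
  arr <- qr$levels + 1L
  qs <- q_fixture(arr, 5)
  expect_equal(unname(nid_features(qs)["contrast"]),
               unname(nid_features(qr)["contrast"]), tolerance = 1e-9)
})

test_that("grey-level dependence features match neighbour-counting oracle", {
  single <- q_fixture(array(1L, c(1, 1, 1)), 1)
  f1 <- ngld_features(single)
  expect_equal(unname(f1["small_number_emphasis"]), 1)

  qc <- q_fixture(array(1L, c(3, 3, 3)), 1)
  qr <- random_q(c(4, 4, 3), n_levels = 3, seed = 55)
  for (q in list(qc, qr)) {
    expect_equal(unname(ngld_features(q)), oracle_ngld_features(q),
                 tolerance = 1e-9)
  }
  # a constant lesion maximizes large-number emphasis among same-shape lesions
  expect_gt(ngld_features(qc)["large_number_emphasis"],
            ngld_features(random_q(c(3, 3, 3), 3, seed = 2, na_frac = 0))[
              "large_number_emphasis"])
})

test_that("texture spectrum has unit peak for constant lesions and symmetric inverses", {
  qc <- q_fixture(array(1L, c(5, 5, 1)), 1)
  fc <- texture_spectrum_features(qc)
  expect_equal(unname(fc["max_spectrum"]), 1)
  expect_equal(unname(fc["black_white_symmetry"]), 1)

  set.seed(77)
  arr <- array(sample.int(4, 49, replace = TRUE), c(7, 7, 1))
  q <- q_fixture(arr, 4)
  qinv <- q_fixture(5L - arr, 4)   # intensity-inverted twin
  f <- texture_spectrum_features(q)
  finv <- texture_spectrum_features(qinv)
  expect_equal(unname(f["black_white_symmetry"]),
               unname(finv["black_white_symmetry"]), tolerance = 1e-12)

  # checkerboard: two alternating texture units, equal frequency
  cb <- array(1L + (outer(1:5, 1:5, "+") %% 2L), c(5, 5, 1))
  fcb <- texture_spectrum_features(q_fixture(cb, 2))
  expect_equal(unname(fcb["max_spectrum"]), 0.5 + 1 / 18, tolerance = 1e-12)

  thin <- q_fixture(array(1L, c(2, 2, 1)), 1)
  expect_true(all(is.nan(texture_spectrum_features(thin))))
})

test_that("texture-feature-coding map and features behave as documented", {
  qc <- q_fixture(array(1L, c(3, 3, 3)), 1)
  fc <- tfc_features(qc)
  expect_equal(unname(fc[c("coarseness", "homogeneity", "variance")]),
               c(1, 1, 0))

  set.seed(23)
  arr <- array(sample.int(3, 48, replace = TRUE), c(4, 4, 3))
  q <- q_fixture(arr, 3)
  # coded map equals the loop oracle
  cm <- petrad:::tfc_code_map(q)
  expect_equal(cm$map, oracle_tfc_map(q))
  # monotone level shift leaves the coded map unchanged
  qs <- q_fixture(arr + 1L, 4)
  expect_identical(tfc_features(q), tfc_features(qs))
  expect_identical(tfcc_features(q), tfcc_features(qs))
})

test_that("TFC co-occurrence features match a brute-force oracle", {
  set.seed(29)
  arr <- array(sample.int(3, 16, replace = TRUE), c(4, 4, 1))
  q <- q_fixture(arr, 3)
  code <- oracle_tfc_map(q)
  qq <- q_fixture(code + 1L, 27)
  C <- oracle_glcm(qq)
  P <- C / sum(C)
  # recompute the eight indices directly on code values
  idx <- which(P > 0, arr.ind = TRUE)
  p <- P[idx]; vi <- idx[, 1] - 1; vj <- idx[, 2] - 1
  mu_i <- sum(vi * p); mu_j <- sum(vj * p)
  s_i <- sqrt(sum((vi - mu_i)^2 * p)); s_j <- sqrt(sum((vj - mu_j)^2 * p))
  pm <- rowSums(P); vv <- 0:26; mu_m <- sum(vv * pm)
  expected <- c(sum(p^2), sum((vi - vj)^2 * p), -sum(p * log2(p)),
                sum(p / (1 + abs(vi - vj))), sum((vi + vj) / 2 * p),
                sum(p / (1 + (vi - vj)^2)),
                if (s_i > 0 && s_j > 0)
                  sum((vi - mu_i) * (vj - mu_j) * p) / (s_i * s_j) else 0,
                sum((vv - mu_m)^2 * pm))
  expect_equal(unname(tfcc_features(q)), expected, tolerance = 1e-9)
})

test_that("probability-normalized matrices sum to one", {
  qr <- random_q(c(5, 5, 3), n_levels = 5, seed = 99, na_frac = 0.1)
  C <- petrad:::glcm_counts(qr)
  expect_equal(sum(C / sum(C)), 1, tolerance = 1e-9)
  tab <- petrad:::run_table(qr)
  expect_equal(sum(tab[, "count"]) / sum(tab[, "count"]), 1)
})
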