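test_that("seed search returns the SUV maximum with deterministic tie-break", {
  v <- array(0.3, c(20, 16, 8))
  v[10, 12, 5] <- 8
  vol <- suv_volume(v, c(1, 1, 1))
  s <- find_global_seed(vol)
  expect_equal(s$index, c(10L, 12L, 5L))
  expect_equal(s$suv, 8)

  v2 <- array(0.3, c(10, 10, 4))
  v2[3, 3, 1] <- 5; v2[7, 7, 3] <- 5
  s2 <- find_global_seed(suv_volume(v2, c(1, 1, 1)))
  expect_equal(s2$index, c(3L, 3L, 1L))   # lower linear index wins

  excl <- array(FALSE, dim(v)); excl[10, 12, 5] <- TRUE
  v[4, 4, 2] <- 6
  s3 <- find_global_seed(suv_volume(v, c(1, 1, 1)), excl)
  expect_equal(s3$index, c(4L, 4L, 2L))
  expect_error(find_global_seed(vol, array(TRUE, dim(v))), "excluded")
})

test_that("region growing recovers threshold isocontours and warns at borders", {
  ph <- standard_phantom(fwhm = 0)
  # strict two-constant volume built from the analytic mask (no edge
  # partial volume): the 40% threshold separates the constants exactly
  truth <- ph$masks[[1]]$voxels
  vol <- suv_volume(ifelse(truth, 5, 0.5), ph$volume$spacing)
  seed <- find_global_seed(vol)
  rg <- region_grow(vol, seed, 0.4)
  expect_identical(rg$region, truth)
  expect_identical(rg$roi, truth[, , seed$index[3]])
  expect_length(rg$warnings, 0)

  # blurred phantom: within 1 voxel of the exhaustive 40% isocontour
  phb <- standard_phantom(fwhm = 5)
  seedb <- find_global_seed(phb$volume)
  rgb_ <- region_grow(phb$volume, seedb, 0.4)
  thr <- phb$volume$voxels >= 0.4 * seedb$suv
  expect_true(all(rgb_$region[!petrad:::dilate26(thr)] == FALSE))
  expect_true(all(thr[rgb_$region]))

  uni <- suv_volume(array(1, c(12, 12, 6)), c(1, 1, 1))
  su <- find_global_seed(uni)
  rgu <- region_grow(uni, su, 0.4)
  expect_true(all(rgu$roi))
  expect_match(rgu$warnings, "border")
})

test_that("the localized contour locks onto a two-region boundary", {
  n <- 48
  sl <- matrix(0.5, n, n)
  cx <- 24.5; cy <- 24.5; r <- 12
  disc <- outer(1:n, 1:n, function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
  sl[disc] <- 5
  # init exactly on the boundary
  m1 <- lac_refine_slice(sl, disc, lac_params(radius_mm = 5), spacing_mm = 1)
  expect_gt(2 * sum(m1 & disc) / (sum(m1) + sum(disc)), 0.95)
  # init from a rough dilated/eroded start still converges
  init <- outer(1:n, 1:n, function(i, j) (i - cx)^2 + (j - cy)^2 <= (r + 4)^2)
  m2 <- lac_refine_slice(sl, init, lac_params(radius_mm = 5), spacing_mm = 1)
  expect_gt(2 * sum(m2 & disc) / (sum(m2) + sum(disc)), 0.95)
})

test_that("with no data term the curvature force shrinks the contour", {
  n <- 40
  sl <- matrix(1, n, n)
  init <- outer(1:n, 1:n, function(i, j) (i - 20)^2 + (j - 20)^2 <= 100)
  out <- lac_refine_slice(sl, init, lac_params(curvature = 0.5,
                                               max_iter = 200))
  expect_lt(sum(out), sum(init))
})

test_that("noisy blurred discs are still delineated accurately", {
  phn <- standard_phantom(fwhm = 5, noise_sd = 0.15, seed = 31)
  seed <- find_global_seed(phn$volume)
  z <- seed$index[3]
  rg <- region_grow(phn$volume, seed, 0.4)
  m <- lac_refine_slice(phn$volume$voxels[, , z], rg$roi,
                        lac_params(), spacing_mm = 1.17)
  truth <- phn$masks[[1]]$voxels[, , z]
  expect_gt(2 * sum(m & truth) / (sum(m) + sum(truth)), 0.90)
})

test_that("single-lesion segmentation is accurate over the clinical radius range", {
  for (r in c(6, 10, 15)) {
    ph <- standard_phantom(radius = r, fwhm = 5)
    seed <- find_global_seed(ph$volume)
    bm <- segment_lesion(ph$volume, seed)
    expect_gt(dice_coefficient(bm, ph$masks[[1]]), 0.90)
    # axial containment: nothing beyond one slice past the analytic extent
    tz <- which(apply(ph$masks[[1]]$voxels, 3, any))
    sz <- which(apply(bm$voxels, 3, any))
    expect_gte(min(sz), min(tz) - 1)
    expect_lte(max(sz), max(tz) + 1)
    expect_true(bm$voxels[seed$linear])
  }
})

test_that("a one-slice slab stays confined to its slice", {
  v <- array(0.4, c(24, 24, 9))
  v[8:16, 8:16, 5] <- 6
  vol <- suv_volume(v, c(1.17, 1.17, 3.27))
  bm <- segment_lesion(vol, find_global_seed(vol))
  expect_true(all(which(apply(bm$voxels, 3, any)) == 5))
})

test_that("moderate noise barely moves the Dice coefficient", {
  ph0 <- standard_phantom(fwhm = 5)
  d0 <- dice_coefficient(segment_lesion(ph0$volume, find_global_seed(ph0$volume)),
                         ph0$masks[[1]])
  phn <- standard_phantom(fwhm = 5, noise_sd = 0.3, seed = 7)
  dn <- dice_coefficient(segment_lesion(phn$volume, find_global_seed(phn$volume)),
                         phn$masks[[1]])
  expect_lt(abs(d0 - dn), 0.05)
})

test_that("the multi-lesion loop finds planted lesions and stops below 2 g/ml", {
  ph2 <- make_pet_phantom(
    shape = c(64, 64, 40), spacing = c(1.17, 1.17, 3.27),
    background_suv = 0.5,
    lesions = list(phantom_lesion(c(22, 22, 40), 8, 8),
                   phantom_lesion(c(52, 50, 75), 6, 5)),
    psf_fwhm_mm = 5, seed = 2)
  expect_warning(ls <- segment_all(ph2$volume), "multiple")
  expect_length(ls$masks, 2)
  expect_true(all(diff(ls$suv_max) <= 0))
  gm <- find_global_seed(ph2$volume)
  expect_true(ls$masks[[1]]$voxels[gm$linear])
  expect_false(any(ls$masks[[1]]$voxels & ls$masks[[2]]$voxels))
  expect_gt(dice_coefficient(ls$masks[[1]], ph2$masks[[1]]), 0.90)
  expect_gt(dice_coefficient(ls$masks[[2]], ph2$masks[[2]]), 0.90)
  # determinism
  ls2 <- suppressWarnings(segment_all(ph2$volume))
  expect_identical(ls$masks[[1]]$voxels, ls2$masks[[1]]$voxels)
})

test_that("sub-threshold uptake and uniform volumes yield no lesions", {
  ph <- make_pet_phantom(shape = c(48, 48, 24), spacing = c(1.17, 1.17, 3.27),
                         background_suv = 0.3,
                         lesions = list(phantom_lesion(c(28, 28, 40), 7, 1.5)),
                         psf_fwhm_mm = 0, seed = 3)
  expect_length(segment_all(ph$volume)$masks, 0)
  uni <- suv_volume(array(0.3, c(24, 24, 10)), c(1.17, 1.17, 3.27))
  ls <- segment_all(uni)
  expect_length(ls$masks, 0)
  expect_length(ls$warnings, 0)
})
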