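# Synthetic data generators: 3D PET phantoms with ground-truth lesion masks
# for the segmentation/extraction code, and labelled Gaussian feature cohorts
# with planted effects for the selection/classification code.

#' Describe one phantom lesion
#'
#' @param center_mm lesion centre in world mm (voxel centres sit at
#'   `(i - 0.5) * spacing`)
#' @param radius_mm sphere radius, or three semi-axes for an ellipsoid
#' @param peak_suv lesion uptake, g/ml (before scanner blur)
#' @param shape `"sphere"` or `"ellipsoid"`
#' @export
phantom_lesion <- function(center_mm, radius_mm, peak_suv,
                           shape = c("sphere", "ellipsoid")) {
  shape <- match.arg(shape)
  radius_mm <- as.numeric(radius_mm)
  if (shape == "sphere" && length(radius_mm) == 1) radius_mm <- rep(radius_mm, 3)
  stopifnot(length(radius_mm) == 3, all(radius_mm > 0), peak_suv > 0)
  list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
       peak_suv = peak_suv, shape = shape)
}

# partial-volume fill fraction of each voxel for one ellipsoid, by 3x
# supersampling; returned over the full grid (zero far from the lesion)
lesion_fill_fraction <- function(shape, spacing, les, supersample = 3L) {
  frac <- array(0, shape)
  lo <- pmax(floor((les$center_mm - les$radius_mm) / spacing), 1)
  hi <- pmin(ceiling((les$center_mm + les$radius_mm) / spacing) + 1, shape)
  if (any(lo > hi)) return(frac)
  sub <- (seq_len(supersample) - 0.5) / supersample  # offsets within a voxel
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  acc <- array(0, c(length(ii), length(jj), length(kk)))
  for (sx in sub) for (sy in sub) for (sz in sub) {
    x <- ((ii - 1) + sx) * spacing[1]
    y <- ((jj - 1) + sy) * spacing[2]
    z <- ((kk - 1) + sz) * spacing[3]
    dx2 <- ((x - les$center_mm[1]) / les$radius_mm[1])^2
    dy2 <- ((y - les$center_mm[2]) / les$radius_mm[2])^2
    dz2 <- ((z - les$center_mm[3]) / les$radius_mm[3])^2
    acc <- acc + (outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1)
  }
  frac[ii, jj, kk] <- acc / supersample^3
  frac
}

#' Generate a synthetic brain amino-acid PET phantom
#'
#' Emulates the conditions the segmentation and feature code are meant for:
#' a low uniform background, one or more hyperintense quasi-spherical lesions
#' (typical lesion uptake 3-10 g/ml), Gaussian scanner blur (PSF FWHM), and
#' optional voxel noise. The ground-truth mask of each lesion is the
#' *pre-blur* analytic indicator (voxel fill fraction >= 0.5), i.e. the
#' biological extent segmentation accuracy is judged against.
#'
#' The default grid mirrors a clinical brain PET reconstruction: in-plane
#' spacing 1.17 mm, slice thickness 3.27 mm, so axis anisotropy is exercised.
#'
#' @param shape grid dimensions (x, y, z)
#' @param spacing voxel size, mm
#' @param background_suv uniform background uptake, g/ml
#' @param lesions list of [phantom_lesion()] descriptions
#' @param psf_fwhm_mm Gaussian point-spread FWHM, mm (0 disables blur)
#' @param noise `list(type = "none")`, `list(type = "gaussian", sd = )` in
#'   g/ml, or `list(type = "poisson", scale = )` (voxel values are scaled,
#'   Poisson-resampled and rescaled)
#' @param seed RNG seed; the phantom is fully deterministic given it
#' @return list with `volume` (a [suv_volume()]), `masks` (list of
#'   [btv_mask()] ground truths, in input order) and `lesions` (the specs)
#' @export
make_pet_phantom <- function(shape = c(64, 64, 32),
                             spacing = c(1.17, 1.17, 3.27),
                             background_suv = 0.5,
                             lesions = list(),
                             psf_fwhm_mm = 0,
                             noise = list(type = "none"),
                             seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), background_suv >= 0,
            psf_fwhm_mm >= 0)
  fracs <- lapply(lesions, function(l) lesion_fill_fraction(shape, spacing, l))
  for (l in lesions) {
    if (l$peak_suv <= background_suv) {
      stop("lesion peak SUV must exceed the background", call. = FALSE)
    }
    lov <- (l$center_mm - l$radius_mm) / spacing
    hiv <- (l$center_mm + l$radius_mm) / spacing
    if (any(lov < 0) || any(hiv > shape)) {
      stop("lesion extends outside the grid", call. = FALSE)
    }
  }
  if (length(fracs) > 1) {
    for (a in seq_along(fracs)) for (b in seq_along(fracs)) {
      if (a < b && any(fracs[[a]] > 0 & fracs[[b]] > 0)) {
        stop("lesions overlap; adjust centres/radii", call. = FALSE)
      }
    }
  }
  vox <- array(background_suv, shape)
  for (i in seq_along(fracs)) {
    vox <- vox + (lesions[[i]]$peak_suv - background_suv) * fracs[[i]]
  }
  if (psf_fwhm_mm > 0) {
    sigma_vox <- (psf_fwhm_mm / 2.3548) / spacing
    vox <- gauss_smooth3d(vox, sigma_vox)
  }
  set.seed(as.integer(seed))
  if (noise$type == "gaussian") {
    vox <- vox + array(stats::rnorm(length(vox), 0, noise$sd), shape)
  } else if (noise$type == "poisson") {
    vox <- array(stats::rpois(length(vox), pmax(vox, 0) * noise$scale) / noise$scale, shape)
  } else if (noise$type != "none") {
    stop("unknown noise type: ", noise$type, call. = FALSE)
  }
  vox[vox < 0] <- 0
  vol <- suv_volume(vox, spacing = spacing)
  masks <- lapply(seq_along(fracs), function(i) {
    btv_mask(fracs[[i]] >= 0.5, spacing = spacing, lesion_id = i)
  })
  list(volume = vol, masks = masks, lesions = lesions)
}

#' Generate a labelled synthetic feature cohort
#'
#' Class-conditional Gaussian features emulating a lesions-by-features table
#' with a binary outcome. Informative features differ between classes by a
#' standardized mean shift; correlated blocks share a latent factor so that
#' within-block Pearson correlation is `block_r`.
#'
#' @param n_per_class observations per class (length 1 or 2; class order is
#'   non-responder = 0 then responder = 1)
#' @param n_features number of feature columns; when <= 108 they take the
#'   radiomics registry names so downstream code sees realistic columns
#' @param informative indices (or names) of features given a class effect
#' @param effect_size standardized mean difference for informative features
#' @param block_size features per correlated block (1 = independent)
#' @param block_r within-block Pearson correlation, in [0, 1)
#' @param seed RNG seed
#' @return a `data.frame` with feature columns plus a 0/1 `label` column;
#'   attributes `informative` (names) and `block` (block id per feature)
#' @export
make_feature_cohort <- function(n_per_class = 30, n_features = 108,
                                informative = integer(0), effect_size = 1.5,
                                block_size = 1L, block_r = 0, seed = 1L) {
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, 2)
  stopifnot(all(n_per_class >= 2), n_features >= 1,
            block_r >= 0, block_r < 1, block_size >= 1)
  n <- sum(n_per_class)
  label <- rep(c(0L, 1L), n_per_class)
  nm <- if (n_features <= 108) feature_registry()$name[seq_len(n_features)]
        else sprintf("f%03d", seq_len(n_features))
  if (is.character(informative)) informative <- match(informative, nm)
  stopifnot(all(informative >= 1 & informative <= n_features))
  block <- ((seq_len(n_features) - 1L) %/% block_size) + 1L
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n * max(block)), n, max(block))  # latent factors
  e <- matrix(stats::rnorm(n * n_features), n, n_features)
  x <- sqrt(block_r) * z[, block, drop = FALSE] + sqrt(1 - block_r) * e
  x[label == 1L, informative] <- x[label == 1L, informative] + effect_size
  colnames(x) <- nm
  out <- data.frame(x, check.names = FALSE)
  out$label <- label
  attr(out, "informative") <- nm[informative]
  attr(out, "block") <- block
  out
}
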