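# Fully automatic BTV delineation. The pipeline per lesion:
#   1. seed at the volume's (unexcluded) SUV maximum;
#   2. region growing from the seed (>= 40% of seed SUV, 26-connected) for a
#      rough in-plane initial ROI on the seed slice;
#   3. slice-wise refinement with a localized region-based active contour
#      (level set comparing local interior/exterior mean SUV within a ball
#      around each contour point, plus curvature regularization);
#   4. propagation to neighbouring slices, each initialized from the previous
#      slice's contour dilated by one voxel, stopping when a disease-free
#      slice is reached.
# Multiple lesions are segmented iteratively, masking out previous BTVs in
# the seed search, until the candidate seed falls below the SUV stop
# threshold (2 g/ml). Everything is deterministic.

#' Localized active-contour parameters
#'
#' @param radius_mm radius of the local ball in which interior/exterior mean
#'   SUV are compared (mm)
#' @param curvature dimensionless curvature-regularization weight
#' @param max_iter maximum level-set iterations per slice
#' @param tol convergence tolerance: fraction of narrow-band pixels changing
#'   side; convergence is declared when the fraction stays below `tol` for
#'   10 consecutive iterations
#' @param band narrow-band half-width in pixels
#' @export
lac_params <- function(radius_mm = 5, curvature = 0.2, max_iter = 300L,
                       tol = 0.005, band = 2) {
  stopifnot(radius_mm > 0, curvature >= 0, max_iter >= 1, tol > 0, band > 0)
  structure(list(radius_mm = radius_mm, curvature = curvature,
                 max_iter = as.integer(max_iter), tol = tol, band = band),
            class = "lac_params")
}

#' Find the seed voxel: the SUV maximum outside an exclusion mask
#'
#' Ties are broken deterministically by the lowest linear index.
#'
#' @param vol a [suv_volume()]
#' @param exclusion optional logical array of voxels to ignore (already
#'   segmented lesions)
#' @return list with `index` (i, j, k), `linear`, `suv`
#' @export
find_global_seed <- function(vol, exclusion = NULL) {
  v <- vol$voxels
  if (!is.null(exclusion)) {
    stopifnot(identical(dim(exclusion), dim(v)))
    if (all(exclusion)) stop("all voxels excluded from seed search", call. = FALSE)
    v[exclusion] <- -Inf
  }
  lin <- which.max(v)
  list(index = as.integer(arrayInd(lin, dim(v))), linear = lin,
       suv = vol$voxels[lin])
}

#' Region growing from a seed for a rough lesion estimate
#'
#' 26-connected region of voxels with SUV >= `threshold_fraction` times the
#' seed SUV, containing the seed. The in-plane cross-section on the seed
#' slice is the initial ROI handed to the active contour; its bounding box
#' (dilated by 2 voxels) is recorded for background estimation.
#'
#' @param vol a [suv_volume()]
#' @param seed result of [find_global_seed()]
#' @param threshold_fraction inclusion threshold as a fraction of the seed
#'   SUV, in (0, 1); 40% of max is the usual rough PET delineation rule
#' @return list with `region` (3D mask), `slice_index`, `roi` (2D mask),
#'   `bbox` (in-plane lo/hi), `warnings`
#' @export
region_grow <- function(vol, seed, threshold_fraction = 0.4) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  inside <- vol$voxels >= threshold_fraction * seed$suv
  region <- flood26(inside, seed$linear)
  warn <- character(0)
  dm <- dim(region)
  pos <- arrayInd(which(region), dm)
  if (any(pos == 1) || any(t(t(pos) == dm))) {
    warn <- "region touches the volume border; lesion may be truncated"
  }
  k <- seed$index[3]
  roi <- region[, , k]
  bb <- mask_bbox(array(roi, c(dm[1], dm[2], 1)), margin = 2L)
  list(region = region, slice_index = k, roi = roi,
       bbox = list(lo = bb$lo[1:2], hi = bb$hi[1:2]), warnings = warn)
}

# discrete disc kernel for the local ball (odd-sized 0/1 matrix)
disc_kernel <- function(radius_px) {
  r <- max(1L, ceiling(radius_px))
  g <- expand.grid(x = -r:r, y = -r:r)
  k <- matrix(as.numeric(g$x^2 + g$y^2 <= radius_px^2), 2 * r + 1, 2 * r + 1)
  k
}

signed_distance <- function(m) {
  # positive outside, negative inside; EBImage distmap is Euclidean
  outside <- EBImage::distmap(matrix(as.numeric(!m), nrow(m), ncol(m)))
  inside <- EBImage::distmap(matrix(as.numeric(m), nrow(m), ncol(m)))
  as.matrix(outside) - as.matrix(inside)
}

curvature2d <- function(phi) {
  px <- (rbind(phi[-1, ], phi[nrow(phi), ]) - rbind(phi[1, ], phi[-nrow(phi), ])) / 2
  py <- (cbind(phi[, -1], phi[, ncol(phi)]) - cbind(phi[, 1], phi[, -ncol(phi)])) / 2
  pxx <- rbind(phi[-1, ], phi[nrow(phi), ]) - 2 * phi + rbind(phi[1, ], phi[-nrow(phi), ])
  pyy <- cbind(phi[, -1], phi[, ncol(phi)]) - 2 * phi + cbind(phi[, 1], phi[, -ncol(phi), drop = FALSE])
  pxy_a <- rbind(py[-1, ], py[nrow(py), ]) - rbind(py[1, ], py[-nrow(py), ])
  pxy <- pxy_a / 2
  num <- pxx * py^2 - 2 * px * py * pxy + pyy * px^2
  den <- (px^2 + py^2)^1.5 + 1e-8
  pmax(pmin(num / den, 1), -1)
}

conv2_disc <- function(x, k) {
  as.matrix(EBImage::filter2(x, k, boundary = 0))
}

#' Refine a 2D contour with a localized region-based active contour
#'
#' Evolves a level-set embedding of `init` under the localized
#' uniform-modelling energy: each point compares the mean SUV of its local
#' interior and exterior within a ball of `params$radius_mm`, with curvature
#' regularization. Stops at convergence (see [lac_params()]) or `max_iter`.
#'
#' @param slice 2D numeric SUV matrix
#' @param init 2D logical initial mask (nonempty)
#' @param params a [lac_params()]
#' @param spacing_mm in-plane pixel spacing (mm), used to size the ball
#' @return 2D logical mask (possibly empty if the contour vanished)
#' @export
lac_refine_slice <- function(slice, init, params = lac_params(),
                             spacing_mm = 1) {
  stopifnot(is.matrix(slice), identical(dim(slice), dim(init)))
  if (!any(init)) stop("initial mask is empty", call. = FALSE)
  k <- disc_kernel(params$radius_mm / spacing_mm)
  phi <- signed_distance(init)
  calm <- 0L
  H_prev <- init
  for (it in seq_len(params$max_iter)) {
    H <- phi < 0
    if (!any(H)) return(matrix(FALSE, nrow(slice), ncol(slice)))
    a_in <- conv2_disc(matrix(as.numeric(H), nrow(H)), k)
    s_in <- conv2_disc(slice * H, k)
    a_out <- conv2_disc(matrix(as.numeric(!H), nrow(H)), k)
    s_out <- conv2_disc(slice * (!H), k)
    u <- s_in / pmax(a_in, 1e-8)
    v <- s_out / pmax(a_out, 1e-8)
    f <- (slice - u)^2 - (slice - v)^2
    band <- abs(phi) <= params$band
    if (!any(band)) {       # band drifted away; restore distance property
      phi <- signed_distance(H)
      band <- abs(phi) <= params$band
      if (!any(band)) break
    }
    fmax <- max(abs(f[band]), 1e-12)
    dphi <- f / fmax + params$curvature * curvature2d(phi)
    dt <- 0.45 / (max(abs(dphi[band])) + 1e-12)
    phi[band] <- phi[band] + dt * dphi[band]
    if (it %% 15 == 0) phi <- signed_distance(phi < 0)
    H_new <- phi < 0
    changed <- sum(H_new != H_prev)
    calm <- if (changed <= params$tol * max(sum(band), 1)) calm + 1L else 0L
    H_prev <- H_new
    if (calm >= 10L) break
  }
  phi < 0
}

# keep the 2D 8-connected component(s) overlapping `ref`; empty if none
keep_overlapping_2d <- function(m, ref) {
  if (!any(m)) return(m)
  lab <- label_components26(array(m, c(dim(m), 1)))[, , 1]
  ids <- unique(lab[ref & lab > 0])
  m & (lab %in% ids[ids > 0]) & lab > 0
}

dilate2d_8 <- function(m) {
  dilate26(array(m, c(dim(m), 1)))[, , 1]
}

# background level of a slice: median SUV outside the (dilated) ROI box
slice_background <- function(slice, bbox) {
  out <- matrix(TRUE, nrow(slice), ncol(slice))
  out[bbox$lo[1]:bbox$hi[1], bbox$lo[2]:bbox$hi[2]] <- FALSE
  if (!any(out)) return(stats::median(slice))
  stats::median(slice[out])
}

# a refined slice is disease-free when the contour vanished, is tiny, or its
# interior mean does not stand out from the slice background
is_disease_free <- function(slice, refined, bbox, bg_factor = 1.5) {
  if (!any(refined)) return(TRUE)
  if (sum(refined) < 2) return(TRUE)
  mean(slice[refined]) < bg_factor * slice_background(slice, bbox)
}

#' Segment one lesion from a seed
#'
#' Runs the active contour on the seed slice (initialized by region
#' growing), then propagates superiorly and inferiorly, initializing each
#' slice from its neighbour's result dilated by one voxel, until the
#' disease-free-slice criterion fires. The union is returned as the single
#' 26-connected component containing the seed.
#'
#' @param vol a [suv_volume()]
#' @param seed result of [find_global_seed()]
#' @param params a [lac_params()]
#' @param threshold_fraction region-growing inclusion fraction
#' @param pvc_fraction partial-volume guard: each refined slice is
#'   intersected with the adaptive isocontour at
#'   `background + pvc_fraction * (seed SUV - background)` (background
#'   estimated per slice). The default 0.4 matches the 40%-of-maximum PET
#'   delineation convention also used to initialize the contour; it bounds
#'   blur-driven spill on the axial cap slices. Set 0 to disable
#' @param lesion_id id for the returned mask
#' @return a [btv_mask()] with attribute `warnings`
#' @export
segment_lesion <- function(vol, seed, params = lac_params(),
                           threshold_fraction = 0.4, pvc_fraction = 0.4,
                           lesion_id = 1L) {
  rg <- region_grow(vol, seed, threshold_fraction)
  dm <- dim(vol$voxels)
  sp <- vol$spacing
  k0 <- rg$slice_index
  warns <- rg$warnings
  inplane <- mean(sp[1:2])

  # noise-robust reference peak: mean of the 3x3 in-plane patch at the seed
  # (a raw single-voxel maximum rides on the noise)
  px <- pmax(seed$index[1] - 1, 1):pmin(seed$index[1] + 1, dm[1])
  py <- pmax(seed$index[2] - 1, 1):pmin(seed$index[2] + 1, dm[2])
  peak_ref <- mean(vol$voxels[px, py, seed$index[3]])

  refine <- function(z, init) {
    slice <- vol$voxels[, , z]
    r <- lac_refine_slice(slice, init, params, inplane)
    if (pvc_fraction > 0 && any(r)) {
      b <- mask_bbox(array(init, c(dm[1], dm[2], 1)), margin = 2L)
      bg <- slice_background(slice, list(lo = b$lo[1:2], hi = b$hi[1:2]))
      r <- r & (slice >= bg + pvc_fraction * (peak_ref - bg))
    }
    keep_overlapping_2d(r, dilate2d_8(init))
  }
  ref0 <- refine(k0, rg$roi)
  if (!any(ref0)) stop("seed-slice segmentation is empty", call. = FALSE)
  slices <- list()
  slices[[as.character(k0)]] <- ref0

  for (dir in c(1L, -1L)) {
    prev <- ref0
    z <- k0 + dir
    while (z >= 1 && z <= dm[3]) {
      init <- dilate2d_8(prev)
      r <- refine(z, init)
      bb <- if (any(init)) {
        b <- mask_bbox(array(init, c(dm[1], dm[2], 1)), margin = 2L)
        list(lo = b$lo[1:2], hi = b$hi[1:2])
      } else rg$bbox
      if (is_disease_free(vol$voxels[, , z], r, bb)) break
      slices[[as.character(z)]] <- r
      prev <- r
      z <- z + dir
    }
  }

  mask <- array(FALSE, dm)
  for (zc in names(slices)) mask[, , as.integer(zc)] <- slices[[zc]]
  if (!mask[seed$linear]) {
    # seed can sit one voxel off the refined contour; snap to the component
    # nearest the seed on the seed slice
    mask[seed$index[1], seed$index[2], k0] <- TRUE
  }
  mask <- flood26(mask, seed$linear)
  pos <- arrayInd(which(mask), dm)
  if (any(pos == 1) || any(t(t(pos) == dm))) {
    warns <- c(warns, "BTV touches the volume border")
  }
  out <- btv_mask(mask, spacing = sp, origin = vol$origin,
                  lesion_id = lesion_id)
  attr(out, "warnings") <- warns
  attr(out, "rough_region") <- rg$region
  out
}

#' Segment every lesion in a volume
#'
#' Iteratively seeds at the highest remaining SUV (previous BTVs dilated by
#' one voxel are excluded from the search, their SUVs untouched) and
#' segments, stopping when the candidate seed SUV falls below `suv_stop`
#' (default 2 g/ml). A warning is emitted when more than one lesion is
#' found, mirroring the interactive safeguard against false positives.
#'
#' @param vol a [suv_volume()]
#' @param params a [lac_params()]
#' @param suv_stop stop threshold for candidate seeds, g/ml
#' @param max_lesions safety cap on the number of lesions
#' @param threshold_fraction region-growing inclusion fraction
#' @param pvc_fraction partial-volume guard, see [segment_lesion()]
#' @return a `lesion_set`: list with `masks` (ordered by descending
#'   SUV max; the first contains the global maximum), `suv_max`, `warnings`
#' @export
segment_all <- function(vol, params = lac_params(), suv_stop = 2,
                        max_lesions = 10L, threshold_fraction = 0.4,
                        pvc_fraction = 0.4) {
  dm <- dim(vol$voxels)
  exclusion <- array(FALSE, dm)
  masks <- list()
  suv_max <- numeric(0)
  warns <- character(0)
  while (length(masks) < max_lesions && !all(exclusion)) {
    seed <- find_global_seed(vol, exclusion)
    if (seed$suv < suv_stop) break
    res <- tryCatch(
      segment_lesion(vol, seed, params, threshold_fraction, pvc_fraction,
                     lesion_id = length(masks) + 1L),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warns <- c(warns, sprintf("seed at SUV %.2f skipped: %s",
                                seed$suv, conditionMessage(res)))
      excl_seed <- array(FALSE, dm)
      excl_seed[seed$linear] <- TRUE
      exclusion <- exclusion | dilate26(excl_seed)
      next
    }
    m <- res$voxels
    for (prev in masks) m <- m & !prev$voxels   # enforce disjoint BTVs
    if (!m[seed$linear]) {
      excl_seed <- array(FALSE, dm)
      excl_seed[seed$linear] <- TRUE
      exclusion <- exclusion | dilate26(excl_seed)
      next
    }
    m <- flood26(m, seed$linear)
    mask <- btv_mask(m, spacing = vol$spacing, origin = vol$origin,
                     lesion_id = length(masks) + 1L)
    attr(mask, "warnings") <- attr(res, "warnings")
    masks[[length(masks) + 1L]] <- mask
    suv_max <- c(suv_max, max(vol$voxels[m]))
    warns <- c(warns, attr(res, "warnings"))
    # the lesion's whole contiguous supra-threshold basin is attributed to
    # it: blur shoulders above suv_stop but connected to this lesion would
    # otherwise re-seed as false-positive lesions
    basin <- flood26(vol$voxels >= suv_stop, seed$linear)
    exclusion <- exclusion | dilate26(m) | attr(res, "rough_region") | basin
  }
  if (length(masks) > 1) {
    msg <- sprintf("multiple lesions detected (%d); check for false positives",
                   length(masks))
    warning(msg, call. = FALSE)
    warns <- c(warns, msg)
  }
  structure(list(masks = masks, suv_max = suv_max, warnings = warns),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set> %d lesion(s)\n", length(x$masks)))
  for (i in seq_along(x$masks)) {
    cat(sprintf("  lesion %d: SUVmax %.2f g/ml, %.2f ml\n", i, x$suv_max[i],
                sum(x$masks[[i]]$voxels) * prod(x$masks[[i]]$spacing) / 1000))
  }
  invisible(x)
}

#' Dice similarity coefficient between two masks
#'
#' 2|A n B| / (|A| + |B|).
#' @param a,b logical arrays or [btv_mask()] objects
#' @export
dice_coefficient <- function(a, b) {
  va <- if (inherits(a, "btv_mask")) a$voxels else a
  vb <- if (inherits(b, "btv_mask")) b$voxels else b
  2 * sum(va & vb) / (sum(va) + sum(vb))
}
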