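# PET volume containers and quantification (SUV / SUL).
#
# Volumes are lightweight S3 lists around a 3D numeric array plus grid
# geometry. Axis order is (x, y, z) with z the slice axis; voxel indices are
# 1-based in R code; spacing is mm per axis.

new_pet_grid <- function(voxels, spacing, origin) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive mm values", call. = FALSE)
  }
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3)
  list(voxels = voxels, spacing = spacing, origin = origin)
}

#' Construct an activity-concentration volume (Bq/ml)
#'
#' @param voxels 3D numeric array of activity concentration, Bq/ml
#' @param spacing voxel size per axis, mm
#' @param origin world coordinates of the first voxel, mm
#' @param dose_MBq injected dose, MBq (optional metadata)
#' @param weight_kg patient weight, kg (optional metadata)
#' @param decay_corrected logical; whether values are already decay-corrected
#'   to a common reference time (the usual state of reconstructed PET)
#' @return an `activity_volume` object
#' @export
activity_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                            dose_MBq = NA_real_, weight_kg = NA_real_,
                            decay_corrected = TRUE) {
  g <- new_pet_grid(voxels, spacing, origin)
  if (any(g$voxels < 0, na.rm = TRUE)) {
    stop("activity concentration must be non-negative", call. = FALSE)
  }
  structure(
    c(g, list(dose_MBq = dose_MBq, weight_kg = weight_kg,
              decay_corrected = decay_corrected)),
    class = c("activity_volume", "pet_volume")
  )
}

#' Construct an SUV volume (g/ml)
#'
#' @inheritParams activity_volume
#' @param units `"g/ml"` for body-weight SUV or `"SUL"` for lean-body-mass
#'   normalized values
#' @export
suv_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                       weight_kg = NA_real_, dose_MBq = NA_real_,
                       units = "g/ml") {
  g <- new_pet_grid(voxels, spacing, origin)
  if (any(!is.finite(g$voxels)) || any(g$voxels < 0)) {
    stop("SUV values must be finite and non-negative", call. = FALSE)
  }
  structure(
    c(g, list(weight_kg = weight_kg, dose_MBq = dose_MBq, units = units)),
    class = c("suv_volume", "pet_volume")
  )
}

#' Construct a biological-target-volume (BTV) mask
#'
#' A binary mask aligned to a parent volume, holding one lesion as a single
#' 26-connected component.
#'
#' @param voxels logical (or 0/1) 3D array
#' @param spacing,origin grid geometry copied from the parent volume
#' @param lesion_id integer lesion identifier
#' @param check if `TRUE`, verify the mask is nonempty and 26-connected
#' @export
btv_mask <- function(voxels, spacing, origin = c(0, 0, 0), lesion_id = 1L,
                     check = TRUE) {
  voxels <- array(as.logical(voxels), dim(voxels))
  g <- new_pet_grid(array(0, dim(voxels)), spacing, origin)
  if (check) {
    if (!any(voxels)) stop("BTV mask must be nonempty", call. = FALSE)
    lab <- label_components26(voxels)
    if (max(lab) != 1L) {
      stop("BTV mask must be a single 26-connected component", call. = FALSE)
    }
  }
  structure(
    list(voxels = voxels, spacing = g$spacing, origin = g$origin,
         lesion_id = as.integer(lesion_id)),
    class = "btv_mask"
  )
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.btv_mask <- function(x, ...) {
  cat(sprintf("<btv_mask> lesion %d, %d voxels (%.3f ml)\n", x$lesion_id,
              sum(x$voxels), sum(x$voxels) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Load a PET volume from disk
#'
#' NIfTI-1 is the supported on-disk format (via RNifti). DICOM series are not
#' read by this package; convert series to NIfTI upstream.
#'
#' @param path path to a NIfTI file
#' @param format `"nifti"`
#' @param dose_MBq,weight_kg optional acquisition metadata, required later for
#'   SUV conversion when absent
#' @return an [activity_volume()]
#' @export
load_volume <- function(path, format = c("nifti", "dicom"),
                        dose_MBq = NA_real_, weight_kg = NA_real_) {
  format <- match.arg(format)
  if (format == "dicom") {
    stop("DICOM series input is not supported; convert to NIfTI first",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim(img))
  sp <- attr(img, "pixdim")[seq_len(3)]
  origin <- tryCatch(RNifti::xform(img)[1:3, 4], error = function(e) c(0, 0, 0))
  if (is.na(dose_MBq) || is.na(weight_kg)) {
    warning("injected dose and/or patient weight not supplied; ",
            "SUV conversion will require explicit parameters", call. = FALSE)
  }
  activity_volume(vox, spacing = sp, origin = origin,
                  dose_MBq = dose_MBq, weight_kg = weight_kg)
}

#' Save any volume or mask as NIfTI-1
#'
#' Masks are written as uint8 {0,1}; scalar volumes as float64 so values
#' round-trip exactly.
#' @param x a `pet_volume` or `btv_mask`
#' @param path output path (`.nii` / `.nii.gz`)
#' @export
save_volume <- function(x, path) {
  dt <- if (inherits(x, "btv_mask")) "uint8" else "double"
  vox <- if (inherits(x, "btv_mask")) array(as.integer(x$voxels), dim(x$voxels)) else x$voxels
  img <- RNifti::asNifti(vox, reference = list(pixdim = c(-1, x$spacing, 1, 1, 1, 1)),
                         datatype = dt)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname save_volume
#' @param mask a [btv_mask()] to save
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "btv_mask"))
  if (!any(mask$voxels)) stop("refusing to save an empty BTV mask", call. = FALSE)
  save_volume(mask, path)
}

#' Load a BTV mask and check alignment against its parent volume
#'
#' @param path NIfTI mask path
#' @param parent the `suv_volume` (or other `pet_volume`) the mask belongs to
#' @param lesion_id identifier to assign
#' @export
load_mask <- function(path, parent, lesion_id = 1L) {
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img) > 0.5, dim(img))
  sp <- attr(img, "pixdim")[seq_len(3)]
  if (!identical(dim(vox), dim(parent$voxels)) ||
      any(abs(sp - parent$spacing) > 1e-4)) {
    stop("mask geometry does not match the parent volume", call. = FALSE)
  }
  btv_mask(vox, spacing = parent$spacing, origin = parent$origin,
           lesion_id = lesion_id)
}

#' Convert activity concentration to body-weight SUV
#'
#' SUV (g/ml) = activity (Bq/ml) / (injected dose (Bq) / body weight (g)).
#' Activity is assumed decay-corrected to a common reference time by the
#' scanner; see [decay_correct()] for an explicit correction.
#'
#' @param vol an [activity_volume()]
#' @param weight_kg body weight, kg; defaults to the volume's metadata
#' @param dose_MBq injected dose, MBq; defaults to the volume's metadata
#' @return a [suv_volume()] in g/ml
#' @export
to_suv <- function(vol, weight_kg = vol$weight_kg, dose_MBq = vol$dose_MBq) {
  stopifnot(inherits(vol, "activity_volume"))
  if (is.na(weight_kg) || is.na(dose_MBq)) {
    stop("weight_kg and dose_MBq are required for SUV conversion", call. = FALSE)
  }
  if (weight_kg <= 0 || dose_MBq <= 0) {
    stop("weight and dose must be positive", call. = FALSE)
  }
  suv <- vol$voxels / ((dose_MBq * 1e6) / (weight_kg * 1e3))
  suv_volume(suv, spacing = vol$spacing, origin = vol$origin,
             weight_kg = weight_kg, dose_MBq = dose_MBq)
}

#' Lean body mass by the James (1976) formula
#'
#' male: 1.10 W - 128 (W/H)^2; female: 1.07 W - 148 (W/H)^2, W in kg, H in cm.
#' @param weight_kg body weight, kg
#' @param height_cm height, cm
#' @param sex `"M"` or `"F"`
#' @return lean body mass, kg
#' @export
lean_body_mass <- function(weight_kg, height_cm, sex = c("M", "F")) {
  sex <- match.arg(sex)
  if (height_cm <= 0 || weight_kg <= 0) {
    stop("weight and height must be positive", call. = FALSE)
  }
  if (sex == "M") 1.10 * weight_kg - 128 * (weight_kg / height_cm)^2
  else            1.07 * weight_kg - 148 * (weight_kg / height_cm)^2
}

#' Convert a body-weight SUV volume to SUL (lean-body-mass SUV)
#'
#' SUL = SUV * LBM / weight, with LBM from [lean_body_mass()].
#'
#' @param vol a [suv_volume()] in g/ml
#' @param sex `"M"` or `"F"`
#' @param height_cm height, cm
#' @param weight_kg weight, kg; defaults to the volume's metadata
#' @return a [suv_volume()] with `units = "SUL"`
#' @export
to_sul <- function(vol, sex, height_cm, weight_kg = vol$weight_kg) {
  stopifnot(inherits(vol, "suv_volume"))
  if (missing(sex) || missing(height_cm)) {
    stop("sex and height_cm must be supplied for SUL normalization", call. = FALSE)
  }
  if (is.na(weight_kg)) stop("weight_kg unknown; supply it explicitly", call. = FALSE)
  lbm <- lean_body_mass(weight_kg, height_cm, sex)
  suv_volume(vol$voxels * lbm / weight_kg, spacing = vol$spacing,
             origin = vol$origin, weight_kg = weight_kg,
             dose_MBq = vol$dose_MBq, units = "SUL")
}

#' Explicit radioactive-decay correction
#'
#' Rescales activity to the injection time for a tracer with the given
#' half-life (default 20.4 min, carbon-11).
#'
#' @param vol an [activity_volume()] with `decay_corrected = FALSE`
#' @param elapsed_min minutes between injection and acquisition
#' @param half_life_min isotope half-life, minutes
#' @export
decay_correct <- function(vol, elapsed_min, half_life_min = 20.4) {
  stopifnot(inherits(vol, "activity_volume"))
  if (isTRUE(vol$decay_corrected)) {
    warning("volume already flagged decay-corrected; returning unchanged",
            call. = FALSE)
    return(vol)
  }
  out <- vol
  out$voxels <- vol$voxels * 2^(elapsed_min / half_life_min)
  out$decay_corrected <- TRUE
  out
}
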