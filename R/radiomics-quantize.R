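# Grey-level quantization of a lesion prior to texture-matrix construction.

#' Quantize in-mask SUV values to discrete grey levels
#'
#' Equal-width binning of the in-mask SUV range into `levels` bins (default
#' 64). The in-mask maximum maps to level `levels`; a constant region maps
#' every voxel to level 1 (zero-range rule). Voxels outside the mask carry NA
#' and are excluded from every texture matrix.
#'
#' @param vol a [suv_volume()]
#' @param mask a [btv_mask()] aligned to `vol`
#' @param levels number of quantization levels
#' @return a `quantized_lesion`: list with `levels` (integer array, NA
#'   outside the mask), `n_levels`, `min_suv`, `max_suv`, `mask`, `spacing`
#' @export
quantize <- function(vol, mask, levels = 64L) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "btv_mask"))
  if (!same_geometry(vol, mask)) stop("volume/mask geometry mismatch", call. = FALSE)
  m <- mask$voxels
  if (!any(m)) stop("mask is empty", call. = FALSE)
  v <- vol$voxels[m]
  lo <- min(v); hi <- max(v)
  lv <- array(NA_integer_, dim(m))
  if (hi > lo) {
    lv[m] <- pmin.int(as.integer(levels),
                      1L + as.integer(floor((v - lo) / (hi - lo) * levels)))
  } else {
    lv[m] <- 1L
  }
  structure(
    list(levels = lv, n_levels = as.integer(levels), min_suv = lo,
         max_suv = hi, mask = m, spacing = mask$spacing),
    class = "quantized_lesion"
  )
}

#' @export
print.quantized_lesion <- function(x, ...) {
  cat(sprintf("<quantized_lesion> %d voxels, %d levels, SUV [%.3g, %.3g]\n",
              sum(x$mask), x$n_levels, x$min_suv, x$max_suv))
  invisible(x)
}
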