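# Feature registry and full per-lesion extraction: 108 named values in fixed
# order — 59 texture features from 9 matrix families plus 49 SUV indices.

registry_env <- new.env(parent = emptyenv())

#' The fixed 108-feature registry
#'
#' Family order and per-family cardinalities: co-occurrence (7),
#' voxel-alignment (11), neighbourhood intensity difference (5), intensity
#' size-zone (11), normalized co-occurrence (6), texture spectrum (2),
#' texture feature coding (4), texture-feature-coding co-occurrence (8),
#' neighbourhood grey-level dependence (5), SUV indices (49). Names are
#' stable column names for downstream tables.
#'
#' @return data.frame with columns `name`, `family`, `family_index`
#' @export
feature_registry <- function() {
  if (!is.null(registry_env$reg)) return(registry_env$reg)
  fam <- list(
    cooc = c("second_angular_moment", "contrast", "entropy", "homogeneity",
             "dissimilarity", "inverse_difference_moment", "correlation"),
    valign = c("short_run_emphasis", "long_run_emphasis",
               "intensity_variability", "run_length_variability",
               "run_percentage", "low_intensity_run_emphasis",
               "high_intensity_run_emphasis",
               "low_intensity_short_run_emphasis",
               "high_intensity_short_run_emphasis",
               "low_intensity_long_run_emphasis",
               "high_intensity_long_run_emphasis"),
    nid = c("coarseness", "contrast", "busyness", "complexity", "strength"),
    szm = c("short_zone_emphasis", "large_zone_emphasis",
            "intensity_variability", "size_zone_variability",
            "zone_percentage", "low_intensity_zone_emphasis",
            "high_intensity_zone_emphasis",
            "low_intensity_short_zone_emphasis",
            "high_intensity_short_zone_emphasis",
            "low_intensity_large_zone_emphasis",
            "high_intensity_large_zone_emphasis"),
    ncooc = c("second_angular_moment", "contrast", "entropy", "homogeneity",
              "inverse_difference_moment", "dissimilarity"),
    tspec = c("max_spectrum", "black_white_symmetry"),
    tfc = c("coarseness", "homogeneity", "mean_convergence", "variance"),
    tfcc = c("second_angular_moment", "contrast", "entropy", "homogeneity",
             "intensity", "inverse_difference_moment", "correlation",
             "variance"),
    ngld = c("small_number_emphasis", "large_number_emphasis",
             "number_nonuniformity", "second_moment", "entropy")
  )
  rows <- do.call(rbind, lapply(names(fam), function(f) {
    data.frame(name = paste0(f, "_", fam[[f]]), family = f,
               family_index = seq_along(fam[[f]]))
  }))
  suv_names <- c("suv_min", "suv_max", "suv_mean", "suv_variance", "suv_sd",
                 "suv_skewness", "suv_kurtosis",
                 "suv_skewness_bias_corrected", "suv_kurtosis_bias_corrected",
                 "tlg", "tumor_volume_ml", "suv_entropy", "sul_peak",
                 "surface_area", "asphericity_1", "asphericity_2",
                 "asphericity_3",
                 paste0("surface_mean_suv_", 1:4),
                 paste0("surface_total_suv_", 1:4),
                 paste0("surface_suv_entropy_", 1:4),
                 paste0("surface_suv_variance_", 1:4),
                 paste0("surface_suv_sd_", 1:4),
                 paste0("surface_suv_nsr_", 1:4),
                 "suv_mean_prod_asphericity", "suv_max_prod_asphericity",
                 "entropy_prod_asphericity", "sul_peak_prod_asphericity",
                 "suv_mean_prod_surface_area", "suv_max_prod_surface_area",
                 "entropy_prod_surface_area", "sul_peak_prod_surface_area")
  rows <- rbind(rows, data.frame(name = suv_names, family = "suv",
                                 family_index = seq_along(suv_names)))
  stopifnot(nrow(rows) == 108, !anyDuplicated(rows$name))
  registry_env$reg <- rows
  rows
}

#' Extract the full 108-feature vector for one lesion
#'
#' Quantizes the in-mask SUVs to `levels` grey levels, builds the nine
#' texture-matrix families, computes the 49 SUV indices, and concatenates
#' everything in registry order. Degenerate lesions (single voxel, too thin
#' for a family's neighbourhood) yield NaN for the affected features, with
#' the reasons recorded in the `nan_reasons` attribute.
#'
#' @param vol a [suv_volume()] in g/ml
#' @param mask a [btv_mask()]
#' @param sul_vol optional SUL volume for SULpeak-based features
#' @param levels quantization levels (default 64)
#' @return named numeric vector of length 108 (class `feature_vector`),
#'   attribute `lesion_id`
#' @export
extract_features <- function(vol, mask, sul_vol = NULL, levels = 64L) {
  q <- quantize(vol, mask, levels)
  reg <- feature_registry()
  fams <- list(
    cooc = cooccurrence_features(q),
    valign = voxel_alignment_features(q),
    nid = nid_features(q),
    szm = size_zone_features(q),
    ncooc = normalized_cooccurrence_features(q),
    tspec = texture_spectrum_features(q),
    tfc = tfc_features(q),
    tfcc = tfcc_features(q),
    ngld = ngld_features(q),
    suv = suv_indices(vol, mask, sul_vol)
  )
  reasons <- character(0)
  vals <- numeric(0)
  for (f in names(fams)) {
    x <- fams[[f]]
    r <- attr(x, "nan_reason")
    if (!is.null(r)) reasons <- c(reasons, stats::setNames(r, f))
    if (f == "suv") {
      if (is.null(sul_vol)) {
        reasons <- c(reasons, suv = "SUL volume absent; SULpeak features NaN")
      }
      vals <- c(vals, stats::setNames(unname(x), names(x)))
    } else {
      vals <- c(vals, stats::setNames(unname(x), paste0(f, "_", names(x))))
    }
  }
  stopifnot(identical(names(vals), reg$name))
  structure(vals, class = "feature_vector", lesion_id = mask$lesion_id,
            nan_reasons = reasons)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> lesion %s, %d features (%d NaN)\n",
              attr(x, "lesion_id"), length(x), sum(is.nan(x))))
  print(utils::head(unclass(x), 10))
  invisible(x)
}

#' Extract features for several lesions into a table
#'
#' @param vol a [suv_volume()]
#' @param masks list of [btv_mask()]
#' @param sul_vol optional SUL volume
#' @param levels quantization levels
#' @return data.frame, one row per lesion, `lesion_id` plus 108 feature
#'   columns in registry order
#' @export
extract_feature_table <- function(vol, masks, sul_vol = NULL, levels = 64L) {
  rows <- lapply(masks, function(m) {
    fv <- extract_features(vol, m, sul_vol, levels)
    cbind(data.frame(lesion_id = attr(fv, "lesion_id")),
          as.data.frame(as.list(unclass(fv)), check.names = FALSE))
  })
  do.call(rbind, rows)
}
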