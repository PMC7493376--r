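# End-to-end workflow: segment -> extract -> (delta) -> select -> classify.
# Each stage is runnable on its own through the exported module functions;
# run_pipeline() chains them, logging a manifest per stage, and writes the
# resolved configuration beside the outputs so every run is reproducible.

default_config <- function() {
  list(
    out_dir = "petrad_run",
    levels = 64L,
    segment = list(suv_stop = 2, radius_mm = 5, curvature = 0.2,
                   max_iter = 300L, max_lesions = 10L,
                   threshold_fraction = 0.4),
    select = list(corr_threshold = 0.9, rpb_threshold = 0.25),
    classify = list(k = 5L, seed = 1L),
    input = list(type = "feature_table")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  known <- names(default_config())
  extra <- setdiff(names(cfg), c(known, "input"))
  if (length(extra) > 0) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Input modes: `input$type = "volumes"` takes a data.frame `volumes` with
#' columns `path`, `patient_id`, `weight_kg`, `dose_MBq` plus a `labels`
#' data.frame (`patient_id`, `label`); each volume is segmented, features
#' are extracted per lesion, then selection and classification run on the
#' patient table. `input$type = "feature_table"` takes `features` (a
#' data.frame with a `label` column, e.g. from [make_feature_cohort()]) and
#' skips the imaging stages. All stage outputs and a manifest are written
#' under `out_dir`.
#'
#' @param config nested list overriding the defaults (see source of
#'   `petrad:::default_config`); may also be a YAML file path
#' @return (invisibly) the output directory; side effects: CSV/JSON outputs
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required to read config files", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(merge_config(default_config(), config))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list())
  writeLines(jsonlite::toJSON(cfg[setdiff(names(cfg), "input")],
                              auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(cfg$out_dir, "config.json"))

  if (identical(cfg$input$type, "volumes")) {
    params <- lac_params(radius_mm = cfg$segment$radius_mm,
                         curvature = cfg$segment$curvature,
                         max_iter = cfg$segment$max_iter)
    rows <- list()
    for (i in seq_len(nrow(cfg$input$volumes))) {
      vinfo <- cfg$input$volumes[i, ]
      act <- load_volume(vinfo$path, dose_MBq = vinfo$dose_MBq,
                         weight_kg = vinfo$weight_kg)
      suv <- to_suv(act)
      ls <- segment_all(suv, params, suv_stop = cfg$segment$suv_stop,
                        max_lesions = cfg$segment$max_lesions,
                        threshold_fraction = cfg$segment$threshold_fraction)
      for (m in ls$masks) {
        save_mask(m, file.path(cfg$out_dir, sprintf("%s_lesion%d.nii.gz",
                                                    vinfo$patient_id,
                                                    m$lesion_id)))
      }
      ft <- extract_feature_table(suv, ls$masks, levels = cfg$levels)
      if (!is.null(ft)) {
        ft$patient_id <- vinfo$patient_id
        rows[[length(rows) + 1]] <- ft
      }
      manifest$stages$segment[[vinfo$patient_id]] <-
        list(n_lesions = length(ls$masks), warnings = ls$warnings)
    }
    feats <- do.call(rbind, rows)
    feats <- merge(feats, cfg$input$labels, by = "patient_id")
    feats$lesion_id <- NULL
    utils::write.csv(feats, file.path(cfg$out_dir, "features.csv"),
                     row.names = FALSE)
    tab <- feats[setdiff(names(feats), "patient_id")]
  } else {
    tab <- cfg$input$features
    utils::write.csv(tab, file.path(cfg$out_dir, "features.csv"),
                     row.names = FALSE)
  }
  if (is.null(tab$label)) {
    stop("no label column; classification requires outcomes", call. = FALSE)
  }

  sel_cfg <- selection_config(corr_threshold = cfg$select$corr_threshold,
                              rpb_threshold = cfg$select$rpb_threshold)
  sel <- select_features(tab, sel_cfg)
  writeLines(jsonlite::toJSON(list(selected = sel$selected,
                                   stats = sel$stats, audit = sel$audit),
                              auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(cfg$out_dir, "selection.json"))
  manifest$stages$select <- list(n_selected = length(sel$selected))

  feats_use <- if (length(sel$selected) > 0) sel$selected
               else setdiff(names(tab), "label")
  rep <- cross_validate(tab, feats_use, k = cfg$classify$k,
                        seed = cfg$classify$seed)
  writeLines(jsonlite::toJSON(list(metrics = as.list(rep$metrics),
                                   auc = rep$auc, auc_ci = rep$auc_ci,
                                   k = rep$k, features = rep$features),
                              auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(cfg$out_dir, "classification.json"))
  utils::write.csv(rep$roc, file.path(cfg$out_dir, "roc.csv"),
                   row.names = FALSE)
  manifest$stages$classify <- list(accuracy = unname(rep$metrics["accuracy"]),
                                   auc = rep$auc)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(cfg$out_dir, "manifest.json"))
  invisible(cfg$out_dir)
}
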