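# Longitudinal per-feature percent change between baseline and follow-up.

#' Per-feature percent change relative to baseline
#'
#' delta(%) = 100 * (follow-up value - baseline value) / baseline value.
#' Features with a zero baseline are undefined and reported as NaN, with the
#' feature names recorded in the `nan_features` attribute.
#'
#' @param baseline,followup named numeric vectors over the same feature
#'   registry (e.g. [extract_features()] outputs)
#' @return named numeric vector of percent changes with attribute
#'   `nan_features`
#' @export
delta_percent <- function(baseline, followup) {
  if (!identical(names(baseline), names(followup))) {
    stop("baseline and follow-up feature registries differ", call. = FALSE)
  }
  b <- as.numeric(baseline)
  f <- as.numeric(followup)
  d <- 100 * (f - b) / b
  d[b == 0] <- NaN
  out <- stats::setNames(d, names(baseline))
  attr(out, "nan_features") <- names(baseline)[b == 0 & !is.na(b)]
  out
}

#' Percent-change table for paired examinations
#'
#' @param baseline_table,followup_table data.frames with an id column plus
#'   feature columns (same registries); rows are matched on `id_col`
#' @param id_col name of the identifier column
#' @return data.frame of per-feature percent change, one row per matched id
#' @export
delta_table <- function(baseline_table, followup_table, id_col = "patient_id") {
  ids <- intersect(baseline_table[[id_col]], followup_table[[id_col]])
  if (length(ids) == 0) stop("no matching ids between examinations", call. = FALSE)
  feats <- setdiff(names(baseline_table), id_col)
  stopifnot(identical(feats, setdiff(names(followup_table), id_col)))
  rows <- lapply(ids, function(id) {
    b <- unlist(baseline_table[baseline_table[[id_col]] == id, feats][1, ])
    f <- unlist(followup_table[followup_table[[id_col]] == id, feats][1, ])
    as.data.frame(as.list(delta_percent(b, f)), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  cbind(stats::setNames(data.frame(ids), id_col), out)
}
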