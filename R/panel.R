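#' ROI time-series panel
#'
#' The raw input of the pipeline: one ROI-by-time numeric matrix per subject
#' plus a binary label (patient = 1, control = 0) and an optional site id.
#' Stored as a tibble with a `series` list-column so the panel pipes through
#' dplyr verbs.
#'
#' @param subject_id Character vector of subject identifiers.
#' @param label Integer/numeric vector of 0/1 labels.
#' @param series List of numeric matrices, all with the same row count
#'   (ROIs); columns are time points.
#' @param site Optional site ids (default 1).
#' @return A `ts_panel` tibble with columns `subject_id`, `label`, `site`,
#'   `series`.
#' @export
ts_panel <- function(subject_id, label, series, site = 1L) {
  if (length(subject_id) != length(series) || length(label) != length(series))
    validation_error("series", "subject_id, label and series lengths differ")
  if (!all(label %in% c(0, 1)))
    validation_error("label", "labels must be binary 0 (control) / 1 (patient)")
  if (!all(vapply(series, is.matrix, logical(1))))
    validation_error("series", "every element must be a numeric matrix")
  rois <- vapply(series, nrow, integer(1))
  if (length(unique(rois)) > 1L)
    validation_error("series", "all subjects must share the same ROI count")
  if (anyNA(unlist(lapply(series, function(m) anyNA(m)))) ||
      any(vapply(series, anyNA, logical(1))))
    validation_error("series", "missing values are not allowed")
  out <- tibble(subject_id = as.character(subject_id),
                label = as.integer(label),
                site = rep_len(as.integer(site), length(series)),
                series = series)
  class(out) <- c("ts_panel", class(out))
  out
}

#' @export
print.ts_panel <- function(x, ...) {
  lens <- vapply(x$series, ncol, integer(1))
  cat(sprintf("<ts_panel> %d subjects (%d patients / %d controls), %d ROIs, series length %s\n",
              nrow(x), sum(x$label == 1L), sum(x$label == 0L),
              n_rois_panel(x),
              if (length(unique(lens)) == 1L) as.character(lens[1])
              else paste0(min(lens), "-", max(lens))))
  NextMethod()
}

n_rois_panel <- function(panel) nrow(panel$series[[1L]])

#' Write / read a time-series cohort as delimited text
#'
#' One tab-delimited matrix per subject (`<subject_id>.tsv`, rows = ROIs,
#' columns = time points), a `subjects.tsv` with ids, labels and sites, and —
#' when ground truth is supplied — a `ground_truth.json` recording planted
#' edges (pairs and flat indices) and target correlations.
#'
#' @param panel A [ts_panel()].
#' @param dir Output directory (created if absent).
#' @param truth Optional `ground_truth` from [generate_cohort()].
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a [ts_panel()].
#' @export
write_cohort <- function(panel, dir, truth = NULL) {
  stopifnot(inherits(panel, "ts_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in seq_len(nrow(panel))) {
    utils::write.table(panel$series[[s]],
                       file.path(dir, paste0(panel$subject_id[s], ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  readr::write_tsv(dplyr::select(as_tibble(panel), -"series"),
                   file.path(dir, "subjects.tsv"), progress = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(planted_edges = unclass(truth$planted_edges),
           edge_flat = truth$edge_flat, planted_rois = truth$planted_rois,
           r_base = truth$r_base, r_alt = truth$r_alt, n_rois = truth$n_rois),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- readr::read_tsv(file.path(dir, "subjects.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  series <- lapply(meta$subject_id, function(id) {
    f <- file.path(dir, paste0(id, ".tsv"))
    if (!file.exists(f)) data_error(sprintf("missing series file `%s`", f))
    as.matrix(utils::read.table(f, sep = "\t"))
  })
  series <- lapply(series, function(m) {
    dimnames(m) <- NULL
    m
  })
  ts_panel(meta$subject_id, meta$label, series,
           site = if ("site" %in% names(meta)) meta$site else 1L)
}
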