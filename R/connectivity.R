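#' Normalize and slice ROI time series to a uniform length
#'
#' Z-scores every ROI series (mean 0, sd 1) and truncates each subject's
#' series to its first `target_length` time points, so that Pearson
#' correlations are comparable across subjects and multi-site affine
#' mean/scale shifts are removed. A constant (zero-variance) series cannot
#' be z-scored; it is mapped to all zeros with a warning, and its edges will
#' later receive correlation 0.
#'
#' @param panel A [ts_panel()].
#' @param target_length `"min"` (default: the shortest series in the panel)
#'   or an integer `>= 10` no longer than every subject's series.
#' @return A [ts_panel()] with z-scored, equal-length series.
#' @export
normalize_and_slice <- function(panel, target_length = "min") {
  stopifnot(inherits(panel, "ts_panel"))
  lens <- vapply(panel$series, ncol, integer(1))
  if (identical(target_length, "min")) target_length <- min(lens)
  target_length <- check_count(target_length, "target_length", min = 1L)
  if (target_length < 10L)
    validation_error("target_length",
                     "must be >= 10 for stable correlation estimates")
  if (target_length > min(lens))
    validation_error("target_length",
                     sprintf("exceeds shortest series length (%d)", min(lens)))
  n_const <- 0L
  out <- lapply(panel$series, function(m) {
    m <- m[, seq_len(target_length), drop = FALSE]
    sds <- apply(m, 1L, stats::sd)
    mus <- rowMeans(m)
    z <- (m - mus) / ifelse(sds > 0, sds, 1)
    if (any(sds == 0)) {
      z[sds == 0, ] <- 0
      n_const <<- n_const + sum(sds == 0)
    }
    z
  })
  if (n_const > 0L)
    warn(sprintf("%d constant ROI series mapped to zero during normalization",
                 n_const))
  panel$series <- out
  panel
}

#' Compute the functional-connectivity feature table
#'
#' Computes, for every subject, the Pearson correlation of each ROI pair,
#' producing the subjects-by-edges feature table the classifier consumes.
#' With the 90-ROI AAL cerebrum each subject yields a 4,005-dimensional
#' feature vector (one per unordered pair). Edge columns follow the package
#' flat-edge ordering (see [edge_index]) and are named `ROIa_ROIb`. Edges
#' touching a zero-variance series get correlation 0 (flagged via a
#' warning), never `NaN`.
#'
#' @param panel A [ts_panel()], normally after [normalize_and_slice()].
#' @return An `fc_dataset`: a tibble with `subject_id`, `label`, `site`
#'   then one column per edge, with attribute `n_rois`.
#' @examples
#' spec <- synthetic_spec(n_per_group = 3, n_rois = 5, n_timepoints = 20,
#'                        planted_edges = cbind(1, 2), seed = 1)
#' fc <- compute_fc(generate_cohort(spec)$panel)
#' dim(fc_matrix(fc))  # 6 subjects x 10 edges
#' @export
compute_fc <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  lens <- vapply(panel$series, ncol, integer(1))
  if (length(unique(lens)) != 1L)
    data_error("series lengths differ; run normalize_and_slice() first")
  R <- n_rois_panel(panel)
  n_zero <- 0L
  feats <- vapply(panel$series, function(m) {
    C <- suppressWarnings(cor(t(m)))
    if (anyNA(C)) {
      n_zero <<- n_zero + 1L
      C[is.na(C)] <- 0
    }
    # column-major lower triangle of a symmetric matrix = row-major upper
    # triangle: exactly the package flat-edge order
    C[lower.tri(C)]
  }, numeric(n_edges(R)))
  feats <- if (n_edges(R) == 1L) matrix(feats, ncol = 1L) else t(feats)
  if (n_zero > 0L)
    warn(sprintf("%d subject(s) had zero-variance series; affected edges set to r = 0",
                 n_zero))
  colnames(feats) <- edge_names(R)
  out <- dplyr::bind_cols(
    dplyr::select(as_tibble(panel), "subject_id", "label", "site"),
    as_tibble(feats))
  new_fc_dataset(out, R)
}

new_fc_dataset <- function(tbl, n_rois) {
  attr(tbl, "n_rois") <- as.integer(n_rois)
  class(tbl) <- unique(c("fc_dataset", class(tbl)))
  tbl
}

#' Accessors for an fc_dataset
#'
#' `fc_matrix()` returns the subjects-by-edges numeric feature matrix,
#' `fc_labels()` the integer label vector, and `fc_n_rois()` the ROI count.
#'
#' @param fc An `fc_dataset` from [compute_fc()] or [read_fc()].
#' @return See description.
#' @export
fc_matrix <- function(fc) {
  as.matrix(as_tibble(fc)[, setdiff(names(fc), c("subject_id", "label", "site"))])
}

#' @rdname fc_matrix
#' @export
fc_labels <- function(fc) fc$label

#' @rdname fc_matrix
#' @export
fc_n_rois <- function(fc) {
  R <- attr(fc, "n_rois")
  if (is.null(R)) {
    E <- ncol(fc) - sum(c("subject_id", "label", "site") %in% names(fc))
    R <- as.integer((1 + sqrt(1 + 8 * E)) / 2)
  }
  R
}

#' @export
print.fc_dataset <- function(x, ...) {
  cat(sprintf("<fc_dataset> %d subjects x %d edges (%d ROIs)\n",
              nrow(x), n_edges(fc_n_rois(x)), fc_n_rois(x)))
  NextMethod()
}

#' Write / read the connectivity table
#'
#' The table is stored as a single TSV (`subject_id`, `label`, `site`, then
#' one named column per edge) with a companion JSON documenting the edge
#' ordering convention so the file is self-describing.
#'
#' @param fc An `fc_dataset`.
#' @param path Output TSV path; the companion JSON is `<path>.meta.json`.
#' @return `write_fc()` returns `path` invisibly; `read_fc()` an
#'   `fc_dataset`.
#' @export
write_fc <- function(fc, path) {
  readr::write_tsv(as_tibble(fc), path, progress = FALSE)
  jsonlite::write_json(
    list(n_rois = fc_n_rois(fc), n_edges = n_edges(fc_n_rois(fc)),
         edge_order = "1-based row-major strict upper triangle, i < j"),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fc
#' @export
read_fc <- function(path) {
  if (!file.exists(path)) data_error(sprintf("missing FC table `%s`", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tbl$label <- as.integer(tbl$label)
  if ("site" %in% names(tbl)) tbl$site <- as.integer(tbl$site)
  meta_path <- paste0(path, ".meta.json")
  R <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)$n_rois else NULL
  if (is.null(R)) {
    E <- ncol(tbl) - sum(c("subject_id", "label", "site") %in% names(tbl))
    R <- (1 + sqrt(1 + 8 * E)) / 2
  }
  new_fc_dataset(tbl, R)
}
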