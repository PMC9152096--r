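#' Select superior ensemble members
#'
#' Sorts screened members by accuracy (descending) and keeps those whose
#' accuracy is strictly greater than `threshold` (default 0.75). Only these
#' high-accuracy members contribute to feature-frequency biomarker ranking:
#' a member's accuracy certifies that its random feature subspace carries
#' discriminative signal. Validation (S2) accuracy is used by default so
#' that test labels never influence feature discovery; set
#' `accuracies` to substitute another reading (e.g. per-member test
#' accuracy) of the same length as the member list.
#'
#' @param cluster A screened `svm_cluster`.
#' @param threshold Strict lower bound on accuracy (default 0.75).
#' @param accuracies Optional numeric override, one value per member.
#' @return An `svm_cluster` containing only the superior members, sorted by
#'   accuracy descending.
#' @export
superior_members <- function(cluster, threshold = 0.75, accuracies = NULL) {
  stopifnot(inherits(cluster, "svm_cluster"))
  if (!cluster$screened) data_error("cluster must be screened first")
  acc <- if (is.null(accuracies))
    vapply(cluster$members, `[[`, numeric(1), "validation_accuracy")
  else {
    if (length(accuracies) != length(cluster$members))
      validation_error("accuracies", "must have one value per member")
    accuracies
  }
  keep <- which(acc > threshold)
  if (length(keep) == 0L)
    empty_error(sprintf(
      "no member exceeds accuracy %.2f; reduce the superior threshold", threshold))
  ord <- keep[order(acc[keep], decreasing = TRUE)]
  cluster$members <- cluster$members[ord]
  cluster$k <- length(ord)
  cluster$superior_threshold <- threshold
  cluster
}

#' Edge appearance frequencies across superior members
#'
#' Counts, for every edge, the number of superior members whose random
#' feature subspace contains it. Edges that genuinely separate the groups
#' make the members holding them accurate — hence superior — so
#' discriminative edges accumulate high counts. The table total is exactly
#' `(number of superior members) * d`.
#'
#' @param cluster An `svm_cluster` (normally the output of
#'   [superior_members()]).
#' @return A `feature_frequency_table` tibble: `edge`, `roi_a`, `roi_b`,
#'   `count`, with attributes `n_superior` and `d`.
#' @export
feature_frequencies <- function(cluster) {
  stopifnot(inherits(cluster, "svm_cluster"))
  if (length(cluster$members) == 0L) empty_error("no members to tally")
  E <- cluster$n_edges
  counts <- tabulate(unlist(lapply(cluster$members, `[[`, "feature_idx")),
                     nbins = E)
  out <- edge_pairs(cluster$n_rois)
  out$count <- as.integer(counts)
  attr(out, "n_superior") <- length(cluster$members)
  attr(out, "d") <- cluster$d
  class(out) <- c("feature_frequency_table", class(out))
  out
}

#' Extract the optimal edge set
#'
#' The `k` edges with the highest appearance counts are the "optimal
#' features" — the most discriminative functional connections. Ties at the
#' selection boundary are broken by ascending flat edge index, so output is
#' bit-stable. If fewer than `k` edges have nonzero counts, all nonzero
#' edges are returned with a warning.
#'
#' @param freq A [feature_frequencies()] table.
#' @param k Number of edges to keep (the reference run uses 148, its tuned
#'   subspace dimensionality).
#' @return Integer vector of flat edge indices, highest count first.
#' @export
top_features <- function(freq, k = 148L) {
  k <- check_count(k, "k", min = 1L)
  if (k > nrow(freq)) validation_error("k", "cannot exceed the edge count")
  ord <- order(-freq$count, freq$edge)
  nonzero <- sum(freq$count > 0L)
  if (nonzero < k) {
    warn(sprintf("only %d edges have nonzero counts (requested %d)", nonzero, k))
    k <- nonzero
  }
  freq$edge[ord[seq_len(k)]]
}

#' ROI weights from the optimal edge set
#'
#' Each optimal edge increments the weight of both its endpoint ROIs by 1;
#' an ROI's weight is therefore its appearance frequency among the optimal
#' functional connections, and the highest-weight ROIs are nominated as
#' candidate pathogenic regions. Weights always sum to twice the number of
#' optimal edges.
#'
#' @param edges Integer vector of flat edge indices (from [top_features()]).
#' @param n_rois ROI count that defines the edge indexing (default 90).
#' @param labels Label table with `index` and `short_name` columns; default
#'   [aal_labels()] when `n_rois` is 90.
#' @return An `roi_weight_table` tibble: `roi`, `name`, `weight`, `rank`
#'   (competition ranking, ties share a rank), sorted by weight descending
#'   then ROI index.
#' @export
roi_weights <- function(edges, n_rois = 90L, labels = NULL) {
  if (length(edges) == 0L) validation_error("edges", "must be non-empty")
  pairs <- edge_to_rois(edges, n_rois)
  w <- tabulate(c(pairs$roi_a, pairs$roi_b), nbins = n_rois)
  nm <- if (is.null(labels)) roi_names(n_rois) else labels$short_name
  out <- tibble(roi = seq_len(n_rois), name = nm, weight = as.integer(w))
  out <- dplyr::arrange(out, desc(.data$weight), .data$roi)
  out$rank <- rank(-out$weight, ties.method = "min")
  class(out) <- c("roi_weight_table", class(out))
  out
}

#' @rdname roi_weights
#' @param weights An `roi_weight_table`.
#' @param top_k Number of top-ranked ROIs to return.
#' @export
rank_regions <- function(weights, top_k = 10L) {
  top_k <- check_count(top_k, "top_k", min = 1L)
  utils::head(weights, top_k)
}

#' Export / read a connectome edge list
#'
#' Writes the `top_n` highest-frequency edges as a plain-text edge list
#' (`<stem>_edges.tsv`: ROI names and frequency) plus a node table
#' (`<stem>_nodes.tsv`: ROI name and weight restricted to the exported
#' edges), a format connectome viewers and graph tools ingest directly.
#'
#' @param freq A [feature_frequencies()] table.
#' @param stem Output path stem.
#' @param top_n Number of edges to export (default 20).
#' @param labels Optional label table (see [roi_weights()]).
#' @return `export_connectome()` returns the stem invisibly;
#'   `read_connectome()` returns `list(edges = <tibble>, nodes = <tibble>)`.
#' @export
export_connectome <- function(freq, stem, top_n = 20L, labels = NULL) {
  top_n <- check_count(top_n, "top_n", min = 1L)
  if (top_n > nrow(freq)) validation_error("top_n", "cannot exceed edge count")
  n_rois <- max(freq$roi_b)
  sel <- top_features(freq, k = top_n)
  pairs <- edge_to_rois(sel, n_rois)
  nm <- if (is.null(labels)) roi_names(n_rois) else labels$short_name
  edges <- tibble(edge = sel, roi_a = nm[pairs$roi_a], roi_b = nm[pairs$roi_b],
                  frequency = freq$count[match(sel, freq$edge)])
  w <- roi_weights(sel, n_rois = n_rois, labels = labels)
  nodes <- dplyr::filter(as_tibble(w), .data$weight > 0L)[, c("name", "weight")]
  readr::write_tsv(edges, paste0(stem, "_edges.tsv"), progress = FALSE)
  readr::write_tsv(nodes, paste0(stem, "_nodes.tsv"), progress = FALSE)
  invisible(stem)
}

#' @rdname export_connectome
#' @export
read_connectome <- function(stem) {
  edges <- readr::read_tsv(paste0(stem, "_edges.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  nodes <- readr::read_tsv(paste0(stem, "_nodes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  edges$edge <- as.integer(edges$edge)
  edges$frequency <- as.integer(edges$frequency)
  nodes$weight <- as.integer(nodes$weight)
  list(edges = edges, nodes = nodes)
}
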