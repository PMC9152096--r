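#' Flat edge indexing for ROI pairs
#'
#' Every unordered ROI pair (an edge of the functional-connectivity network)
#' is assigned a flat index. The convention, fixed across the whole package,
#' is 1-based row-major enumeration of the strict upper triangle: for `R`
#' ROIs, edge 1 is (1,2), edge 2 is (1,3), ..., edge `R-1` is (1,R), edge `R`
#' is (2,3), and edge `R(R-1)/2` is (R-1,R). With the 90-ROI AAL cerebrum
#' this yields the 4,005 features of the connectivity vector. All frequency
#' tables, feature subsets and exports rely on this ordering being stable.
#'
#' @param i,j ROI indices, `1 <= i < j <= n_rois`. Vectorised.
#' @param e Flat edge indices in `1..n_rois*(n_rois-1)/2`. Vectorised.
#' @param n_rois Number of ROIs (default 90).
#' @return `rois_to_edge()` returns integer flat indices; `edge_to_rois()`
#'   returns a tibble with columns `edge`, `roi_a`, `roi_b` (`roi_a < roi_b`);
#'   `n_edges()` returns `n_rois*(n_rois-1)/2`.
#' @examples
#' n_edges(90)                 # 4005
#' rois_to_edge(1, 2)          # 1
#' edge_to_rois(4005)          # ROIs 89, 90
#' @name edge_index
NULL

#' @rdname edge_index
#' @export
n_edges <- function(n_rois) {
  n_rois <- check_count(n_rois, "n_rois", min = 2L)
  as.integer(n_rois * (n_rois - 1L) / 2L)
}

#' @rdname edge_index
#' @export
rois_to_edge <- function(i, j, n_rois = 90L) {
  n_rois <- check_count(n_rois, "n_rois", min = 2L)
  bad <- i >= j | i < 1L | j > n_rois | i != floor(i) | j != floor(j)
  if (any(bad))
    validation_error("i,j", sprintf("need 1 <= i < j <= %d", n_rois))
  i <- as.integer(i); j <- as.integer(j)
  # edges in rows 1..i-1: sum_{a<i} (R - a)
  before <- (i - 1L) * n_rois - (i - 1L) * i / 2
  as.integer(before + (j - i))
}

#' @rdname edge_index
#' @export
edge_to_rois <- function(e, n_rois = 90L) {
  n_rois <- check_count(n_rois, "n_rois", min = 2L)
  E <- n_edges(n_rois)
  if (any(e < 1L | e > E | e != floor(e)))
    validation_error("e", sprintf("flat edge index must be in 1..%d", E))
  e <- as.integer(e)
  # cumulative edge count after finishing row i
  cum <- cumsum((n_rois - 1L):1L)
  i <- findInterval(e, cum, left.open = TRUE) + 1L
  before <- (i - 1L) * n_rois - (i - 1L) * i / 2
  j <- as.integer(e - before + i)
  tibble(edge = e, roi_a = as.integer(i), roi_b = j)
}

# matrix of all (roi_a, roi_b) pairs in flat-edge order
edge_pairs <- function(n_rois) {
  edge_to_rois(seq_len(n_edges(n_rois)), n_rois)
}

# display name for each edge, e.g. "LING.R_SFGmed.R"
edge_names <- function(n_rois) {
  nm <- roi_names(n_rois)
  p <- edge_pairs(n_rois)
  paste(nm[p$roi_a], nm[p$roi_b], sep = "_")
}
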