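#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy / glance methods
#'
#' broom-style summaries: `tidy()` returns one row per member, grid point,
#' method or ROI; `glance()` a one-row configuration/result summary.
#'
#' @param x An `svm_cluster`, `sweep_result`, `benchmark_result` or
#'   `roi_weight_table`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy svm_cluster
#' @export
tidy.svm_cluster <- function(x, ...) {
  dplyr::bind_rows(lapply(x$members, function(mb) {
    tibble(member = mb$index, seed = mb$seed,
           n_samples = length(mb$sample_idx),
           n_features = length(mb$feature_idx),
           validation_accuracy = mb$validation_accuracy)
  }))
}

#' @rdname tidiers
#' @method glance svm_cluster
#' @export
glance.svm_cluster <- function(x, ...) {
  tibble(n = x$n, k = x$k, d = x$d, M = x$M, kernel = x$kernel,
         cost = x$cost, screen_threshold = x$screen_threshold,
         screened = x$screened, seed = x$seed, n_edges = x$n_edges)
}

#' @rdname tidiers
#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) {
  out <- x$results
  names(out)[names(out) == "value"] <- x$parameter
  out
}

#' @rdname tidiers
#' @method glance sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  tibble(parameter = x$parameter, selected = x$selected, rule = x$rule,
         n_grid = nrow(x$results),
         best_accuracy = max(x$results$mean_accuracy))
}

#' @rdname tidiers
#' @method tidy benchmark_result
#' @export
tidy.benchmark_result <- function(x, ...) x$accuracies

#' @rdname tidiers
#' @method glance benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$accuracies, .data$method),
                   mean_accuracy = mean(.data$accuracy),
                   sd_accuracy = sd(.data$accuracy),
                   repeats = dplyr::n(), .groups = "drop")
}
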