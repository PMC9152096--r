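#' Selection rules for parameter sweeps
#'
#' Pure functions of an accuracy curve, unit-testable without any training.
#'
#' `select_stable()` formalizes "accuracy has stopped improving": it returns
#' the smallest grid value at which a window of `w` consecutive accuracies
#' (starting there) has range `< tol`. If no window qualifies, the largest
#' grid value is returned with a warning.
#'
#' `select_argmax()` returns the grid value with the highest accuracy, ties
#' broken toward the smaller (cheaper) value.
#'
#' @param values Ascending grid values.
#' @param accuracy Accuracies, one per grid value.
#' @param w Window length (default 5).
#' @param tol Maximum accuracy range inside a stable window (default 0.02).
#' @return The selected grid value.
#' @examples
#' select_stable(1:10, c(0.5, 0.6, 0.7, rep(0.8, 7)), w = 3, tol = 0.01)  # 4
#' select_argmax(c(10, 20, 30), c(0.7, 0.9, 0.9))                        # 20
#' @export
select_stable <- function(values, accuracy, w = 5L, tol = 0.02) {
  stopifnot(length(values) == length(accuracy), !is.unsorted(values))
  w <- check_count(w, "w", min = 1L)
  if (length(values) < w) {
    warn("grid shorter than the stability window; returning the grid maximum")
    return(values[length(values)])
  }
  for (i in seq_len(length(values) - w + 1L)) {
    win <- accuracy[i:(i + w - 1L)]
    if (diff(range(win)) < tol) return(values[i])
  }
  warn("no stable window found; returning the grid maximum")
  values[length(values)]
}

#' @rdname select_stable
#' @export
select_argmax <- function(values, accuracy) {
  stopifnot(length(values) == length(accuracy))
  best <- which(accuracy == max(accuracy))
  values[best[which.min(values[best])]]
}

sweep_engine <- function(fc, split, grid, repeats, seed, build_args) {
  rows <- purrr::map(seq_along(grid), function(gi) {
    accs <- vapply(seq_len(repeats), function(r) {
      args <- c(list(fc = fc, split = split,
                     seed = derive_seed(seed, gi, stream = r)),
                build_args(grid[gi]))
      cl <- tryCatch(screen_cluster(do.call(build_cluster, args), fc),
                     rsvmc_empty_error = function(e) NULL)
      if (is.null(cl)) return(NA_real_)
      evaluate_cluster(cl, fc)$accuracy
    }, numeric(1))
    tibble(value = grid[gi], mean_accuracy = mean(accs, na.rm = TRUE),
           sd_accuracy = if (repeats > 1L) sd(accs, na.rm = TRUE) else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Sweep the ensemble size n
#'
#' Re-trains and evaluates the screened cluster over a grid of ensemble
#' sizes (the reference protocol sweeps 5 to 600 in steps of 5) with the
#' subspace dimensionality `d` held fixed, then picks the smallest `n` at
#' which the accuracy curve has stabilized (see [select_stable()]). The same
#' subject split is reused at every grid point so the curve is comparable;
#' repeats re-randomize only member construction.
#'
#' @param fc An `fc_dataset`.
#' @param split A [split_dataset()] result shared across grid points.
#' @param d Fixed subspace dimensionality.
#' @param grid Ascending integer grid of ensemble sizes.
#' @param repeats Cluster rebuilds averaged per grid point (default 5).
#' @param w,tol Stability-rule parameters, see [select_stable()].
#' @param seed Master seed.
#' @param ... Passed to [build_cluster()] (e.g. `M`, `kernel`, `cost`).
#' @return A `sweep_result`: list with `results` (tibble `value`,
#'   `mean_accuracy`, `sd_accuracy`, `selected`), `selected`, `parameter`
#'   and the selection rule.
#' @export
sweep_n <- function(fc, split, d, grid = seq(5L, 600L, by = 5L),
                    repeats = 5L, w = 5L, tol = 0.02, seed = 1L, ...) {
  if (is.unsorted(grid)) validation_error("grid", "must be ascending")
  extra <- list(...)
  res <- sweep_engine(fc, split, grid, repeats, seed,
                      function(g) c(list(n = g, d = d), extra))
  sel <- select_stable(res$value, res$mean_accuracy, w = w, tol = tol)
  new_sweep_result(res, sel, "n", "stable_window", list(w = w, tol = tol))
}

#' Sweep the subspace dimensionality d
#'
#' Re-trains and evaluates the screened cluster over a grid of subspace
#' dimensionalities (the reference protocol starts at 70, roughly the
#' square root of the 4,005 edges, and sweeps to 300 in steps of 2) with
#' the ensemble size `n` fixed, selecting the `d` with the highest mean
#' accuracy (ties toward smaller `d`).
#'
#' @inheritParams sweep_n
#' @param n Fixed ensemble size.
#' @param grid Grid of dimensionalities within `[1, E]`.
#' @return A `sweep_result`; see [sweep_n()].
#' @export
sweep_d <- function(fc, split, n, grid = seq(70L, 300L, by = 2L),
                    repeats = 5L, seed = 1L, ...) {
  E <- n_edges(fc_n_rois(fc))
  if (any(grid < 1L | grid > E))
    validation_error("grid", sprintf("must lie within [1, %d]", E))
  extra <- list(...)
  res <- sweep_engine(fc, split, grid, repeats, seed,
                      function(g) c(list(n = n, d = g), extra))
  sel <- select_argmax(res$value, res$mean_accuracy)
  new_sweep_result(res, sel, "d", "argmax", list())
}

new_sweep_result <- function(results, selected, parameter, rule, rule_params) {
  results$selected <- results$value == selected
  structure(list(results = results, selected = selected, parameter = parameter,
                 rule = rule, rule_params = rule_params),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over %d grid points; selected %s = %d (%s)\n",
              x$parameter, nrow(x$results), x$parameter, x$selected, x$rule))
  invisible(x)
}

#' Write a sweep result as TSV + JSON summary
#'
#' @param sweep A `sweep_result`.
#' @param path Output TSV path; the JSON summary is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  readr::write_tsv(sweep$results, path, progress = FALSE)
  jsonlite::write_json(c(list(parameter = sweep$parameter,
                              selected = sweep$selected, rule = sweep$rule),
                         sweep$rule_params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
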