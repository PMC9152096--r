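#' Stratified train / validation / test split
#'
#' Splits subjects into a training set (S1), a validation set used to screen
#' ensemble members (S2) and a held-out test set (S3), preserving the
#' patient/control proportion within each set. The default 4:1:5 ratio
#' mirrors a case-control design in which half the cohort is held out for
#' testing. Set sizes follow largest-remainder rounding of the ratios on
#' the whole cohort; within classes, floor quotas are topped up by
#' descending fractional part under those set totals, keeping every set
#' class-balanced to within one subject. Sizes are therefore deterministic;
#' the seed only shuffles which subject lands where.
#'
#' @param fc An `fc_dataset` (or any tibble with a binary `label` column).
#' @param ratios Numeric length-3 vector of set proportions; normalized to
#'   sum to 1. Default `c(4, 1, 5)`.
#' @param seed Integer seed for the within-class shuffle.
#' @return A `dataset_split`: list with integer row-index vectors `train`,
#'   `validation`, `test`, plus `ratios` and `seed`.
#' @examples
#' fc <- tibble::tibble(label = rep(c(0, 1), each = 5))
#' lengths(split_dataset(fc, seed = 1)[1:3])  # 4 / 1 / 5
#' @export
split_dataset <- function(fc, ratios = c(4, 1, 5), seed = 1L) {
  if (length(ratios) != 3L || any(!is.finite(ratios)) || any(ratios < 0) ||
      sum(ratios) <= 0)
    validation_error("ratios", "must be 3 non-negative numbers with positive sum")
  ratios <- ratios / sum(ratios)
  labels <- fc$label
  if (any(table(labels) < 2L))
    data_error("need at least 2 subjects per class to split")
  set.seed(seed)
  classes <- sort(unique(labels))
  counts <- stratified_allocation(vapply(classes, function(cl)
    sum(labels == cl), integer(1)), ratios)
  idx <- list(train = integer(), validation = integer(), test = integer())
  for (ci in seq_along(classes)) {
    rows <- sample(which(labels == classes[ci]))
    ends <- cumsum(counts[ci, ])
    idx$train <- c(idx$train, rows[seq_len(counts[ci, 1L])])
    if (counts[ci, 2L] > 0L)
      idx$validation <- c(idx$validation, rows[(ends[1L] + 1L):ends[2L]])
    if (counts[ci, 3L] > 0L)
      idx$test <- c(idx$test, rows[(ends[2L] + 1L):ends[3L]])
  }
  structure(list(train = sort(idx$train), validation = sort(idx$validation),
                 test = sort(idx$test), ratios = ratios, seed = as.integer(seed)),
            class = "dataset_split")
}

# largest-remainder allocation of each set's total size across sets
largest_remainder <- function(n, p) {
  quota <- n * p
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# class-by-set allocation: set totals follow largest remainder on the whole
# cohort; per-class floor quotas get their leftovers by descending fractional
# part, constrained to the set totals, so each set stays class-balanced to
# within one subject while set sizes match the cohort-level rounding
stratified_allocation <- function(class_sizes, p) {
  totals <- largest_remainder(sum(class_sizes), p)
  quota <- outer(class_sizes, p)
  base <- floor(quota)
  cells <- order(quota - base, decreasing = TRUE)
  class_left <- class_sizes - rowSums(base)
  set_left <- totals - colSums(base)
  for (cell in cells) {
    ci <- (cell - 1L) %% nrow(base) + 1L
    si <- (cell - 1L) %/% nrow(base) + 1L
    if (class_left[ci] > 0L && set_left[si] > 0L) {
      base[ci, si] <- base[ci, si] + 1
      class_left[ci] <- class_left[ci] - 1L
      set_left[si] <- set_left[si] - 1L
    }
  }
  storage.mode(base) <- "integer"
  base
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}
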