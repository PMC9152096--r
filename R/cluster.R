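#' Build a random SVM cluster
#'
#' Constructs the ensemble at the heart of the pipeline: `n` support vector
#' machines, each trained on `M` subjects drawn at random from the training
#' set and a random `d`-of-`E` feature subspace (edges drawn without
#' replacement). Randomizing both axes diversifies the members; the features
#' a member happens to hold are what later drives biomarker discovery, so
#' each member records its sample and feature indices. Per-member randomness
#' comes from a documented seed stream derived from `seed` and the member
#' index, making builds reproducible and order-independent.
#'
#' @param fc An `fc_dataset`.
#' @param split A [split_dataset()] result; members train on `split$train`.
#' @param n Number of members.
#' @param d Subspace dimensionality (features per member), `1 <= d <= E`.
#' @param M Subjects per member. Default `ceiling(0.8 * |S1|)` drawn without
#'   replacement; set `replace = TRUE` (with `M = |S1|`) for bootstrap
#'   resampling.
#' @param kernel,cost Base-learner settings passed to [e1071::svm()].
#'   Default linear kernel with unit cost: correlation features are
#'   near-linear and a linear margin keeps the feature-frequency reading
#'   clean.
#' @param replace Sample subjects with replacement?
#' @param seed Master seed.
#' @param max_retries Resampling attempts when a member's subject draw
#'   contains a single class.
#' @return An `svm_cluster` object: member list (each with `sample_idx`,
#'   `feature_idx`, fitted model, `seed`, `validation_accuracy`), the split,
#'   and the configuration.
#' @seealso [screen_cluster()], [predict.svm_cluster()], [evaluate_cluster()]
#' @export
build_cluster <- function(fc, split, n = 360L, d = 148L, M = NULL,
                          kernel = "linear", cost = 1, replace = FALSE,
                          seed = 1L, max_retries = 100L) {
  n <- check_count(n, "n", min = 1L)
  E <- n_edges(fc_n_rois(fc))
  d <- check_count(d, "d", min = 1L)
  if (d > E) validation_error("d", sprintf("cannot exceed E = %d", E))
  s1 <- split$train
  if (is.null(M)) M <- ceiling(0.8 * length(s1))
  M <- check_count(M, "M", min = 2L)
  if (!replace && M > length(s1))
    validation_error("M", sprintf("cannot exceed |S1| = %d without replacement",
                                  length(s1)))
  X <- fc_matrix(fc)
  y <- as_label_factor(fc_labels(fc))
  members <- vector("list", n)
  for (m in seq_len(n)) {
    mseed <- derive_seed(seed, m)
    set.seed(mseed)
    sample_idx <- NULL
    for (try in seq_len(max_retries)) {
      cand <- sort(sample(s1, M, replace = replace))
      if (length(unique(y[cand])) == 2L) {
        sample_idx <- cand
        break
      }
    }
    if (is.null(sample_idx))
      data_error(sprintf(
        "member %d: could not draw a subject subset containing both classes after %d tries",
        m, max_retries))
    feature_idx <- sort(sample.int(E, d, replace = FALSE))
    model <- e1071::svm(x = X[sample_idx, feature_idx, drop = FALSE],
                        y = y[sample_idx], kernel = kernel, cost = cost,
                        scale = FALSE)
    members[[m]] <- list(index = m, seed = mseed, sample_idx = sample_idx,
                         feature_idx = feature_idx, model = model,
                         validation_accuracy = NA_real_)
  }
  structure(list(members = members, n = n, k = NA_integer_, d = d, M = M,
                 kernel = kernel, cost = cost, replace = replace,
                 screen_threshold = NA_real_, split = split,
                 seed = as.integer(seed), n_edges = E,
                 n_rois = fc_n_rois(fc), screened = FALSE),
            class = "svm_cluster")
}

member_predict <- function(member, X) {
  predict(member$model, X[, member$feature_idx, drop = FALSE])
}

#' Screen ensemble members by validation accuracy
#'
#' Evaluates every member on the validation set S2 (each member using only
#' its own feature subspace), records the accuracy, and deletes members
#' whose accuracy falls strictly below `threshold` — such members do worse
#' than guessing and would degrade the majority vote. Members at exactly the
#' threshold are retained. The surviving count `k` is recorded.
#'
#' @param cluster An unscreened [build_cluster()] result.
#' @param fc The `fc_dataset` the cluster was built from.
#' @param threshold Deletion threshold on validation accuracy (default 0.5).
#' @return The screened `svm_cluster` (members carry
#'   `validation_accuracy`; `k <= n`).
#' @export
screen_cluster <- function(cluster, fc, threshold = 0.5) {
  stopifnot(inherits(cluster, "svm_cluster"))
  s2 <- cluster$split$validation
  if (length(s2) == 0L) data_error("validation set is empty")
  X <- fc_matrix(fc)
  y <- as_label_factor(fc_labels(fc))[s2]
  Xv <- X[s2, , drop = FALSE]
  members <- lapply(cluster$members, function(mb) {
    mb$validation_accuracy <- mean(member_predict(mb, Xv) == y)
    mb
  })
  keep <- vapply(members, function(mb) mb$validation_accuracy >= threshold,
                 logical(1))
  if (!any(keep))
    empty_error(paste0(
      "all ", cluster$n, " members screened out (validation accuracy < ",
      threshold, "); increase n or check the signal"))
  cluster$members <- members[keep]
  cluster$k <- sum(keep)
  cluster$screen_threshold <- threshold
  cluster$screened <- TRUE
  cluster
}

#' Majority-vote prediction from a screened cluster
#'
#' Every surviving member classifies each subject from its own feature
#' subspace; the cluster label is the majority vote. The fraction of members
#' voting "patient" is exposed as a score in \[0, 1\] for precision-recall
#' analysis. An exact tie (fraction 0.5) is resolved toward the patient
#' label — deterministic, and errs toward sensitivity in a screening
#' context.
#'
#' @param object A screened `svm_cluster`.
#' @param fc An `fc_dataset` holding all `E` features.
#' @param indices Optional row indices to predict (default: all rows).
#' @param type `"class"` for 0/1 labels, `"vote"` for the patient vote
#'   fraction.
#' @param ... Unused.
#' @return Integer labels or numeric vote fractions, one per subject.
#' @export
predict.svm_cluster <- function(object, fc, indices = NULL,
                                type = c("class", "vote"), ...) {
  type <- match.arg(type)
  if (length(object$members) == 0L) empty_error("cluster has no members")
  X <- fc_matrix(fc)
  if (!is.null(indices)) X <- X[indices, , drop = FALSE]
  votes <- vapply(object$members,
                  function(mb) member_predict(mb, X) == "1",
                  logical(nrow(X)))
  if (nrow(X) == 1L) votes <- matrix(votes, nrow = 1L)
  frac <- rowMeans(votes)
  if (type == "vote") frac else as.integer(frac >= 0.5)
}

#' @rdname predict.svm_cluster
#' @export
vote_fractions <- function(object, fc, indices = NULL) {
  predict(object, fc, indices = indices, type = "vote")
}

#' Evaluate a screened cluster on held-out subjects
#'
#' Computes test accuracy (correct / |S3|), and precision and recall with
#' the patient class as positive. When no subject is predicted patient,
#' precision is undefined; it is reported as 0 with
#' `degenerate_precision = TRUE`.
#'
#' @param cluster A screened `svm_cluster`.
#' @param fc The `fc_dataset`.
#' @param indices Row indices to evaluate on; defaults to the cluster's
#'   test set S3.
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `n_test`,
#'   `degenerate_precision`.
#' @export
evaluate_cluster <- function(cluster, fc, indices = NULL) {
  if (is.null(indices)) indices <- cluster$split$test
  if (length(indices) == 0L) data_error("test set is empty")
  pred <- predict(cluster, fc, indices = indices, type = "class")
  truth <- fc_labels(fc)[indices]
  classification_metrics(truth, pred)
}

# confusion-matrix bookkeeping shared by cluster and baseline evaluation
classification_metrics <- function(truth, pred) {
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  degenerate <- (tp + fp) == 0L
  tibble(accuracy = mean(pred == truth),
         precision = if (degenerate) 0 else tp / (tp + fp),
         recall = if ((tp + fn) == 0L) 0 else tp / (tp + fn),
         n_test = length(truth),
         degenerate_precision = degenerate)
}

#' @export
print.svm_cluster <- function(x, ...) {
  cat(sprintf("<svm_cluster> n = %d, d = %d, M = %d, kernel = %s%s\n",
              x$n, x$d, x$M, x$kernel,
              if (x$screened)
                sprintf("; screened at %.2f -> k = %d", x$screen_threshold, x$k)
              else " (unscreened)"))
  invisible(x)
}

#' Serialize a cluster to a directory of plain-text artifacts
#'
#' Writes a manifest JSON (n, k, d, M, thresholds, seed, base-learner
#' config) plus per-member feature-index and sample-index arrays and
#' validation accuracies. Members are retrainable from the recorded indices
#' and seed, so no binary model files are stored.
#'
#' @param cluster An `svm_cluster`.
#' @param dir Output directory.
#' @param fc The `fc_dataset`, required by `read_cluster()` to retrain
#'   member models.
#' @return `write_cluster()` returns `dir` invisibly; `read_cluster()` an
#'   `svm_cluster` equivalent to the one written.
#' @export
write_cluster <- function(cluster, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(n = cluster$n, k = cluster$k, d = cluster$d, M = cluster$M,
                   kernel = cluster$kernel, cost = cluster$cost,
                   replace = cluster$replace,
                   screen_threshold = cluster$screen_threshold,
                   screened = cluster$screened, seed = cluster$seed,
                   n_edges = cluster$n_edges, n_rois = cluster$n_rois,
                   split = cluster$split[c("train", "validation", "test")],
                   ratios = cluster$split$ratios,
                   split_seed = cluster$split$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  members <- purrr::map(cluster$members, function(mb) {
    list(index = mb$index, seed = mb$seed, sample_idx = mb$sample_idx,
         feature_idx = mb$feature_idx,
         validation_accuracy = mb$validation_accuracy)
  })
  jsonlite::write_json(members, file.path(dir, "members.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_cluster
#' @export
read_cluster <- function(dir, fc) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) data_error(sprintf("missing cluster manifest `%s`", mf))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  X <- fc_matrix(fc)
  y <- as_label_factor(fc_labels(fc))
  raw <- jsonlite::read_json(file.path(dir, "members.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  members <- purrr::map(raw, function(mb) {
    sample_idx <- as.integer(unlist(mb$sample_idx))
    feature_idx <- as.integer(unlist(mb$feature_idx))
    model <- e1071::svm(x = X[sample_idx, feature_idx, drop = FALSE],
                        y = y[sample_idx], kernel = manifest$kernel,
                        cost = manifest$cost, scale = FALSE)
    list(index = mb$index, seed = mb$seed, sample_idx = sample_idx,
         feature_idx = feature_idx, model = model,
         validation_accuracy = as.numeric(mb$validation_accuracy))
  })
  split <- structure(list(train = as.integer(manifest$split$train),
                          validation = as.integer(manifest$split$validation),
                          test = as.integer(manifest$split$test),
                          ratios = manifest$ratios,
                          seed = manifest$split_seed),
                     class = "dataset_split")
  structure(list(members = members, n = manifest$n, k = manifest$k,
                 d = manifest$d, M = manifest$M, kernel = manifest$kernel,
                 cost = manifest$cost, replace = manifest$replace,
                 screen_threshold = manifest$screen_threshold, split = split,
                 seed = manifest$seed, n_edges = manifest$n_edges,
                 n_rois = manifest$n_rois, screened = manifest$screened),
            class = "svm_cluster")
}
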