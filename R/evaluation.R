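#' Baseline comparison harness
#'
#' Benchmarks the random SVM cluster (RSVMC) against standard single
#' learners — k-nearest neighbour, naive Bayes, a small feedforward neural
#' network, a single SVM, and a random forest — under repeated random
#' splits. Within one repeat every method sees the identical split (a
#' paired design), and all methods train on the S1 training rows and are
#' scored on the held-out S3 rows, so accuracy distributions are directly
#' comparable as box plots and the per-method scores feed precision-recall
#' curves.
#'
#' The feedforward net (`"net"`) stands in for product-based neural
#' networks, which have no canonical R implementation; the comparison's
#' purpose — ensemble versus single learners — is unaffected.
#'
#' @param fc An `fc_dataset`.
#' @param methods Character subset of
#'   `c("knn", "bayes", "net", "svm", "rf", "rsvmc")`.
#' @param repeats Number of re-randomized splits (reference protocol: 50).
#' @param ratios Split ratios, see [split_dataset()].
#' @param seed Master seed; repeat `r` uses a derived stream.
#' @param rsvmc_args List of arguments for [build_cluster()]
#'   (`n`, `d`, `M`, ...).
#' @param method_args Named list of per-method argument lists, e.g.
#'   `list(knn = list(k = 5), rf = list(ntree = 200))`.
#' @return A `benchmark_result`: list with `accuracies` (tibble `method`,
#'   `repeat`, `accuracy`, `precision`, `recall`) and `scores` (tibble
#'   `method`, `repeat`, `label`, `score` for P-R analysis).
#' @export
run_baselines <- function(fc, methods = c("knn", "bayes", "net", "svm", "rf", "rsvmc"),
                          repeats = 50L, ratios = c(4, 1, 5), seed = 1L,
                          rsvmc_args = list(n = 100L, d = 100L),
                          method_args = list()) {
  registered <- c("knn", "bayes", "net", "svm", "rf", "rsvmc")
  unknown <- setdiff(methods, registered)
  if (length(unknown) > 0L)
    validation_error("methods",
                     sprintf("unknown method(s) %s; registered: %s",
                             paste0("`", unknown, "`", collapse = ", "),
                             paste(registered, collapse = ", ")))
  repeats <- check_count(repeats, "repeats", min = 1L)
  X <- fc_matrix(fc)
  y <- fc_labels(fc)
  acc_rows <- list(); score_rows <- list()
  for (r in seq_len(repeats)) {
    rseed <- derive_seed(seed, r, stream = 1L)
    split <- split_dataset(fc, ratios = ratios, seed = rseed)
    s1 <- split$train; s3 <- split$test
    for (m in methods) {
      set.seed(derive_seed(rseed, match(m, registered), stream = 2L))
      fit <- fit_baseline(m, X, y, fc, split, rseed, rsvmc_args,
                          method_args[[m]])
      metrics <- classification_metrics(y[s3], fit$pred)
      acc_rows[[length(acc_rows) + 1L]] <-
        dplyr::bind_cols(tibble(method = m, rep = r), metrics)
      score_rows[[length(score_rows) + 1L]] <-
        tibble(method = m, rep = r, label = y[s3], score = fit$score)
    }
  }
  structure(list(accuracies = dplyr::bind_rows(acc_rows),
                 scores = dplyr::bind_rows(score_rows),
                 repeats = repeats, seed = as.integer(seed)),
            class = "benchmark_result")
}

fit_baseline <- function(method, X, y, fc, split, seed, rsvmc_args, args) {
  s1 <- split$train; s3 <- split$test
  Xtr <- X[s1, , drop = FALSE]; ytr <- as_label_factor(y[s1])
  Xte <- X[s3, , drop = FALSE]
  args <- if (is.null(args)) list() else args
  switch(method,
    knn = {
      k <- args$k %||% 5L
      pred <- class::knn(Xtr, Xte, cl = ytr, k = k, prob = TRUE)
      p_win <- attr(pred, "prob")
      score <- ifelse(pred == "1", p_win, 1 - p_win)
      list(pred = as.integer(pred == "1"), score = score)
    },
    bayes = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      score <- predict(fit, Xte, type = "raw")[, "1"]
      list(pred = as.integer(score >= 0.5), score = score)
    },
    net = {
      fit <- nnet::nnet(Xtr, as.numeric(y[s1]),
                        size = args$size %||% 5L,
                        decay = args$decay %||% 0.1,
                        maxit = args$maxit %||% 100L,
                        entropy = TRUE, trace = FALSE,
                        MaxNWts = (ncol(Xtr) + 2L) * (args$size %||% 5L) + 10L)
      score <- as.numeric(predict(fit, Xte))
      list(pred = as.integer(score >= 0.5), score = score)
    },
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = args$kernel %||% "linear",
                        cost = args$cost %||% 1, scale = FALSE,
                        probability = TRUE)
      pred <- predict(fit, Xte, probability = TRUE)
      score <- attr(pred, "probabilities")[, "1"]
      list(pred = as.integer(pred == "1"), score = score)
    },
    rf = {
      fit <- randomForest::randomForest(Xtr, ytr,
                                        ntree = args$ntree %||% 200L)
      score <- predict(fit, Xte, type = "prob")[, "1"]
      pred <- predict(fit, Xte)
      list(pred = as.integer(pred == "1"), score = score)
    },
    rsvmc = {
      cl <- do.call(build_cluster,
                    c(list(fc = fc, split = split, seed = seed), rsvmc_args))
      cl <- screen_cluster(cl, fc)
      score <- vote_fractions(cl, fc, indices = s3)
      list(pred = as.integer(score >= 0.5), score = score)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d method(s) x %d repeat(s)\n",
              length(unique(x$accuracies$method)), x$repeats))
  print(dplyr::summarise(dplyr::group_by(x$accuracies, .data$method),
                         mean_accuracy = mean(.data$accuracy),
                         sd = sd(.data$accuracy), .groups = "drop"))
  invisible(x)
}

#' Precision-recall curve from classification scores
#'
#' Sweeps the decision threshold over every unique score (predicting
#' patient when `score >= threshold`) and records precision and recall at
#' each, the standard P-R construction for comparing classifiers whose
#' scores live on different scales (vote fractions, probabilities, network
#' outputs).
#'
#' @param scores Finite numeric scores; larger means more patient-like.
#' @param labels Binary 0/1 labels (both classes must occur).
#' @return Tibble `threshold`, `precision`, `recall`, sorted by recall
#'   (ascending), then threshold.
#' @export
pr_curve <- function(scores, labels) {
  if (any(!is.finite(scores))) validation_error("scores", "must be finite")
  if (length(scores) != length(labels))
    validation_error("labels", "length mismatch with scores")
  if (length(unique(labels)) < 2L)
    validation_error("labels", "both classes must be present")
  out <- dplyr::bind_rows(lapply(sort(unique(scores), decreasing = TRUE),
    function(t) {
      pred <- as.integer(scores >= t)
      m <- classification_metrics(labels, pred)
      tibble(threshold = t, precision = m$precision, recall = m$recall)
    }))
  dplyr::arrange(out, .data$recall, .data$threshold)
}

#' Cohort demographic summary tests
#'
#' The standard case-control "Table 1": per-variable group summaries
#' (`mean +/- sd`) with a two-sided Welch two-sample t-test for the IQ
#' measures and a chi-square test on binned age. Accepts either raw
#' per-subject metadata (e.g. from [generate_metadata()]) or printed group
#' summary statistics.
#'
#' @param metadata Tibble with `label` plus numeric demographic columns
#'   (raw interface).
#' @param summaries Tibble with columns `variable`, `group`
#'   (`"patient"`/`"control"`), `mean`, `sd`, `n` (summary interface; the
#'   t statistic is computed in closed form from the summaries).
#' @param variables Columns to test in the raw interface.
#' @param age_bins Bin edges for the age chi-square (default decade bins).
#' @return Tibble `variable`, `patients`, `controls` (formatted
#'   `mean +/- sd`), `test`, `statistic`, `df`, `p_value`.
#' @examples
#' s <- tibble::tibble(variable = "FIQ", group = c("patient", "control"),
#'                     mean = c(105.21, 111.20), sd = c(16.56, 12.80),
#'                     n = c(479, 478))
#' cohort_summary_tests(summaries = s)
#' @export
cohort_summary_tests <- function(metadata = NULL, summaries = NULL,
                                 variables = c("age", "FIQ", "PIQ", "VIQ"),
                                 age_bins = seq(0, 100, by = 10)) {
  if (is.null(metadata) && is.null(summaries))
    validation_error("metadata", "supply raw metadata or group summaries")
  if (!is.null(metadata)) {
    if (min(table(metadata$label)) < 2L)
      data_error("need at least 2 subjects per group")
    rows <- lapply(intersect(variables, names(metadata)), function(v) {
      pat <- metadata[[v]][metadata$label == 1L]
      con <- metadata[[v]][metadata$label == 0L]
      fmt <- function(x) sprintf("%.2f ± %.2f", mean(x), sd(x))
      if (v == "age") {
        bins <- cut(metadata[[v]], breaks = age_bins, include.lowest = TRUE)
        tab <- table(bins, metadata$label)
        tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
        ct <- suppressWarnings(stats::chisq.test(tab))
        tibble(variable = v, patients = fmt(pat), controls = fmt(con),
               test = "chi-square (binned)",
               statistic = unname(ct$statistic), df = unname(ct$parameter),
               p_value = ct$p.value)
      } else {
        tt <- stats::t.test(pat, con)
        tibble(variable = v, patients = fmt(pat), controls = fmt(con),
               test = "Welch t", statistic = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value)
      }
    })
    return(dplyr::bind_rows(rows))
  }
  rows <- lapply(unique(summaries$variable), function(v) {
    s <- summaries[summaries$variable == v, ]
    p <- s[s$group == "patient", ]; c_ <- s[s$group == "control", ]
    if (nrow(p) != 1L || nrow(c_) != 1L)
      validation_error("summaries", sprintf("need one patient and one control row for `%s`", v))
    if (p$n < 2L || c_$n < 2L) data_error("need n >= 2 per group")
    w <- welch_from_summary(p$mean, p$sd, p$n, c_$mean, c_$sd, c_$n)
    tibble(variable = v,
           patients = sprintf("%.2f ± %.2f", p$mean, p$sd),
           controls = sprintf("%.2f ± %.2f", c_$mean, c_$sd),
           test = "Welch t (from summaries)", statistic = w$t, df = w$df,
           p_value = w$p)
  })
  dplyr::bind_rows(rows)
}

# Welch two-sample t from (mean, sd, n) summaries with Welch-Satterthwaite
# df; no installed package exposes a summary-statistics t-test
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
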