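test_that("splits are stratified with largest-remainder sizes", {
  fc10 <- tibble::tibble(label = rep(c(0L, 1L), each = 5))
  sp <- split_dataset(fc10, seed = 1)
  expect_identical(lengths(sp[c("train", "validation", "test")]),
                   c(train = 4L, validation = 1L, test = 5L))
  expect_identical(sort(c(sp$train, sp$validation, sp$test)), 1:10)

  # independent largest-remainder enumeration for the 479/478 cohort
  allocate <- function(n, p) {
    q <- n * p; b <- floor(q); left <- n - sum(b)
    if (left > 0) {
      o <- order(q - b, decreasing = TRUE)[seq_len(left)]
      b[o] <- b[o] + 1
    }
    b
  }
  p <- c(4, 1, 5) / 10
  expected <- allocate(479, p) + allocate(478, p)
  expect_equal(expected, c(383, 96, 478))
  fc957 <- tibble::tibble(label = rep(c(1L, 0L), times = c(479, 478)))
  sp957 <- split_dataset(fc957, seed = 7)
  expect_identical(lengths(sp957[c("train", "validation", "test")]),
                   c(train = 383L, validation = 96L, test = 478L))
  # class proportions preserved to within one subject per class
  for (set in c("train", "validation", "test")) {
    labs <- fc957$label[sp957[[set]]]
    expect_lte(abs(sum(labs == 1L) - sum(labs == 0L)), 1L)
  }
})

test_that("splits are reproducible in the seed and reject bad ratios", {
  fc <- tibble::tibble(label = rep(c(0L, 1L), each = 20))
  a <- split_dataset(fc, seed = 3); b <- split_dataset(fc, seed = 3)
  expect_identical(a[c("train", "validation", "test")],
                   b[c("train", "validation", "test")])
  c_ <- split_dataset(fc, seed = 4)
  expect_false(identical(a$train, c_$train))
  expect_identical(lengths(a[1:3]), lengths(c_[1:3]))
  expect_error(split_dataset(fc, ratios = c(1, 2)),
               class = "rsvmc_validation_error")
  expect_error(split_dataset(tibble::tibble(label = c(0L, 1L, 1L))),
               class = "rsvmc_data_error")
})

test_that("cluster building is reproducible and members are diverse", {
  got <- small_fc(seed = 2L, n_per_group = 15L, n_rois = 12L,
                  n_timepoints = 40L, n_planted = 2L)
  sp <- split_dataset(got$fc, seed = 2)
  a <- build_cluster(got$fc, sp, n = 10, d = 8, seed = 5)
  b <- build_cluster(got$fc, sp, n = 10, d = 8, seed = 5)
  for (m in 1:10) {
    expect_identical(a$members[[m]]$feature_idx, b$members[[m]]$feature_idx)
    expect_identical(a$members[[m]]$sample_idx, b$members[[m]]$sample_idx)
  }
  # feature subsets of distinct members collide with negligible probability
  sets <- lapply(a$members, `[[`, "feature_idx")
  expect_identical(anyDuplicated(sets), 0L)
  # every member trains inside S1 only, with both classes
  for (mb in a$members) {
    expect_true(all(mb$sample_idx %in% sp$train))
    expect_identical(sort(unique(got$fc$label[mb$sample_idx])), c(0L, 1L))
    expect_identical(length(mb$feature_idx), 8L)
  }
  expect_error(build_cluster(got$fc, sp, n = 2, d = 10000, seed = 1),
               class = "rsvmc_validation_error")
  expect_error(build_cluster(got$fc, sp, n = 2, d = 8, M = 1000, seed = 1),
               class = "rsvmc_validation_error")
})

test_that("screening records accuracies, keeps the 0.5 boundary, never grows", {
  got <- small_fc(seed = 4L, n_per_group = 20L, n_rois = 12L,
                  n_timepoints = 40L, n_planted = 2L)
  sp <- split_dataset(got$fc, seed = 4)
  cl <- screen_cluster(build_cluster(got$fc, sp, n = 25, d = 10, seed = 4),
                       got$fc)
  accs <- vapply(cl$members, `[[`, numeric(1), "validation_accuracy")
  expect_true(all(accs >= 0.5))
  expect_lte(cl$k, cl$n)
  expect_identical(cl$k, length(cl$members))
  # a member at exactly 0.5 survives ("lower than 0.5" deletes strictly)
  expect_true(cl$screened)
  # impossible threshold empties the cluster with the dedicated error class
  expect_error(screen_cluster(build_cluster(got$fc, sp, n = 3, d = 10, seed = 1),
                              got$fc, threshold = 1.01),
               class = "rsvmc_empty_error")
})

test_that("majority vote equals a brute-force tally of member predictions", {
  for (seed in 1:4) {
    got <- small_fc(seed = seed, n_per_group = 12L, n_rois = 10L,
                    n_timepoints = 40L, n_planted = 2L)
    sp <- split_dataset(got$fc, seed = seed)
    cl <- screen_cluster(build_cluster(got$fc, sp, n = 5, d = 6, seed = seed),
                         got$fc)
    idx <- sp$test
    X <- fc_matrix(got$fc)[idx, , drop = FALSE]
    member_votes <- sapply(cl$members, function(mb)
      as.integer(predict(mb$model, X[, mb$feature_idx, drop = FALSE]) == "1"))
    frac_oracle <- rowMeans(member_votes)
    label_oracle <- as.integer(frac_oracle >= 0.5)
    expect_equal(vote_fractions(cl, got$fc, indices = idx), frac_oracle)
    expect_identical(predict(cl, got$fc, indices = idx), label_oracle)
  }
})

test_that("exact vote ties break toward the patient label", {
  cl <- disagreeing_cluster()
  fc <- structure(tibble::tibble(subject_id = c("a", "b"), label = c(0L, 1L),
                                 site = 1L, f1 = c(-2, 2)),
                  class = c("fc_dataset", class(tibble::tibble())))
  attr(fc, "n_rois") <- 2L
  expect_identical(vote_fractions(cl, fc), c(0.5, 0.5))
  expect_identical(predict(cl, fc), c(1L, 1L))
})

test_that("unanimous members give vote fractions of exactly 0 or 1", {
  got <- small_fc(seed = 9L, n_per_group = 20L, n_rois = 10L,
                  n_timepoints = 60L, n_planted = 3L, r_alt = 0.9)
  sp <- split_dataset(got$fc, seed = 9)
  cl <- screen_cluster(build_cluster(got$fc, sp, n = 1, d = 45, seed = 9),
                       got$fc)
  frac <- vote_fractions(cl, got$fc, indices = sp$test)
  expect_true(all(frac %in% c(0, 1)))
})

test_that("evaluation agrees with an independent confusion-matrix computation", {
  got <- small_fc(seed = 6L, n_per_group = 15L, n_rois = 10L,
                  n_timepoints = 40L, n_planted = 2L)
  sp <- split_dataset(got$fc, seed = 6)
  cl <- screen_cluster(build_cluster(got$fc, sp, n = 9, d = 6, seed = 6),
                       got$fc)
  m <- evaluate_cluster(cl, got$fc)
  pred <- predict(cl, got$fc, indices = sp$test)
  truth <- fc_labels(got$fc)[sp$test]
  cm <- table(factor(truth, 0:1), factor(pred, 0:1))
  expect_equal(m$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(m$recall, cm["1", "1"] / sum(cm["1", ]))
  if (sum(cm[, "1"]) > 0)
    expect_equal(m$precision, cm["1", "1"] / sum(cm[, "1"]))
  expect_identical(m$n_test, length(sp$test))
})

test_that("all-control predictions yield flagged zero precision", {
  truth <- c(0L, 0L, 1L, 1L)
  m <- rsvmcluster:::classification_metrics(truth, rep(0L, 4))
  expect_identical(m$precision, 0)
  expect_identical(m$recall, 0)
  expect_true(m$degenerate_precision)
  perfect <- rsvmcluster:::classification_metrics(truth, truth)
  expect_equal(unlist(perfect[1, 1:3]),
               c(accuracy = 1, precision = 1, recall = 1))
})

test_that("the screened cluster beats its average member on planted-signal data", {
  cluster_acc <- member_acc <- numeric(0)
  for (seed in 1:10) {
    got <- small_fc(seed = seed, n_per_group = 25L, n_rois = 20L,
                    n_timepoints = 60L, n_planted = 4L, r_alt = 0.55)
    sp <- split_dataset(got$fc, seed = seed)
    cl <- screen_cluster(build_cluster(got$fc, sp, n = 20, d = 15, seed = seed),
                         got$fc)
    cluster_acc <- c(cluster_acc, evaluate_cluster(cl, got$fc)$accuracy)
    X <- fc_matrix(got$fc)[sp$test, , drop = FALSE]
    truth <- fc_labels(got$fc)[sp$test]
    member_acc <- c(member_acc, mean(vapply(cl$members, function(mb)
      mean((predict(mb$model, X[, mb$feature_idx, drop = FALSE]) == "1") ==
             (truth == 1L)), numeric(1))))
  }
  expect_gte(mean(cluster_acc), mean(member_acc))
})

test_that("a cluster round-trips through its plain-text serialization", {
  dir <- withr::local_tempdir()
  got <- small_fc(seed = 7L, n_per_group = 15L, n_rois = 10L,
                  n_timepoints = 40L, n_planted = 2L)
  sp <- split_dataset(got$fc, seed = 7)
  cl <- screen_cluster(build_cluster(got$fc, sp, n = 8, d = 6, seed = 7),
                       got$fc)
  write_cluster(cl, file.path(dir, "cluster"))
  back <- read_cluster(file.path(dir, "cluster"), got$fc)
  expect_identical(back$k, cl$k)
  expect_equal(tidy(back), tidy(cl))
  expect_identical(predict(back, got$fc, indices = sp$test),
                   predict(cl, got$fc, indices = sp$test))
})
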