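# Small cohorts and FC tables built in code; sized for speed, not realism.

small_spec <- function(seed = 1L, n_per_group = 30L, n_rois = 30L,
                       n_timepoints = 80L, n_planted = 5L,
                       r_base = 0, r_alt = 0.7, ...) {
  synthetic_spec(n_per_group = n_per_group, n_rois = n_rois,
                 n_timepoints = n_timepoints,
                 planted_edges = default_planted_edges(n_planted),
                 r_base = r_base, r_alt = r_alt, seed = seed, ...)
}

small_fc <- function(seed = 1L, ...) {
  cohort <- generate_cohort(small_spec(seed = seed, ...))
  list(fc = compute_fc(normalize_and_slice(cohort$panel)),
       truth = cohort$truth)
}

# strong-effect fixture frozen for recovery checks: 20 vertex-disjoint
# planted edges at r 0.1 -> 0.5, 100 subjects/group, T = 150, 90 ROIs;
# ensemble n = 2000 members of dimensionality d = 100, screening 0.5,
# superior threshold 0.75, top-k 20
recovery_fixture <- function(seed) {
  spec <- synthetic_spec(n_per_group = 100L, n_rois = 90L,
                         n_timepoints = 150L,
                         planted_edges = default_planted_edges(20L),
                         r_base = 0.1, r_alt = 0.5, seed = seed)
  cohort <- generate_cohort(spec)
  fc <- compute_fc(normalize_and_slice(cohort$panel))
  split <- split_dataset(fc, seed = seed)
  cluster <- screen_cluster(
    build_cluster(fc, split, n = 2000L, d = 100L, seed = seed), fc)
  list(fc = fc, truth = cohort$truth, split = split, cluster = cluster)
}

# independent two-pass Pearson correlation, kept deliberately naive
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# minimal hand-built cluster whose two members always disagree: member A
# learned label 1 for positive feature 1, member B the reverse on feature 2
disagreeing_cluster <- function() {
  x <- matrix(c(-1, -1, 1, 1), ncol = 1)
  y <- factor(c(0, 0, 1, 1), levels = c(0, 1))
  up <- e1071::svm(x = x, y = y, kernel = "linear", cost = 10, scale = FALSE)
  down <- e1071::svm(x = -x, y = y, kernel = "linear", cost = 10, scale = FALSE)
  member <- function(model, feature) {
    list(index = feature, seed = 0L, sample_idx = 1:4, feature_idx = feature,
         model = model, validation_accuracy = 1)
  }
  structure(list(members = list(member(up, 1L), member(down, 1L)),
                 n = 2L, k = 2L, d = 1L, M = 4L, kernel = "linear", cost = 10,
                 replace = FALSE, screen_threshold = 0.5,
                 split = structure(list(train = 1:4, validation = 1:4,
                                        test = 1:4, ratios = c(.4, .1, .5),
                                        seed = 0L), class = "dataset_split"),
                 seed = 0L, n_edges = 1L, n_rois = 2L, screened = TRUE),
            class = "svm_cluster")
}
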