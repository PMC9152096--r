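test_that("spec validation names the offending field", {
  expect_error(synthetic_spec(n_per_group = 0), "n_per_group",
               class = "rsvmc_validation_error")
  expect_error(synthetic_spec(n_timepoints = 5), "n_timepoints",
               class = "rsvmc_validation_error")
  expect_error(synthetic_spec(r_alt = 1), "r_alt",
               class = "rsvmc_validation_error")
  expect_error(synthetic_spec(planted_edges = rbind(c(1, 2), c(2, 3))),
               "planted_edges", class = "rsvmc_validation_error")
  expect_error(synthetic_spec(planted_edges = cbind(4, 3)),
               "planted_edges", class = "rsvmc_validation_error")
  expect_error(synthetic_spec(background_noise_sd = -1),
               "background_noise_sd", class = "rsvmc_validation_error")
})

test_that("fixed seed fixes every generated value", {
  spec <- small_spec(seed = 11L, n_sites = 2L, site_mean_shift = 3,
                     site_scale = 1.5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$panel$series, b$panel$series)
  expect_identical(generate_metadata(spec), generate_metadata(spec))
  c_ <- generate_cohort(small_spec(seed = 12L, n_sites = 2L,
                                   site_mean_shift = 3, site_scale = 1.5))
  expect_false(identical(a$panel$series[[1]], c_$panel$series[[1]]))
})

test_that("planted-edge correlations match a Monte-Carlo oracle of the mixing formula", {
  # oracle: draw 1e5 samples directly from the latent-factor construction
  mix_oracle <- function(r, n = 1e5) {
    a <- sqrt(abs(r))
    s <- rnorm(n)
    x <- sqrt(1 - a^2) * rnorm(n) + a * s
    y <- sqrt(1 - a^2) * rnorm(n) + sign(r) * a * s
    cor(x, y)
  }
  set.seed(99)
  expect_equal(mix_oracle(0.5), 0.5, tolerance = 0.02)
  expect_equal(mix_oracle(-0.4), -0.4, tolerance = 0.02)

  spec <- synthetic_spec(n_per_group = 200L, n_rois = 20L, n_timepoints = 150L,
                         planted_edges = cbind(1L, 2L),
                         r_base = 0.1, r_alt = 0.5, seed = 5L)
  cohort <- generate_cohort(spec)
  fc <- compute_fc(normalize_and_slice(cohort$panel))
  r_edge <- fc_matrix(fc)[, cohort$truth$edge_flat]
  for (g in 0:1) {
    vals <- r_edge[fc_labels(fc) == g]
    target <- mix_oracle(if (g == 0) 0.1 else 0.5)
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - target), 3 * se)
  }
})

test_that("non-planted pairs carry no correlation and no-signal specs have no group difference", {
  got <- small_fc(seed = 3L, r_base = 0.3, r_alt = 0.3, n_per_group = 40L)
  X <- fc_matrix(got$fc)
  bg <- setdiff(seq_len(ncol(X)), got$truth$edge_flat)
  expect_lt(abs(mean(X[, bg])), 0.01)
  planted_mean <- colMeans(X[, got$truth$edge_flat, drop = FALSE])
  expect_lt(max(abs(planted_mean - 0.3)), 0.1)
  diff <- colMeans(X[got$fc$label == 1, got$truth$edge_flat, drop = FALSE]) -
    colMeans(X[got$fc$label == 0, got$truth$edge_flat, drop = FALSE])
  expect_lt(max(abs(diff)), 0.15)
})

test_that("empirical planted correlation converges to the target as T grows", {
  err <- vapply(c(50L, 500L, 5000L), function(T) {
    spec <- synthetic_spec(n_per_group = 15L, n_rois = 6L, n_timepoints = T,
                           planted_edges = cbind(1L, 2L),
                           r_base = 0.4, r_alt = 0.4, seed = 21L)
    cohort <- generate_cohort(spec)
    fc <- compute_fc(normalize_and_slice(cohort$panel))
    mean(abs(fc_matrix(fc)[, cohort$truth$edge_flat] - 0.4))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("negative planted correlations are supported", {
  spec <- synthetic_spec(n_per_group = 60L, n_rois = 8L, n_timepoints = 200L,
                         planted_edges = cbind(1L, 2L),
                         r_base = -0.6, r_alt = -0.6, seed = 8L)
  cohort <- generate_cohort(spec)
  fc <- compute_fc(normalize_and_slice(cohort$panel))
  expect_equal(mean(fc_matrix(fc)[, cohort$truth$edge_flat]), -0.6,
               tolerance = 0.05)
})

test_that("site effects are affine and removed by normalization", {
  base <- small_spec(seed = 13L, n_per_group = 6L, n_rois = 8L,
                     n_timepoints = 60L, n_planted = 2L)
  shifted <- small_spec(seed = 13L, n_per_group = 6L, n_rois = 8L,
                        n_timepoints = 60L, n_planted = 2L,
                        n_sites = 3L, site_mean_shift = 10, site_scale = 2)
  fc_a <- compute_fc(normalize_and_slice(generate_cohort(base)$panel))
  fc_b <- compute_fc(normalize_and_slice(generate_cohort(shifted)$panel))
  expect_equal(fc_matrix(fc_a), fc_matrix(fc_b), tolerance = 1e-10)
})

test_that("ground truth matches the synthetic_spec it came from", {
  got <- generate_cohort(small_spec(n_planted = 4L))
  expect_identical(got$truth$planted_rois,
                   sort(unique(as.integer(got$truth$planted_edges))))
  p <- edge_to_rois(got$truth$edge_flat, 30L)
  expect_equal(cbind(p$roi_a, p$roi_b), unname(got$truth$planted_edges))
})

test_that("metadata has one row per subject with matching labels and is configurable", {
  spec <- small_spec(n_per_group = 25L)
  meta <- generate_metadata(spec)
  expect_identical(nrow(meta), 50L)
  expect_identical(meta$label, rep(c(0L, 1L), each = 25L))
  expect_true(all(c("age", "FIQ", "PIQ", "VIQ") %in% names(meta)))
  expect_error(generate_metadata(spec, distributions = list(patient = NULL)),
               class = "rsvmc_validation_error")
  # identical group distributions -> t-test p-values roughly uniform
  big <- small_spec(n_per_group = 60L)
  dist <- default_demographics()
  dist$patient <- dist$control
  ps <- vapply(1:40, function(s) {
    m <- generate_metadata(big, distributions = dist, seed = s)
    stats::t.test(FIQ ~ label, data = m)$p.value
  }, numeric(1))
  expect_gt(mean(ps < 0.5), 0.25)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("a cohort written to disk reads back identically", {
  dir <- withr::local_tempdir()
  got <- generate_cohort(small_spec(n_per_group = 4L, n_rois = 6L,
                                    n_timepoints = 20L, n_planted = 2L,
                                    n_sites = 2L))
  write_cohort(got$panel, dir, truth = got$truth)
  back <- read_cohort(dir)
  expect_equal(back$series, got$panel$series, tolerance = 1e-12)
  expect_identical(back$label, got$panel$label)
  expect_identical(back$site, got$panel$site)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$edge_flat, got$truth$edge_flat)
})
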