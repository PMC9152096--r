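#' Specify a planted-effect synthetic cohort
#'
#' Describes a two-group cohort of ROI time series in which a chosen set of
#' vertex-disjoint ROI pairs ("planted edges") carries a group-differential
#' Pearson correlation: `r_base` in controls (group 0) and `r_alt` in
#' patients (group 1). All other ROI pairs have population correlation 0.
#' The generator is the package's stand-in for preprocessed resting-state
#' fMRI: it emulates the one property the downstream classifier consumes —
#' the correlation structure between regional time courses — and nothing
#' of the imaging physics (no hemodynamics, no head motion, no voxels).
#'
#' Planted edges must be vertex-disjoint (no ROI on two planted edges): each
#' edge then has its own latent factor and the target correlation is exact.
#'
#' @param n_per_group Subjects per group.
#' @param n_rois Number of ROIs (default 90, the AAL cerebrum).
#' @param n_timepoints Time points per series (>= 10).
#' @param planted_edges Two-column matrix (or list of length-2 vectors) of
#'   ROI index pairs `i < j`. Default: 20 disjoint pairs (1,2), (3,4), ...,
#'   (39,40).
#' @param r_base,r_alt Target Pearson correlation on planted edges in group 0
#'   and group 1; `|r| < 1`.
#' @param background_noise_sd Scale of the series (> 0). Correlations are
#'   scale-invariant; this only affects raw magnitudes.
#' @param n_sites Number of acquisition sites; subjects are assigned
#'   round-robin. Site `k` transforms every series affinely:
#'   `x * site_scale^(k-1) + site_mean_shift*(k-1)`, emulating multi-site
#'   mean/variance shifts that z-scoring must undo.
#' @param site_mean_shift,site_scale Site effect parameters (site 1 is
#'   always untouched).
#' @param seed Integer seed; fixes every generated value.
#' @return A validated `synthetic_spec` object (list).
#' @seealso [generate_cohort()], [generate_metadata()]
#' @export
synthetic_spec <- function(n_per_group = 100L, n_rois = 90L, n_timepoints = 150L,
                           planted_edges = default_planted_edges(20L),
                           r_base = 0.1, r_alt = 0.5,
                           background_noise_sd = 1, n_sites = 1L,
                           site_mean_shift = 0, site_scale = 1, seed = 1L) {
  n_per_group <- check_count(n_per_group, "n_per_group", min = 1L)
  n_rois <- check_count(n_rois, "n_rois", min = 2L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 10L)
  n_sites <- check_count(n_sites, "n_sites", min = 1L)
  if (is.list(planted_edges))
    planted_edges <- do.call(rbind, planted_edges)
  planted_edges <- matrix(as.integer(planted_edges), ncol = 2L)
  if (nrow(planted_edges) > 0L) {
    i <- planted_edges[, 1L]; j <- planted_edges[, 2L]
    if (any(i >= j | i < 1L | j > n_rois))
      validation_error("planted_edges", "pairs must satisfy 1 <= i < j <= n_rois")
    if (anyDuplicated(c(i, j)))
      validation_error("planted_edges",
                       "must be vertex-disjoint (no ROI on two planted edges)")
  }
  for (f in c("r_base", "r_alt")) {
    r <- get(f)
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) >= 1)
      validation_error(f, "must satisfy |r| < 1")
  }
  if (!is.numeric(background_noise_sd) || background_noise_sd <= 0)
    validation_error("background_noise_sd", "must be > 0")
  if (!is.numeric(site_scale) || site_scale <= 0)
    validation_error("site_scale", "must be > 0")
  structure(list(n_per_group = n_per_group, n_rois = n_rois,
                 n_timepoints = n_timepoints, planted_edges = planted_edges,
                 r_base = r_base, r_alt = r_alt,
                 background_noise_sd = background_noise_sd,
                 n_sites = n_sites, site_mean_shift = site_mean_shift,
                 site_scale = site_scale, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @param n_edges Number of disjoint default pairs.
#' @export
default_planted_edges <- function(n_edges = 20L) {
  n_edges <- check_count(n_edges, "n_edges", min = 0L)
  if (n_edges == 0L) return(matrix(integer(), ncol = 2L))
  cbind(seq(1L, by = 2L, length.out = n_edges),
        seq(2L, by = 2L, length.out = n_edges))
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d+%d subjects, %d ROIs x %d timepoints, %d planted edges (r %g -> %g), %d site(s), seed %d\n",
    x$n_per_group, x$n_per_group, x$n_rois, x$n_timepoints,
    nrow(x$planted_edges), x$r_base, x$r_alt, x$n_sites, x$seed))
  invisible(x)
}

#' Generate a synthetic two-group ROI time-series cohort
#'
#' Draws the cohort described by a [synthetic_spec()]. Each ROI series is
#' unit-variance white noise; for a planted edge (i, j) with group target
#' correlation `r`, the endpoint series share a latent factor:
#' `x_i = sqrt(1-a^2) * e_i + a * s` and
#' `x_j = sqrt(1-a^2) * e_j + sign(r) * a * s` with `a = sqrt(|r|)` and
#' `s`, `e_i`, `e_j` independent standard normal, so the population
#' correlation of the pair is exactly `r`. Vertex-disjointness of planted
#' edges guarantees every non-planted pair has population correlation 0.
#' Series are then scaled by `background_noise_sd` and the per-site affine
#' shift/scale is applied.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components `panel` (a [ts_panel()]: tibble with
#'   `subject_id`, `label`, `site` and a `series` list-column of
#'   ROI-by-time matrices) and `truth` (a `ground_truth` list: planted edge
#'   pairs, their flat indices under the package edge ordering, the planted
#'   ROI set, and the per-group target correlations).
#' @examples
#' spec <- synthetic_spec(n_per_group = 5, n_rois = 10, n_timepoints = 30,
#'                        planted_edges = cbind(1, 2), seed = 7)
#' cohort <- generate_cohort(spec)
#' cohort$truth$planted_rois
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_total <- 2L * spec$n_per_group
  labels <- rep(c(0L, 1L), each = spec$n_per_group)
  sites <- ((seq_len(n_total) - 1L) %% spec$n_sites) + 1L
  targets <- c(spec$r_base, spec$r_alt)
  pe <- spec$planted_edges
  series <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    x <- matrix(rnorm(spec$n_rois * spec$n_timepoints),
                nrow = spec$n_rois, ncol = spec$n_timepoints)
    r <- targets[labels[s] + 1L]
    if (nrow(pe) > 0L && r != 0) {
      a <- sqrt(abs(r))
      for (k in seq_len(nrow(pe))) {
        latent <- rnorm(spec$n_timepoints)
        i <- pe[k, 1L]; j <- pe[k, 2L]
        x[i, ] <- sqrt(1 - a^2) * x[i, ] + a * latent
        x[j, ] <- sqrt(1 - a^2) * x[j, ] + sign(r) * a * latent
      }
    }
    x <- x * spec$background_noise_sd
    k <- sites[s]
    x <- x * spec$site_scale^(k - 1L) + spec$site_mean_shift * (k - 1L)
    series[[s]] <- x
  }
  panel <- ts_panel(subject_id = sprintf("sub%04d", seq_len(n_total)),
                    label = labels, series = series, site = sites)
  flat <- if (nrow(pe) > 0L) rois_to_edge(pe[, 1L], pe[, 2L], spec$n_rois) else integer()
  truth <- structure(list(planted_edges = pe, edge_flat = flat,
                          planted_rois = sort(unique(as.integer(pe))),
                          r_base = spec$r_base, r_alt = spec$r_alt,
                          n_rois = spec$n_rois),
                     class = "ground_truth")
  list(panel = panel, truth = truth)
}

#' Generate a demographics table for a synthetic cohort
#'
#' Draws per-subject age and IQ scores (full-scale, performance, verbal:
#' FIQ/PIQ/VIQ) from per-group normal distributions, mimicking the
#' demographics table of a case-control neuroimaging cohort. Defaults are
#' the printed group summaries of the ABIDE-I ASD/control cohort this
#' package's workflow targets. Metadata is generated independently of the
#' time series: demographics are cohort description, not features.
#'
#' @param spec A [synthetic_spec()].
#' @param distributions Named list with elements `patient` and `control`,
#'   each a named list of `c(mean, sd)` for `age`, `FIQ`, `PIQ`, `VIQ`.
#' @param seed Seed; defaults to a stream derived from `spec$seed`.
#' @return Tibble with one row per subject: `subject_id`, `label`, `site`,
#'   `age`, `FIQ`, `PIQ`, `VIQ`.
#' @export
generate_metadata <- function(spec, distributions = default_demographics(),
                              seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (g in c("patient", "control")) {
    if (is.null(distributions[[g]]))
      validation_error("distributions", sprintf("missing group `%s`", g))
    for (v in c("age", "FIQ", "PIQ", "VIQ"))
      if (length(distributions[[g]][[v]]) != 2L)
        validation_error("distributions",
                         sprintf("`%s$%s` must be c(mean, sd)", g, v))
  }
  set.seed(if (is.null(seed)) derive_seed(spec$seed, 0L, stream = 9L) else seed)
  n_total <- 2L * spec$n_per_group
  labels <- rep(c(0L, 1L), each = spec$n_per_group)
  sites <- ((seq_len(n_total) - 1L) %% spec$n_sites) + 1L
  draw <- function(v) {
    vapply(labels, function(l) {
      p <- distributions[[if (l == 1L) "patient" else "control"]][[v]]
      rnorm(1L, p[1L], p[2L])
    }, numeric(1))
  }
  tibble(subject_id = sprintf("sub%04d", seq_len(n_total)),
         label = labels, site = sites,
         age = draw("age"), FIQ = draw("FIQ"), PIQ = draw("PIQ"),
         VIQ = draw("VIQ"))
}

#' @rdname generate_metadata
#' @export
default_demographics <- function() {
  list(patient = list(age = c(16.70, 8.23), FIQ = c(105.21, 16.56),
                      PIQ = c(104.89, 17.06), VIQ = c(103.25, 18.05)),
       control = list(age = c(17.20, 8.06), FIQ = c(111.20, 12.80),
                      PIQ = c(108.61, 13.31), VIQ = c(110.37, 13.50)))
}
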