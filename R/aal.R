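#' AAL atlas label table
#'
#' Loads the Automated Anatomical Labeling (AAL) parcellation table shipped
#' with the package: 116 parcels with index, short name (e.g. `LING.R`,
#' `SFGmed.R`), full name, lobe, and a cerebellum flag. Resting-state
#' connectivity studies of the cerebrum conventionally drop the 26 cerebellar
#' parcels, leaving 90 regions of interest (ROIs); that filter is the default.
#'
#' @param drop_cerebellum If `TRUE` (default) the 26 cerebellar parcels are
#'   removed, returning the 90 cerebral ROIs in atlas order.
#' @return A tibble with columns `index`, `short_name`, `full_name`, `lobe`,
#'   `cerebellum`.
#' @examples
#' nrow(aal_labels())               # 90
#' nrow(aal_labels(FALSE))          # 116
#' @export
aal_labels <- function(drop_cerebellum = TRUE) {
  path <- system.file("extdata", "aal116.tsv", package = "rsvmcluster")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (drop_cerebellum) tab <- dplyr::filter(tab, .data$cerebellum == 0L)
  tab
}

# ROI display names for an R-region panel: AAL short names when R matches the
# filtered atlas, generic V01.. otherwise.
roi_names <- function(n_rois) {
  if (n_rois == 90L) return(aal_labels()$short_name)
  sprintf("V%02d", seq_len(n_rois))
}
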