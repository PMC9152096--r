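#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select bind_rows group_by summarise desc
#' @importFrom stats cor rnorm sd predict setNames
#' @keywords internal
"_PACKAGE"

# Deterministic per-unit seed stream derived from a master seed.  Keeps every
# member / repeat / grid point reproducible and order-independent; constants
# are arbitrary odd primes, result kept inside the 32-bit integer range.
derive_seed <- function(seed, index, stream = 0L) {
  as.integer((as.double(seed) * 48271 + index * 7919 + stream * 104729) %% 2147483647)
}

validation_error <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg),
        class = c("rsvmc_validation_error", "rsvmc_config_error"))
}

data_error <- function(msg) abort(msg, class = "rsvmc_data_error")

empty_error <- function(msg) abort(msg, class = "rsvmc_empty_error")

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    validation_error(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

# labels are stored as integers: patient = 1, control = 0
as_label_factor <- function(labels) factor(labels, levels = c(0L, 1L))
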