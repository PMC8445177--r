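#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# All randomness flows through explicit seeds; callers' RNG state is never
# touched. Seeds must stay below .Machine$integer.max, including derived
# per-position offsets.
check_seed <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > .Machine$integer.max - 1000L) {
    stop("`seed` must be a non-negative integer below 2^31 - 1000.",
         call. = FALSE)
  }
  seed
}

with_seed <- function(seed, code) {
  withr::with_seed(check_seed(seed), code)
}
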