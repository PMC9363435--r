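#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number slice pull across all_of distinct count
#' @importFrom stats rnorm rpois rnbinom runif predict setNames
#' @importFrom utils head
NULL

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# stop unless `cond`; message built with sprintf
stopf <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) abort(sprintf(fmt, ...))
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)
}
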