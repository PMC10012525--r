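# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# First-seen order of a character vector; identifier order is never sorted so
# that eigenvector/weight output aligns positionally with the input.
first_seen <- function(x) unique(as.character(x))

# Euclidean (L2) normalization used for every eigenvector column.
unit_norm <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) {
    abort("Cannot normalize an all-zero vector.", class = "mahp_degenerate_error")
  }
  x / n
}

stop_if_not_trial_cols <- function(data, call = rlang::caller_env()) {
  need <- c("family", "replicate", "condition", "trait", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(miss, collapse = ", "), "."),
      class = "mahp_format_error", call = call
    )
  }
  invisible(data)
}
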