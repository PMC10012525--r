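#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection fit
#'
#' @param x An [mahp_selection()] result.
#' @param what Which component to return: family `"scores"` (ranked, with
#'   selection flags; default), trait `"weights"`, `"params"`,
#'   `"stability"`, `"anova"` or `"correlations"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mahp_fit
#' @export
tidy.mahp_fit <- function(x, what = c("scores", "weights", "params",
                                      "stability", "anova", "correlations"),
                          ...) {
  what <- match.arg(what)
  out <- switch(what,
    scores = x$selection,
    weights = x$weights,
    params = x$params,
    stability = x$stability,
    anova = x$anova,
    correlations = x$correlations
  )
  as_tibble(out)
}

#' One-row summary of a selection fit
#'
#' @param x An [mahp_selection()] result.
#' @param ... Unused.
#' @return A one-row tibble: design sizes, retained/selected counts, and
#'   the main tuning parameters.
#' @method glance mahp_fit
#' @export
glance.mahp_fit <- function(x, ...) {
  tibble(
    n_families = nrow(x$scores),
    n_reps = x$params$n_reps[1],
    n_traits = nrow(x$filter),
    n_retained = sum(x$filter$retained),
    n_selected = sum(x$selection$selected),
    k = x$config$k,
    alpha = x$config$alpha
  )
}
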