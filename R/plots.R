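#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot family scores with the selected set highlighted
#'
#' @param scores A ranked score tibble (from [select_top()] or
#'   `tidy(fit, "scores")`).
#' @return A ggplot.
#' @export
plot_family_scores <- function(scores) {
  scores$family <- factor(scores$family, levels = scores$family)
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$family, y = .data$score,
                               fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#1b7837",
                                          `FALSE` = "grey70"),
                               name = "selected") +
    ggplot2::labs(x = "family (ranked)", y = "final score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot per-parameter contributions to trait weights
#'
#' Stacked eigenvector entries per trait; the bar total is the final
#' weight (contributions from negatively correlated parameters plot below
#' zero).
#'
#' @param weights A [trait_weights()] result.
#' @return A ggplot.
#' @export
plot_trait_weights <- function(weights) {
  params <- attr(weights, "parameters") %||%
    setdiff(names(weights), c("trait", "final_weight"))
  long <- tidyr::pivot_longer(as_tibble(weights),
                              dplyr::all_of(params),
                              names_to = "parameter", values_to = "entry")
  long$trait <- factor(long$trait, levels = weights$trait)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$entry,
                                     fill = .data$parameter)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(
      data = as_tibble(weights),
      ggplot2::aes(x = .data$trait, y = .data$final_weight),
      inherit.aes = FALSE, shape = 18, size = 2
    ) +
    ggplot2::labs(x = NULL, y = "eigenvector entry / final weight (◆)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Autoplot method for selection fits
#'
#' @param object An [mahp_selection()] result.
#' @param type `"scores"` (default) or `"weights"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mahp_fit
#' @export
autoplot.mahp_fit <- function(object, type = c("scores", "weights"), ...) {
  type <- match.arg(type)
  switch(type,
    scores = plot_family_scores(object$selection),
    weights = plot_trait_weights(object$weights)
  )
}
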