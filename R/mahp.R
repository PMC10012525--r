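#' Reflect a lower-is-better variable about its maximum
#'
#' `TD_i = max(D) - D_i`: the best (lowest) observation maps to the largest
#' transformed value and the worst to 0, so that every variable entering a
#' comparison matrix reads "larger is better". A constant vector maps to all
#' zeros, which downstream normalization treats as degenerate.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' lower_better_transform(c(3, 1, 2)) # 0 2 1
lower_better_transform <- function(values) {
  if (length(values) == 0) {
    abort("Empty vector.", class = "mahp_parameter_error")
  }
  max(values) - values
}

#' Build a consistency pairwise-comparison matrix from measurements
#'
#' `A[i, j] = v[i] / v[j]`: a reciprocal (`A[i, j] * A[j, i] = 1`), rank-one
#' matrix whose single non-zero eigenvalue is `N` and whose principal
#' eigenvector is proportional to `v`. This is the measurement-driven
#' variant of the analytic hierarchy process: because the matrix is exactly
#' consistent by construction, no consistency-ratio checking is needed.
#'
#' @param v Numeric vector with no zero entries.
#' @param labels Optional dimnames.
#' @return A matrix of class `comparison_matrix` with the generating vector
#'   attached as attribute `generating_vector`.
#' @export
comparison_matrix <- function(v, labels = NULL) {
  if (any(v == 0)) {
    abort(
      "Zero entry in generating vector: the ratio matrix is undefined; use principal_eigenpair() on the vector directly.",
      class = "mahp_zero_division_error"
    )
  }
  a <- outer(v, 1 / v)
  dimnames(a) <- list(labels, labels)
  attr(a, "generating_vector") <- v
  class(a) <- c("comparison_matrix", class(a))
  a
}

#' Principal eigenpair of a consistency matrix
#'
#' For a consistency matrix generated by `v`, the principal eigenvalue is
#' `N` and the principal eigenvector is `v` scaled to unit Euclidean norm
#' (classical AHP's sum-to-one scaling is deliberately not used); the sign
#' is oriented along `v`. Given a numeric vector the eigenpair is computed
#' directly from this closed form; given a matrix it is extracted with a
#' dense eigendecomposition, so the two paths cross-validate each other.
#'
#' @param x A `comparison_matrix` (or plain square matrix) or the generating
#'   numeric vector itself.
#' @return A list with `lambda` (principal eigenvalue) and `vector`
#'   (unit-norm principal eigenvector).
#' @export
#' @examples
#' principal_eigenpair(c(3, 4)) # lambda 2, vector (0.6, 0.8)
principal_eigenpair <- function(x) {
  if (is.matrix(x)) {
    e <- eigen(unclass(x))
    i <- which.max(Re(e$values))
    vec <- Re(e$vectors[, i])
    # A ratio matrix is invariant to v -> c*v (any c != 0), so the sign of
    # the eigenvector is fixed by the generating vector when known and by a
    # largest-entry-positive convention otherwise.
    ref <- attr(x, "generating_vector") %||% x[, 1]
    if (is.null(attr(x, "generating_vector"))) {
      if (vec[which.max(abs(vec))] < 0) vec <- -vec
    } else if (sum(vec * ref) < 0) {
      vec <- -vec
    }
    return(list(lambda = Re(e$values[i]), vector = unit_norm(vec)))
  }
  if (all(x == 0)) {
    abort("Zero generating vector.", class = "mahp_degenerate_error")
  }
  list(lambda = length(x), vector = unit_norm(x))
}

#' Trait weights from per-parameter eigenvectors
#'
#' For each genetic-parameter column (e.g. SI, SIBH, genetic correlations,
#' expected genetic advance per condition): optionally reflect lower-better
#' parameters with [lower_better_transform()], then take the unit-norm
#' principal eigenvector of the implied trait comparison matrix (equal to
#' the L2-normalized column). The final weight of a trait is the plain row
#' sum of its eigenvector entries across parameters. Negative parameter
#' values (correlations) pass through unchanged, so entries and weight
#' contributions may be negative.
#'
#' @param parameter_table A tibble/data frame with a `trait` column followed
#'   by one numeric column per parameter. No `NA`s; replace undefined
#'   parameter values (and log) before calling.
#' @param directions Optional named character vector over parameter columns
#'   with values `"higher_better"` / `"lower_better"`; unnamed parameters
#'   default to `"higher_better"`.
#' @param transform If `FALSE`, skip the lower-better reflection for all
#'   parameters (reproduction mode for published tables built on
#'   untransformed columns).
#' @return A tibble of class `mahp_weights`: `trait`, one eigenvector-entry
#'   column per parameter, `final_weight`.
#' @export
trait_weights <- function(parameter_table, directions = NULL, transform = TRUE) {
  parameter_table <- as_tibble(parameter_table)
  if (!"trait" %in% names(parameter_table)) {
    abort("parameter_table needs a `trait` column.", class = "mahp_format_error")
  }
  params <- setdiff(names(parameter_table), "trait")
  if (length(params) == 0) {
    abort("No parameter columns.", class = "mahp_format_error")
  }
  dirs <- rep("higher_better", length(params))
  names(dirs) <- params
  if (!is.null(directions)) {
    bad <- setdiff(names(directions), params)
    if (length(bad) > 0) {
      abort(paste0("directions name(s) not in parameter columns: ",
                   paste(bad, collapse = ", ")),
            class = "mahp_alignment_error")
    }
    dirs[names(directions)] <- directions
  }
  out <- tibble(trait = parameter_table$trait)
  for (p in params) {
    x <- parameter_table[[p]]
    if (anyNA(x)) {
      abort(paste0("NA in parameter column '", p,
                   "'; resolve undefined values first."),
            class = "mahp_parameter_error")
    }
    if (transform && dirs[[p]] == "lower_better") {
      x <- lower_better_transform(x)
    }
    if (all(x == 0)) {
      abort(paste0("Parameter column '", p, "' is degenerate (all zero",
                   if (dirs[[p]] == "lower_better") " after reflection" else "",
                   ")."),
            class = "mahp_degenerate_error")
    }
    out[[p]] <- principal_eigenpair(x)$vector
  }
  out$final_weight <- rowSums(out[params])
  structure(out, class = c("mahp_weights", class(out)),
            parameters = params, directions = dirs)
}

#' Family scores from weighted per-trait eigenvectors
#'
#' For each trait: reflect lower-better traits, take the unit-norm principal
#' eigenvector of the family comparison matrix implied by the (typically
#' condition-averaged) family means, and combine across traits as the
#' weighted sum with each trait's final weight.
#'
#' @param trait_means A tibble with a `family` column followed by one numeric
#'   column per trait (see [condition_average()]); the trait set must match
#'   `weights$trait`.
#' @param weights A [trait_weights()] result (or tibble with `trait` and
#'   `final_weight`).
#' @param directions Optional named vector over traits,
#'   `"higher_better"` / `"lower_better"` (default higher).
#' @return A tibble of class `mahp_scores`: `family`, one eigenvector-entry
#'   column per trait, `score`, in input family order.
#' @export
family_scores <- function(trait_means, weights, directions = NULL) {
  trait_means <- as_tibble(trait_means)
  traits <- weights$trait
  miss <- setdiff(traits, names(trait_means))
  if (length(miss) > 0) {
    abort(paste0("trait_means is missing weighted trait(s): ",
                 paste(miss, collapse = ", ")),
          class = "mahp_alignment_error")
  }
  dirs <- rep("higher_better", length(traits))
  names(dirs) <- traits
  if (!is.null(directions)) {
    known <- intersect(names(directions), traits)
    dirs[known] <- directions[known]
  }
  out <- tibble(family = as.character(trait_means$family))
  for (tr in traits) {
    x <- trait_means[[tr]]
    if (dirs[[tr]] == "lower_better") x <- lower_better_transform(x)
    out[[tr]] <- principal_eigenpair(x)$vector
  }
  out$score <- as.vector(as.matrix(out[traits]) %*% weights$final_weight)
  structure(out, class = c("mahp_scores", class(out)), traits = traits)
}

#' Rank families and select the top set
#'
#' Sorts descending by score and flags the top `count` families (or
#' `ceiling(fraction * n)`). Ties are broken by input order, so the
#' selection is deterministic.
#'
#' @param scores A tibble with columns `family` and `score` (e.g. from
#'   [family_scores()]).
#' @param count Number of families to select, or
#' @param fraction Selected fraction in `(0, 1]`.
#' @return A tibble sorted by descending score with added `rank` and
#'   `selected` columns.
#' @export
select_top <- function(scores, count = NULL, fraction = NULL) {
  n <- nrow(scores)
  if (is.null(count) && is.null(fraction)) {
    abort("Supply `count` or `fraction`.", class = "mahp_parameter_error")
  }
  if (is.null(count)) {
    if (fraction <= 0 || fraction > 1) {
      abort("fraction must be in (0, 1].", class = "mahp_parameter_error")
    }
    count <- as.integer(ceiling(fraction * n))
  }
  if (count < 1 || count > n) {
    abort(paste0("count must be in [1, ", n, "]."),
          class = "mahp_parameter_error")
  }
  ord <- order(-scores$score) # stable: ties keep input order
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  out$selected <- out$rank <= count
  out
}
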