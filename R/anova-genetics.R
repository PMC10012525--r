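#' Randomized-complete-block ANOVA per trait and condition
#'
#' Fits the two-way RCBD decomposition without interaction
#' (`value ~ replicate + family`) separately for each trait x condition and
#' returns a tidy table of sources. F statistics are against the error mean
#' square; significance codes follow the conventional field notation:
#' `"*"` at 5%, `"**"` at 1%, `"ns"` otherwise.
#'
#' @param data A long-layout trial tibble (see [read_trial()]).
#' @param traits,conditions Optional subsets; defaults to everything present,
#'   in first-seen order.
#' @return A tibble with columns `trait`, `condition`, `term`
#'   (`replication` / `families` / `error`), `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`, `signif`.
#' @export
rcbd_anova <- function(data, traits = NULL, conditions = NULL) {
  stop_if_not_trial_cols(data)
  traits <- traits %||% first_seen(data$trait)
  conditions <- conditions %||% first_seen(data$condition)
  combos <- tidyr::expand_grid(condition = conditions, trait = traits)
  purrr::pmap_dfr(combos, function(condition, trait) {
    sub <- data[data$condition == condition & data$trait == trait, ]
    g <- length(unique(sub$family))
    r <- length(unique(sub$replicate))
    if (g < 2 || r < 2) {
      abort(
        paste0("RCBD ANOVA needs >= 2 families and >= 2 replicates (trait '",
               trait, "', condition '", condition, "': g = ", g,
               ", r = ", r, ")."),
        class = "mahp_df_error"
      )
    }
    sub$family <- factor(sub$family, levels = unique(sub$family))
    sub$replicate <- factor(sub$replicate, levels = unique(sub$replicate))
    fit <- stats::aov(value ~ replicate + family, data = sub)
    sm <- summary(fit)[[1]]
    rn <- trimws(rownames(sm))
    idx <- match(c("replicate", "family", "Residuals"), rn)
    out <- tibble(
      trait = trait,
      condition = condition,
      term = c("replication", "families", "error"),
      df = as.integer(sm$Df[idx]),
      sumsq = sm$`Sum Sq`[idx],
      meansq = sm$`Mean Sq`[idx]
    )
    mse <- out$meansq[3]
    # zero error mean square: F reported as Inf with p = 0 (perfectly
    # replicated data); zero error df cannot occur when g, r >= 2.
    out$statistic <- c(out$meansq[1:2] / mse, NA_real_)
    out$p.value <- c(
      stats::pf(out$statistic[1:2], out$df[1:2], out$df[3], lower.tail = FALSE),
      NA_real_
    )
    out$signif <- dplyr::case_when(
      is.na(out$p.value) ~ NA_character_,
      out$p.value < 0.01 ~ "**",
      out$p.value < 0.05 ~ "*",
      TRUE ~ "ns"
    )
    out
  })
}

#' Variance components and broad-sense heritability from mean squares
#'
#' Family-mean-basis components of the RCBD analysis: genetic variance
#' `sigma2_g = (MSf - MSe) / r`, error variance of a family mean
#' `sigma2_e = MSe / r`, phenotypic variance `sigma2_p = MSf / r`, and
#' broad-sense heritability `h2_raw = sigma2_g / sigma2_p = 1 - MSe / MSf`.
#' `h2_raw` may be negative (families less variable than error expectation);
#' `h2` is the `[0, 1]`-clamped reporting value while `h2_raw` is retained
#' because the heritability-stability ratio (see [sibh()]) is defined on the
#' unclamped estimates.
#'
#' @param ms_families,ms_error Family and error mean squares (vectorized).
#' @param n_reps Number of replicates `r` (>= 2).
#' @return A tibble with columns `sigma2_g`, `sigma2_e`, `sigma2_p`,
#'   `h2_raw`, `h2`.
#' @export
#' @examples
#' variance_components(53.089, 5.925, 3) # h2 = 0.888
variance_components <- function(ms_families, ms_error, n_reps) {
  if (any(n_reps < 2)) {
    abort("variance_components() requires n_reps >= 2.",
          class = "mahp_df_error")
  }
  h2_raw <- ifelse(ms_families == 0, 0, 1 - ms_error / ms_families)
  if (any(ms_families == 0)) {
    warn("MSf = 0: degenerate data, heritability reported as 0.")
  }
  tibble(
    sigma2_g = (ms_families - ms_error) / n_reps,
    sigma2_e = ms_error / n_reps,
    sigma2_p = ms_families / n_reps,
    h2_raw = h2_raw,
    h2 = pmin(pmax(h2_raw, 0), 1)
  )
}

#' Expected genetic advance under truncation selection
#'
#' `EGA = k * h2 * sqrt(sigma2_p)` on the family-mean basis, and
#' `EGA% = 100 * EGA / grand_mean`. Traits with `h2_raw <= 0` have no
#' heritable variance to exploit and return 0.
#'
#' @param h2_raw Unclamped heritability (see [variance_components()]).
#' @param sigma2_p Phenotypic variance of a family mean.
#' @param grand_mean Trait grand mean (non-zero).
#' @param k Selection intensity; default 2.063, the standardized selection
#'   differential for 5% truncation of a standard normal.
#' @return A tibble with columns `ega`, `ega_pct`.
#' @export
expected_genetic_advance <- function(h2_raw, sigma2_p, grand_mean, k = 2.063) {
  if (any(k <= 0)) abort("k must be > 0.", class = "mahp_parameter_error")
  if (any(grand_mean == 0)) {
    abort("EGA% undefined for grand_mean = 0.", class = "mahp_parameter_error")
  }
  h2 <- pmin(pmax(h2_raw, 0), 1)
  ega <- ifelse(h2_raw <= 0, 0, k * h2 * sqrt(sigma2_p))
  tibble(ega = ega, ega_pct = 100 * ega / grand_mean)
}

#' Genetic parameters for every trait and condition
#'
#' Convenience wrapper running [rcbd_anova()] per trait x condition and
#' deriving variance components, heritability and expected genetic advance.
#'
#' @inheritParams rcbd_anova
#' @param k Selection intensity passed to [expected_genetic_advance()].
#' @return A tibble with one row per trait x condition: `n_families`,
#'   `n_reps`, `grand_mean`, `ms_families`, `ms_error`, `f_families`,
#'   `p_families`, `signif`, `sigma2_g`, `sigma2_e`, `sigma2_p`, `h2_raw`,
#'   `h2`, `ega`, `ega_pct`.
#' @export
genetic_params <- function(data, traits = NULL, conditions = NULL, k = 2.063) {
  an <- rcbd_anova(data, traits = traits, conditions = conditions)
  wide <- an |>
    dplyr::group_by(.data$trait, .data$condition) |>
    dplyr::summarise(
      n_reps = .data$df[.data$term == "replication"] + 1L,
      n_families = .data$df[.data$term == "families"] + 1L,
      ms_families = .data$meansq[.data$term == "families"],
      ms_error = .data$meansq[.data$term == "error"],
      f_families = .data$statistic[.data$term == "families"],
      p_families = .data$p.value[.data$term == "families"],
      signif = .data$signif[.data$term == "families"],
      .groups = "drop"
    )
  means <- data |>
    dplyr::group_by(.data$trait, .data$condition) |>
    dplyr::summarise(grand_mean = mean(.data$value), .groups = "drop")
  wide <- dplyr::left_join(wide, means, by = c("trait", "condition"))
  vc <- variance_components(wide$ms_families, wide$ms_error, wide$n_reps)
  ega <- expected_genetic_advance(vc$h2_raw, vc$sigma2_p, wide$grand_mean, k)
  out <- dplyr::bind_cols(wide, vc, ega)
  # restore first-seen ordering lost to group_by
  ord <- tidyr::expand_grid(
    condition = conditions %||% first_seen(data$condition),
    trait = traits %||% first_seen(data$trait)
  )
  out <- dplyr::left_join(ord, out, by = c("condition", "trait"))
  out[, c("trait", "condition", "n_families", "n_reps", "grand_mean",
          "ms_families", "ms_error", "f_families", "p_families", "signif",
          "sigma2_g", "sigma2_e", "sigma2_p", "h2_raw", "h2",
          "ega", "ega_pct")]
}

# Genetic variance and covariance components for one condition from family /
# error mean (cross-)products of the balanced RCBD layout. x and y are
# matrices families x replicates, aligned.
cross_components <- function(x, y) {
  g <- nrow(x); r <- ncol(x)
  fx <- rowMeans(x); fy <- rowMeans(y)
  rx <- colMeans(x); ry <- colMeans(y)
  gx <- mean(x); gy <- mean(y)
  mcp_f <- r * sum((fx - gx) * (fy - gy)) / (g - 1)
  resx <- x - outer(fx, rep(1, r)) - outer(rep(1, g), rx) + gx
  resy <- y - outer(fy, rep(1, r)) - outer(rep(1, g), ry) + gy
  mcp_e <- sum(resx * resy) / ((g - 1) * (r - 1))
  list(mcp_f = mcp_f, mcp_e = mcp_e, cov_g = (mcp_f - mcp_e) / r)
}

# families x replicates value matrix for one trait and condition
trait_matrix <- function(data, trait, condition) {
  sub <- data[data$trait == trait & data$condition == condition, ]
  fams <- first_seen(data$family)
  reps <- first_seen(data$replicate)
  m <- matrix(NA_real_, length(fams), length(reps),
              dimnames = list(fams, reps))
  m[cbind(match(sub$family, fams), match(sub$replicate, reps))] <- sub$value
  m
}

#' Genetic correlation between two traits
#'
#' Estimated from the RCBD analysis of mean cross-products:
#' `cov_g = (MCPf - MCPe) / r`, and
#' `r_g = cov_g / sqrt(|sigma2_g(X)| * |sigma2_g(Y)|)` with the unclamped
#' genetic variances (absolute values guard the sign-allowed case of a
#' negative variance component). The estimator is not bounded by 1; the
#' uncapped value is what downstream weighting consumes, and a capped copy
#' clipped to `[-1, 1]` is returned for reporting.
#'
#' @param data A long-layout trial tibble.
#' @param trait_x,trait_y Trait names present in `data`.
#' @param condition Condition label.
#' @return A one-row tibble: `condition`, `trait_x`, `trait_y`, `cov_g`,
#'   `r_g`, `r_g_capped`.
#' @export
genetic_correlation <- function(data, trait_x, trait_y, condition) {
  stop_if_not_trial_cols(data)
  for (tr in c(trait_x, trait_y)) {
    if (!tr %in% unique(data$trait)) {
      abort(paste0("Trait '", tr, "' not present."),
            class = "mahp_lookup_error")
    }
  }
  x <- trait_matrix(data, trait_x, condition)
  y <- trait_matrix(data, trait_y, condition)
  sx <- cross_components(x, x)$cov_g
  sy <- cross_components(y, y)$cov_g
  if (trait_x == trait_y) {
    rg <- 1
    cv <- sx
  } else {
    if (sx == 0 || sy == 0) {
      abort(
        paste0("Genetic correlation undefined: zero genetic variance for '",
               if (sx == 0) trait_x else trait_y,
               "'. Exclude the trait or the parameter column."),
        class = "mahp_undefined_correlation_error"
      )
    }
    cv <- cross_components(x, y)$cov_g
    rg <- cv / sqrt(abs(sx) * abs(sy))
  }
  tibble(
    condition = condition, trait_x = trait_x, trait_y = trait_y,
    cov_g = cv, r_g = rg, r_g_capped = pmin(pmax(rg, -1), 1)
  )
}

#' Genetic correlations of every trait with a set of reference traits
#'
#' @inheritParams genetic_correlation
#' @param with Reference (dependent) traits; default all pairwise.
#' @param traits Traits to correlate; default all in `data`.
#' @return A tibble of [genetic_correlation()] rows.
#' @export
genetic_correlations <- function(data, condition, traits = NULL, with = NULL) {
  traits <- traits %||% first_seen(data$trait)
  with <- with %||% traits
  combos <- tidyr::expand_grid(trait_x = traits, trait_y = with)
  purrr::pmap_dfr(combos, function(trait_x, trait_y) {
    genetic_correlation(data, trait_x, trait_y, condition)
  })
}
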