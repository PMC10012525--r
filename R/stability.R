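#' Stability Index of a trait across a condition pair
#'
#' The Stability Index (SI) is the absolute value of the ordinary
#' least-squares slope of the stress-condition values (dependent) on the
#' normal-condition values (independent), computed across family means. A
#' slope near zero means the trait's expression under stress is unrelated to
#' its expression under normal conditions, which under this convention is
#' maximal stability; this differs from genotype-stability regressions where
#' slope 1 is the reference. The regression keeps its intercept; only the
#' slope is reported.
#'
#' @param normal,stress Numeric vectors of family means (same length >= 3).
#' @return A one-row tibble: `si` (absolute slope) and `si_slope` (signed).
#' @export
#' @examples
#' stability_index(c(1, 2, 3), c(2, 4, 6)) # slope 2, SI 2
stability_index <- function(normal, stress) {
  if (length(normal) != length(stress)) {
    abort("normal and stress vectors must have equal length.",
          class = "mahp_parameter_error")
  }
  if (length(normal) < 3) {
    abort("SI needs at least 3 families.", class = "mahp_sample_size_error")
  }
  if (stats::var(normal) == 0) {
    abort("SI undefined: normal-condition values are constant.",
          class = "mahp_undefined_slope_error")
  }
  slope <- unname(stats::coef(stats::lm(stress ~ normal))[2])
  tibble(si = abs(slope), si_slope = slope)
}

#' Stability Index of Broad-sense Heritability
#'
#' `SIBH = BH2 / BH1`, the ratio of a trait's broad-sense heritability under
#' stress (`BH2`) to its heritability under normal conditions (`BH1`). The
#' inputs are the UNCLAMPED heritability estimates: when a variance
#' component is negative the ratio is taken on the raw (signed) values and
#' the absolute value is reported, which is the only rule that keeps the
#' statistic defined and continuous through the near-zero-heritability
#' regime. Values above 1 indicate genetic control strengthening under
#' stress.
#'
#' @param h2_raw_normal,h2_raw_stress Unclamped heritabilities (vectorized).
#' @return A tibble with columns `sibh` (absolute) and `sibh_raw` (signed).
#' @export
#' @examples
#' sibh(0.5, 0.5) # 1
sibh <- function(h2_raw_normal, h2_raw_stress) {
  if (any(h2_raw_normal == 0)) {
    abort(
      "SIBH undefined: normal-condition heritability is exactly 0. Exclude the trait or its SIBH column.",
      class = "mahp_undefined_sibh_error"
    )
  }
  raw <- h2_raw_stress / h2_raw_normal
  tibble(sibh = abs(raw), sibh_raw = raw)
}

#' Trait stability statistics for a two-condition trial
#'
#' Computes SI (from per-condition family means) and SIBH (from unclamped
#' heritabilities) for every trait. A trait whose normal-condition
#' heritability is exactly zero gets `NA` SIBH with a message rather than an
#' error, so the remaining parameters stay usable.
#'
#' @param data A long-layout trial tibble with exactly 2 conditions; the
#'   first-seen condition (or `normal`, if present) is treated as the
#'   non-stress reference.
#' @param params Optional precomputed [genetic_params()] table (saves the
#'   ANOVA pass).
#' @return A tibble: `trait`, `si`, `si_slope`, `sibh`, `sibh_raw`.
#' @export
trait_stability <- function(data, params = NULL) {
  conds <- first_seen(data$condition)
  if (length(conds) != 2L) {
    abort("trait_stability() requires exactly 2 conditions.",
          class = "mahp_precondition_error")
  }
  cond_n <- if ("normal" %in% conds) "normal" else conds[1]
  cond_s <- setdiff(conds, cond_n)
  params <- params %||% genetic_params(data)
  traits <- first_seen(data$trait)
  mn <- family_means(data, cond_n)
  ms <- family_means(data, cond_s)
  purrr::map_dfr(traits, function(tr) {
    si <- stability_index(mn[[tr]], ms[[tr]])
    h2n <- params$h2_raw[params$trait == tr & params$condition == cond_n]
    h2s <- params$h2_raw[params$trait == tr & params$condition == cond_s]
    if (h2n == 0) {
      rlang::inform(paste0("SIBH undefined for trait '", tr,
                           "' (zero normal-condition heritability); set to NA."))
      sb <- tibble(sibh = NA_real_, sibh_raw = NA_real_)
    } else {
      sb <- sibh(h2n, h2s)
    }
    dplyr::bind_cols(tibble(trait = tr), si, sb)
  })
}
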