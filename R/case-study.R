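#' Summary tables of the bundled tomato drought-stress case study
#'
#' Plain-text fixtures from a replicated trial of 57 tomato families
#' evaluated in 3 complete blocks under normal and drought-stress
#' conditions, with 18 phenological, morphological and physiological traits
#' (design: g = 57 families, r = 3 replicates; ANOVA df 2/56/112). Only the
#' published summary statistics are bundled, not the raw plot data; values
#' carry the precision they were printed at.
#'
#' Available tables:
#' * `anova_normal`, `anova_stress` - per trait: mean squares for
#'   replication/families/error, printed significance letters (`a` = 5%,
#'   `b` = 1%), printed broad-sense heritability `h2` and expected genetic
#'   advance `ega_pct` (`NA` with `near_zero = TRUE` where printed as
#'   "~ 0", i.e. a negative variance-component estimate clamped to zero).
#' * `stability` - per retained trait (15): Stability Index `si`, `sibh`,
#'   and genetic correlations with Yld and TSS per condition (capped).
#' * `weights` - per retained trait: the eight per-parameter eigenvector
#'   entries, the final weight (their row sum), and the `important` flag.
#' * `scores` - per family: final score and selection flag (top 10).
#'
#' @param table One of `"anova_normal"`, `"anova_stress"`, `"stability"`,
#'   `"weights"`, `"scores"`.
#' @return A tibble.
#' @export
#' @examples
#' tomato_case_study("stability")
tomato_case_study <- function(table = c("anova_normal", "anova_stress",
                                        "stability", "weights", "scores")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("tomato_", table, ".csv"),
                      package = "mahpselect", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Simulation specification emulating the tomato case study
#'
#' Builds a [sim_spec()] whose variance components reproduce the bundled
#' case-study tables: per trait, `sigma2_g = (MSf - MSe) / r` (clamped at
#' 0), `sigma2_e = MSe`, block variance `(MSrep - MSe) / g` (clamped), the
#' stress slope taken from the published Stability Index, the slope-model
#' noise variance set so the stress genetic variance matches the stress
#' table, and the residual multiplier `MSe_stress / MSe_normal`. Grand
#' means are not printed in the summary tables; where the expected genetic
#' advance percentage is printed they are backed out of it
#' (`mean = 100 k h2 sqrt(MSf/r) / EGA%`, k = 2.063), otherwise typical
#' tomato values are used. The genetic-correlation matrix defaults to the
#' identity: the published tables only constrain correlations with Yld and
#' TSS, which under-determines the full matrix.
#'
#' @param genetic_correlation Optional 18 x 18 trait correlation matrix
#'   overriding the identity default.
#' @return A `sim_spec` for 57 families x 3 replicates x 18 traits.
#' @export
case_study_spec <- function(genetic_correlation = NULL) {
  an <- tomato_case_study("anova_normal")
  as_ <- tomato_case_study("anova_stress")
  st <- tomato_case_study("stability")
  r <- 3; g <- 57; k <- 2.063
  fallback_means <- c(H = 120, CN = 30, FN = 60, SFW = 67.6)
  derive_mean <- function(tab, trait) {
    i <- match(trait, tab$trait)
    if (!is.na(tab$ega_pct[i]) && tab$ega_pct[i] > 0) {
      h2 <- max(1 - tab$ms_error[i] / tab$ms_families[i], 0)
      100 * k * h2 * sqrt(tab$ms_families[i] / r) / tab$ega_pct[i]
    } else {
      NA_real_
    }
  }
  means <- purrr::map_dbl(an$trait, function(tr) {
    m <- derive_mean(an, tr)
    if (is.na(m)) m <- derive_mean(as_, tr)
    if (is.na(m)) m <- fallback_means[[tr]]
    m
  })
  sg_n <- pmax((an$ms_families - an$ms_error) / r, 0)
  sg_s <- pmax((as_$ms_families - as_$ms_error) / r, 0)
  slope <- st$si[match(an$trait, st$trait)]
  slope[is.na(slope)] <- 1
  # phenological traits are earliness traits: lower is better
  direction <- ifelse(an$trait %in% c("DTF", "DFF", "DTH"),
                      "lower_better", "higher_better")
  traits <- tibble(
    trait = an$trait, mean = means,
    sigma2_g = sg_n, sigma2_e = an$ms_error, direction = direction
  )
  means_s <- purrr::map_dbl(as_$trait, function(tr) {
    m <- derive_mean(as_, tr)
    if (is.na(m)) m <- means[match(tr, an$trait)]
    m
  })
  stress <- tibble(
    trait = an$trait,
    slope = slope,
    shift = means_s - means,
    noise_var = pmax(sg_s - slope^2 * sg_n, 0),
    error_mult = as_$ms_error / an$ms_error
  )
  sim_spec(
    traits, n_families = g, n_reps = r,
    genetic_correlation = genetic_correlation,
    stress = stress,
    block_var_normal = pmax((an$ms_replication - an$ms_error) / g, 0),
    block_var_stress = pmax((as_$ms_replication - as_$ms_error) / g, 0)
  )
}
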