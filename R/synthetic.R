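#' Specify a synthetic two-condition trial
#'
#' Defines the genetic architecture of a balanced family x replicate x
#' condition x trait trial with Gaussian family, block and residual effects
#' (the assumptions under which the RCBD estimators are derived). Stress
#' family effects follow a per-trait slope model,
#' `g_stress = slope * g_normal + noise`, which makes the slope the
#' generator's known truth for the Stability Index.
#'
#' @param traits Data frame with columns `trait`, `mean` (normal-condition
#'   grand mean), `sigma2_g` (genetic variance), `sigma2_e` (plot residual
#'   variance); optional `direction` (`"higher_better"` / `"lower_better"`).
#' @param n_families,n_reps Design size (both >= 2).
#' @param genetic_correlation Trait x trait genetic correlation matrix
#'   (symmetric positive semidefinite, unit diagonal); default identity.
#' @param stress Data frame with columns `trait` and any of `slope`
#'   (default 1), `shift` (stress mean minus normal mean, default 0),
#'   `noise_var` (variance of the slope-model noise, default 0),
#'   `error_mult` (stress residual-variance multiplier, default 1).
#' @param block_var_normal,block_var_stress Replicate (block) effect
#'   variance, scalar or per-trait vector.
#' @return A list of class `sim_spec`.
#' @seealso [simulate_trial()], [case_study_spec()]
#' @export
sim_spec <- function(traits, n_families = 57, n_reps = 3,
                     genetic_correlation = NULL, stress = NULL,
                     block_var_normal = 0, block_var_stress = 0) {
  traits <- as_tibble(traits)
  need <- c("trait", "mean", "sigma2_g", "sigma2_e")
  miss <- setdiff(need, names(traits))
  if (length(miss) > 0) {
    abort(paste0("traits is missing column(s): ", paste(miss, collapse = ", ")),
          class = "mahp_spec_error")
  }
  if (!"direction" %in% names(traits)) traits$direction <- "higher_better"
  nt <- nrow(traits)
  if (n_families < 2 || n_reps < 2) {
    abort("n_families and n_reps must be >= 2.", class = "mahp_spec_error")
  }
  if (any(traits$sigma2_g < 0) || any(traits$sigma2_e < 0)) {
    abort("Variances must be >= 0.", class = "mahp_spec_error")
  }
  R <- genetic_correlation %||% diag(nt)
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-8)) {
    abort("genetic_correlation must be symmetric with unit diagonal.",
          class = "mahp_spec_error")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("genetic_correlation must be positive semidefinite.",
          class = "mahp_spec_error")
  }
  s <- tibble(trait = traits$trait, slope = 1, shift = 0,
              noise_var = 0, error_mult = 1)
  if (!is.null(stress)) {
    stress <- as_tibble(stress)
    idx <- match(stress$trait, s$trait)
    if (anyNA(idx)) {
      abort("stress refers to unknown trait(s).", class = "mahp_spec_error")
    }
    for (col in intersect(names(stress), c("slope", "shift", "noise_var",
                                           "error_mult"))) {
      s[[col]][idx] <- stress[[col]]
    }
  }
  if (any(s$noise_var < 0) || any(s$error_mult < 0)) {
    abort("noise_var and error_mult must be >= 0.", class = "mahp_spec_error")
  }
  expand_bv <- function(bv) {
    if (length(bv) == 1) bv <- rep(bv, nt)
    if (length(bv) != nt || any(bv < 0)) {
      abort("block variance must be a scalar or per-trait vector >= 0.",
            class = "mahp_spec_error")
    }
    bv
  }
  structure(
    list(traits = traits, n_families = n_families, n_reps = n_reps,
         genetic_correlation = R, stress = s,
         block_var_normal = expand_bv(block_var_normal),
         block_var_stress = expand_bv(block_var_stress)),
    class = "sim_spec"
  )
}

# symmetric PSD square root via eigendecomposition (chol fails on
# semidefinite inputs such as the identity with zero-variance traits)
psd_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R)) %*% t(e$vectors)
}

#' Simulate a balanced two-condition trial
#'
#' Observation model per condition:
#' `value = mean + family_effect + block_effect + residual`, with family
#' effects multivariate normal across traits (covariance
#' `D %*% R %*% D`, `D = diag(sqrt(sigma2_g))`), stress family effects
#' derived through the per-trait slope model, and independent Gaussian
#' block and residual effects. Fully reproducible for a fixed seed; the
#' global RNG state is untouched.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed governing all randomness.
#' @return A validated long-layout trial tibble with conditions `normal`
#'   and `stress`.
#' @export
simulate_trial <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  g <- spec$n_families; r <- spec$n_reps
  tr <- spec$traits; nt <- nrow(tr)
  draws <- withr::with_seed(seed, {
    list(z = matrix(stats::rnorm(g * nt), g, nt),
         zs = matrix(stats::rnorm(g * nt), g, nt),
         bn = matrix(stats::rnorm(r * nt), r, nt),
         bs = matrix(stats::rnorm(r * nt), r, nt),
         en = array(stats::rnorm(g * r * nt), c(g * r, nt)),
         es = array(stats::rnorm(g * r * nt), c(g * r, nt)))
  })
  G_n <- draws$z %*% psd_sqrt(spec$genetic_correlation)
  G_n <- sweep(G_n, 2, sqrt(tr$sigma2_g), `*`)
  G_s <- sweep(G_n, 2, spec$stress$slope, `*`) +
    sweep(draws$zs, 2, sqrt(spec$stress$noise_var), `*`)
  fams <- as.character(seq_len(g))
  reps <- paste0("r", seq_len(r))
  one_condition <- function(cond, G, means, err_var, block_var, zb, ze) {
    B <- sweep(zb, 2, sqrt(block_var), `*`)
    E <- sweep(ze, 2, sqrt(err_var), `*`)
    grid <- tidyr::expand_grid(family = fams, replicate = reps)
    vals <- outer(rep(1, g * r), means) +
      G[match(grid$family, fams), , drop = FALSE] +
      B[match(grid$replicate, reps), , drop = FALSE] + E
    colnames(vals) <- tr$trait
    out <- dplyr::bind_cols(grid, as_tibble(vals))
    out$condition <- cond
    tidyr::pivot_longer(out, dplyr::all_of(tr$trait),
                        names_to = "trait", values_to = "value")
  }
  ds <- dplyr::bind_rows(
    one_condition("normal", G_n, tr$mean, tr$sigma2_e,
                  spec$block_var_normal, draws$bn, draws$en),
    one_condition("stress", G_s, tr$mean + spec$stress$shift,
                  tr$sigma2_e * spec$stress$error_mult,
                  spec$block_var_stress, draws$bs, draws$es)
  )
  validate_trial(ds[, c("family", "replicate", "condition", "trait", "value")])
}

# true (population) statistics implied by a sim_spec, on the family-mean
# basis the estimators target
sim_truth <- function(spec) {
  tr <- spec$traits; s <- spec$stress; r <- spec$n_reps
  sg_n <- tr$sigma2_g
  sg_s <- s$slope^2 * sg_n + s$noise_var
  h2_n <- ifelse(sg_n + tr$sigma2_e / r == 0, 0,
                 sg_n / (sg_n + tr$sigma2_e / r))
  h2_s <- ifelse(sg_s + tr$sigma2_e * s$error_mult / r == 0, 0,
                 sg_s / (sg_s + tr$sigma2_e * s$error_mult / r))
  tibble(
    trait = tr$trait, sigma2_g_normal = sg_n, sigma2_g_stress = sg_s,
    h2_normal = h2_n, h2_stress = h2_s,
    si = abs(s$slope),
    sibh = ifelse(h2_n == 0, NA_real_, abs(h2_s / h2_n))
  )
}

#' Parameter-recovery report for the estimators
#'
#' Simulates `n_sims` independent trials from `spec` (seeds `seed`,
#' `seed + 1`, ...) and compares the estimated heritabilities, SI, SIBH and
#' (optionally) pairwise genetic correlations with the truths implied by
#' the specification. The SI truth is the absolute stress slope, the
#' generator's definition of trait stability.
#'
#' @param spec A [sim_spec()].
#' @param n_sims Number of simulation replicates (>= 1).
#' @param seed Base seed.
#' @param pairs Optional 2-column character matrix/data frame of trait
#'   pairs for genetic-correlation recovery (normal condition); default all
#'   pairs when the spec has at most 6 traits, else none.
#' @return A tibble: `statistic`, `trait`, `truth`, `estimate` (mean over
#'   replicates), `bias`, `rmse`.
#' @export
recovery_report <- function(spec, n_sims = 20, seed = 1, pairs = NULL) {
  stopifnot(inherits(spec, "sim_spec"), n_sims >= 1)
  truth <- sim_truth(spec)
  nt <- nrow(spec$traits)
  if (is.null(pairs) && nt <= 6 && nt >= 2) {
    pairs <- t(utils::combn(spec$traits$trait, 2))
  }
  ests <- purrr::map(seq_len(n_sims), function(i) {
    ds <- simulate_trial(spec, seed = seed + i - 1)
    params <- genetic_params(ds)
    stab <- trait_stability(ds, params = params)
    rg <- if (!is.null(pairs)) {
      purrr::map_dbl(seq_len(nrow(pairs)), function(j) {
        genetic_correlation(ds, pairs[j, 1], pairs[j, 2], "normal")$r_g
      })
    }
    list(params = params, stab = stab, rg = rg)
  })
  pull_stat <- function(label, trait, truth_val, values) {
    tibble(statistic = label, trait = trait, truth = truth_val,
           estimate = mean(values), bias = mean(values) - truth_val,
           rmse = sqrt(mean((values - truth_val)^2)))
  }
  rows <- list()
  for (cond in c("normal", "stress")) {
    tv <- if (cond == "normal") truth$h2_normal else truth$h2_stress
    for (j in seq_len(nt)) {
      vals <- purrr::map_dbl(ests, function(e) {
        e$params$h2_raw[e$params$trait == truth$trait[j] &
                          e$params$condition == cond]
      })
      rows[[length(rows) + 1]] <-
        pull_stat(paste0("h2_", cond), truth$trait[j], tv[j], vals)
    }
  }
  for (j in seq_len(nt)) {
    vals <- purrr::map_dbl(ests, function(e) {
      e$stab$si[e$stab$trait == truth$trait[j]]
    })
    rows[[length(rows) + 1]] <- pull_stat("si", truth$trait[j],
                                          truth$si[j], vals)
    if (!is.na(truth$sibh[j])) {
      vals <- purrr::map_dbl(ests, function(e) {
        e$stab$sibh[e$stab$trait == truth$trait[j]]
      })
      rows[[length(rows) + 1]] <- pull_stat("sibh", truth$trait[j],
                                            truth$sibh[j], vals)
    }
  }
  if (!is.null(pairs)) {
    R <- spec$genetic_correlation
    idx <- function(t) match(t, spec$traits$trait)
    for (j in seq_len(nrow(pairs))) {
      vals <- purrr::map_dbl(ests, function(e) e$rg[j])
      rows[[length(rows) + 1]] <- pull_stat(
        "r_g", paste(pairs[j, 1], pairs[j, 2], sep = ":"),
        R[idx(pairs[j, 1]), idx(pairs[j, 2])], vals
      )
    }
  }
  dplyr::bind_rows(rows)
}
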