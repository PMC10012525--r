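#' Filter traits without exploitable genetic variation
#'
#' A trait is dropped when it shows no heritable variation in either
#' condition: the family effect non-significant at `threshold` AND the
#' clamped heritability 0 in both conditions. (A significant family F test
#' implies `MSf > MSe` and hence positive heritability, so the binding
#' criterion is the zero-heritability one; requiring both keeps marginal
#' traits whose families differ without a positive variance-component
#' estimate.) Every exclusion is logged with its reason; traits informative
#' in at least one condition are retained.
#'
#' @param params A [genetic_params()] table covering both conditions.
#' @param threshold Family F-test significance threshold (default 0.05).
#' @return A tibble: `trait`, `retained` (logical), `reason` (`NA` for
#'   retained traits).
#' @export
filter_traits <- function(params, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must be in (0, 1).", class = "mahp_parameter_error")
  }
  out <- params |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      nonsig_both = all(.data$p_families >= threshold),
      h2_zero_both = all(.data$h2 == 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      retained = !(.data$nonsig_both & .data$h2_zero_both),
      reason = dplyr::if_else(
        .data$retained, NA_character_,
        "no heritable variation: non-significant family effect and zero clamped heritability in both conditions"
      )
    )
  out <- out[match(unique(params$trait), out$trait),
             c("trait", "retained", "reason")]
  if (!any(out$retained)) {
    abort("All traits were filtered out; nothing to weight.",
          class = "mahp_empty_model_error")
  }
  out
}

#' Run the full selection pipeline
#'
#' Orchestrates trait filtering, per-condition genetic parameters, genetic
#' correlations with the dependent traits, stability statistics, trait
#' weighting, condition-averaged family scoring, and top-set selection. The
#' result is an object of class `mahp_fit` with [tidy()][generics::tidy],
#' [glance()][generics::glance], `print()` and
#' [autoplot()][ggplot2::autoplot] methods.
#'
#' The trait-parameter table fed to [trait_weights()] has, per retained
#' trait: SI, SIBH, uncapped genetic correlation with each dependent trait
#' in each condition, and EGA% in each condition. Undefined entries (zero
#' heritability or zero genetic variance) contribute 0 and are logged.
#'
#' @param data A validated two-condition long-layout trial tibble.
#' @param dependent Character vector of dependent (target) traits; must be
#'   a subset of the dataset's traits.
#' @param trait_directions Named vector over traits
#'   (`"lower_better"` / `"higher_better"`, default higher) used when
#'   scoring families, e.g. phenological earliness traits.
#' @param si_lower_better Treat the SI parameter column as lower-is-better
#'   and reflect it before normalization (default `TRUE`, following the
#'   statistic's definition). Set `FALSE` to reproduce published tables
#'   whose SI eigenvector column was built on the untransformed values.
#' @param k Selection intensity for expected genetic advance.
#' @param alpha Trait-filtering significance threshold.
#' @param top_n,top_fraction Selection size; default `top_fraction = 0.05`
#'   (matching the default `k`).
#' @param standardize Optional z-score standardization of parameter columns
#'   before the eigenvector step (off by default; the unit-norm eigenvector
#'   step is itself the scale-removing standardization).
#' @return An `mahp_fit` list: `anova`, `params`, `filter`, `correlations`,
#'   `stability`, `parameter_table`, `weights`, `scores`, `selection`,
#'   `config`, `log`.
#' @export
mahp_selection <- function(data, dependent,
                           trait_directions = NULL,
                           si_lower_better = TRUE,
                           k = 2.063, alpha = 0.05,
                           top_n = NULL, top_fraction = NULL,
                           standardize = FALSE) {
  data <- validate_trial(data)
  conds <- first_seen(data$condition)
  if (length(conds) != 2L) {
    abort("mahp_selection() [stability stage] requires exactly 2 conditions.",
          class = "mahp_precondition_error")
  }
  cond_n <- if ("normal" %in% conds) "normal" else conds[1]
  cond_s <- setdiff(conds, cond_n)
  traits <- first_seen(data$trait)
  missing_dep <- setdiff(dependent, traits)
  if (length(missing_dep) > 0) {
    abort(paste0("Dependent trait(s) not in dataset: ",
                 paste(missing_dep, collapse = ", ")),
          class = "mahp_lookup_error")
  }
  log <- character()
  note <- function(stage, msg) {
    log <<- c(log, paste0("[", stage, "] ", msg))
  }
  note("data", paste0(length(unique(data$family)), " families, ",
                      length(unique(data$replicate)), " replicates, ",
                      length(conds), " conditions, ",
                      length(traits), " traits"))

  an <- rcbd_anova(data)
  params <- genetic_params(data, k = k)
  filt <- filter_traits(params, threshold = alpha)
  for (i in which(!filt$retained)) {
    note("filter", paste0("dropped '", filt$trait[i], "': ", filt$reason[i]))
  }
  retained <- filt$trait[filt$retained]
  if (length(setdiff(dependent, retained)) > 0) {
    abort(paste0("Dependent trait(s) filtered out: ",
                 paste(setdiff(dependent, retained), collapse = ", ")),
          class = "mahp_empty_model_error")
  }

  stab <- trait_stability(
    data[data$trait %in% retained, ],
    params = params[params$trait %in% retained, ]
  )
  cors <- dplyr::bind_rows(
    genetic_correlations(data, cond_n, traits = retained, with = dependent),
    genetic_correlations(data, cond_s, traits = retained, with = dependent)
  )

  # assemble the trait x parameter table
  ptab <- tibble(trait = retained)
  ptab$SI <- stab$si[match(retained, stab$trait)]
  sibh_col <- stab$sibh[match(retained, stab$trait)]
  if (anyNA(sibh_col)) {
    for (tr in retained[is.na(sibh_col)]) {
      note("parameters", paste0("SIBH undefined for '", tr,
                                "'; contributes 0 to the SIBH column"))
    }
    sibh_col[is.na(sibh_col)] <- 0
  }
  ptab$SIBH <- sibh_col
  cond_tag <- c("N", "S")
  names(cond_tag) <- c(cond_n, cond_s)
  for (dep in dependent) {
    for (cc in c(cond_n, cond_s)) {
      col <- paste0("rg_", dep, "_", cond_tag[[cc]])
      sub <- cors[cors$condition == cc & cors$trait_y == dep, ]
      ptab[[col]] <- sub$r_g[match(retained, sub$trait_x)]
    }
  }
  pn <- params[params$condition == cond_n, ]
  ps <- params[params$condition == cond_s, ]
  ptab$EGA_N <- pn$ega_pct[match(retained, pn$trait)]
  ptab$EGA_S <- ps$ega_pct[match(retained, ps$trait)]

  if (standardize) {
    for (p in setdiff(names(ptab), "trait")) {
      s <- stats::sd(ptab[[p]])
      if (s > 0) ptab[[p]] <- (ptab[[p]] - mean(ptab[[p]])) / s
    }
    note("parameters", "z-score standardization applied to parameter columns")
  }

  dir_params <- c(SI = if (si_lower_better) "lower_better" else "higher_better")
  weights <- trait_weights(ptab, directions = dir_params)
  note("weights", paste0("SI column ",
                         if (si_lower_better) "reflected (lower is better)"
                         else "used untransformed (reproduction mode)"))

  avg <- condition_average(data)[, c("family", retained)]
  scores <- family_scores(avg, weights, directions = trait_directions)
  if (is.null(top_n) && is.null(top_fraction)) top_fraction <- 0.05
  selection <- select_top(scores[, c("family", "score")],
                          count = top_n, fraction = top_fraction)
  note("selection", paste0(sum(selection$selected), " of ",
                           nrow(selection), " families selected"))

  structure(
    list(
      anova = an, params = params, filter = filt, correlations = cors,
      stability = stab, parameter_table = ptab, weights = weights,
      scores = scores, selection = selection,
      config = list(
        dependent = dependent, trait_directions = trait_directions,
        si_lower_better = si_lower_better, k = k, alpha = alpha,
        top_n = top_n, top_fraction = top_fraction,
        standardize = standardize,
        condition_normal = cond_n, condition_stress = cond_s
      ),
      log = log
    ),
    class = "mahp_fit"
  )
}

#' @export
print.mahp_fit <- function(x, ...) {
  g <- glance(x)
  cat("Multi-trait selection fit (MAHP)\n")
  cat(sprintf("  families: %d   replicates: %d   traits: %d (retained %d)\n",
              g$n_families, g$n_reps, g$n_traits, g$n_retained))
  cat(sprintf("  dependent: %s   k = %.3f   alpha = %.2f\n",
              paste(x$config$dependent, collapse = ", "),
              x$config$k, x$config$alpha))
  sel <- x$selection$family[x$selection$selected]
  cat(sprintf("  selected %d families: %s\n", length(sel),
              paste(sel, collapse = ", ")))
  top <- utils::head(x$weights[order(-x$weights$final_weight),
                               c("trait", "final_weight")], 5)
  cat("  top trait weights:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-8s %.3f\n", top$trait[i], top$final_weight[i]))
  }
  invisible(x)
}

#' Write all pipeline outputs as CSV plus a Markdown report
#'
#' Writes `anova.csv`, `params.csv`, `rg.csv`, `stability.csv`,
#' `weights.csv`, `scores.csv` and `report.md` to `dir`. Output is
#' deterministic: identical fits yield byte-identical files.
#'
#' @param fit An [mahp_selection()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mahp_results <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_csv(as_tibble(x), file.path(dir, f))
  w(fit$anova, "anova.csv")
  w(fit$params, "params.csv")
  w(fit$correlations, "rg.csv")
  w(fit$stability, "stability.csv")
  w(fit$weights, "weights.csv")
  w(fit$selection, "scores.csv")
  g <- glance(fit)
  report <- c(
    "# Multi-trait selection report", "",
    sprintf("- families: %d; replicates: %d", g$n_families, g$n_reps),
    sprintf("- traits measured: %d; retained after filtering: %d",
            g$n_traits, g$n_retained),
    sprintf("- dependent traits: %s", paste(fit$config$dependent, collapse = ", ")),
    sprintf("- selection intensity k = %.3f; filter alpha = %.2f",
            fit$config$k, fit$config$alpha),
    sprintf("- families selected: %d (%s)", g$n_selected,
            paste(fit$selection$family[fit$selection$selected], collapse = ", ")),
    "", "## Log", "", paste0("- ", fit$log)
  )
  writeLines(report, file.path(dir, "report.md"))
  invisible(dir)
}

#' Read a pipeline configuration file
#'
#' YAML schema (all fields optional except `dependent`): `dependent`
#' (character vector), `trait_directions` (map trait -> direction),
#' `si_lower_better` (logical), `k`, `alpha`, `top_n`, `top_fraction`,
#' `standardize`. The returned list can be spliced into
#' [mahp_selection()] with `do.call()`.
#'
#' @param path YAML file path.
#' @return A named list of arguments.
#' @export
read_mahp_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("dependent", "trait_directions", "si_lower_better", "k",
               "alpha", "top_n", "top_fraction", "standardize")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown config field(s): ", paste(bad, collapse = ", ")),
          class = "mahp_format_error")
  }
  if (!is.null(cfg$trait_directions)) {
    cfg$trait_directions <- unlist(cfg$trait_directions)
  }
  cfg
}
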