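#' Read a replicated two-condition trial table
#'
#' Reads a balanced family x replicate x condition x trait table from CSV.
#' The long layout (the canonical interchange format) has columns `family`,
#' `replicate`, `condition`, `trait`, `value`; the wide layout has columns
#' `family`, `replicate`, `condition` followed by one numeric column per
#' trait. Identifier order is preserved as first seen in the file, never
#' sorted, so downstream eigenvector and weight tables align positionally
#' with the input.
#'
#' @param path Path to a CSV file (UTF-8, header row).
#' @param layout `"long"` (default) or `"wide"`.
#' @param conditions Admissible condition labels, in canonical order. The
#'   model is defined for the pair `c("normal", "stress")`; aliases can be
#'   supplied here (first element = non-stress condition).
#' @return A validated tibble in long layout with columns `family`,
#'   `replicate`, `condition`, `trait`, `value`.
#' @seealso [validate_trial()], [write_trial()], [simulate_trial()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_trial(simulate_trial(sim_spec(
#'   traits = data.frame(trait = "Yld", mean = 10, sigma2_g = 1, sigma2_e = 1),
#'   n_families = 4, n_reps = 2
#' ), seed = 1), path)
#' read_trial(path)
read_trial <- function(path, layout = c("long", "wide"),
                       conditions = c("normal", "stress")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "mahp_format_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (layout == "wide") {
    need <- c("family", "replicate", "condition")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      abort(paste0("Wide layout is missing column(s): ",
                   paste(miss, collapse = ", "), "."),
            class = "mahp_format_error")
    }
    trait_cols <- setdiff(names(raw), need)
    if (length(trait_cols) == 0) {
      abort("Wide layout has no trait columns.", class = "mahp_format_error")
    }
    raw <- tidyr::pivot_longer(raw, dplyr::all_of(trait_cols),
                               names_to = "trait", values_to = "value")
  } else {
    stop_if_not_trial_cols(raw)
    raw <- raw[, c("family", "replicate", "condition", "trait", "value")]
  }
  value_num <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(value_num) & !is.na(raw$value))
  if (length(bad) > 0) {
    abort(
      paste0("Non-numeric trait value at row ", bad[1], ": '",
             raw$value[bad[1]], "'."),
      class = "mahp_parse_error"
    )
  }
  raw$value <- value_num
  validate_trial(as_tibble(raw), conditions = conditions)
}

#' Validate a trial data frame
#'
#' Checks the long-layout contract: required columns, numeric finite values,
#' admissible condition labels (1 or 2 of them), and a fully balanced design
#' (every family x replicate x condition x trait cell present exactly once).
#' Missing or duplicated cells are hard errors listing the offending cells;
#' nothing is imputed.
#'
#' @param data A data frame with columns `family`, `replicate`, `condition`,
#'   `trait`, `value`.
#' @inheritParams read_trial
#' @return The validated data as a tibble (invisibly usable in a pipe).
#' @export
validate_trial <- function(data, conditions = c("normal", "stress")) {
  stop_if_not_trial_cols(data)
  data <- as_tibble(data)
  data$family <- as.character(data$family)
  data$replicate <- as.character(data$replicate)
  data$condition <- as.character(data$condition)
  data$trait <- as.character(data$trait)
  if (!is.numeric(data$value)) {
    abort("Column `value` must be numeric.", class = "mahp_parse_error")
  }
  if (any(!is.finite(data$value))) {
    abort(
      paste0("Missing or non-finite value at row ",
             which(!is.finite(data$value))[1],
             "; the balanced-design estimators do not impute."),
      class = "mahp_parse_error"
    )
  }
  conds <- first_seen(data$condition)
  bad_cond <- setdiff(conds, conditions)
  if (length(bad_cond) > 0) {
    abort(paste0("Unknown condition label(s): ",
                 paste(bad_cond, collapse = ", "),
                 ". Expected among: ", paste(conditions, collapse = ", "), "."),
          class = "mahp_format_error")
  }
  if (!length(conds) %in% c(1L, 2L)) {
    abort("Dataset must contain exactly 1 or 2 conditions.",
          class = "mahp_format_error")
  }
  fams <- first_seen(data$family)
  reps <- first_seen(data$replicate)
  traits <- first_seen(data$trait)
  grid <- tidyr::expand_grid(
    family = fams, replicate = reps, condition = conds, trait = traits
  )
  counts <- dplyr::count(data, .data$family, .data$replicate,
                         .data$condition, .data$trait)
  full <- dplyr::left_join(
    grid, counts, by = c("family", "replicate", "condition", "trait")
  )
  full$n[is.na(full$n)] <- 0L
  off <- full[full$n != 1L, ]
  if (nrow(off) > 0) {
    cells <- utils::head(
      paste0("(", off$family, ", ", off$replicate, ", ", off$condition,
             ", ", off$trait, ") x", off$n),
      10L
    )
    abort(
      paste0("Unbalanced design: ", nrow(off),
             " cell(s) not observed exactly once: ",
             paste(cells, collapse = "; "),
             if (nrow(off) > 10) " ..." else ""),
      class = "mahp_balance_error"
    )
  }
  data
}

#' Write a trial dataset as a long-layout CSV
#'
#' @param data A validated long-layout trial tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(data, path) {
  stop_if_not_trial_cols(data)
  readr::write_csv(
    data[, c("family", "replicate", "condition", "trait", "value")], path
  )
  invisible(path)
}

#' Per-family trait means for one condition
#'
#' Averages over replicates within the given condition, returning one row
#' per family and one column per trait, in first-seen input order.
#'
#' @param data A long-layout trial tibble.
#' @param condition A condition label present in `data`.
#' @return A tibble with column `family` followed by one numeric column per
#'   trait.
#' @export
family_means <- function(data, condition) {
  stop_if_not_trial_cols(data)
  if (!condition %in% unique(data$condition)) {
    abort(paste0("Condition '", condition, "' not present in the data."),
          class = "mahp_lookup_error")
  }
  fams <- first_seen(data$family)
  traits <- first_seen(data$trait)
  sub <- data[data$condition == condition, ]
  out <- sub |>
    dplyr::group_by(.data$family, .data$trait) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  out <- out[match(fams, out$family), c("family", traits)]
  as_tibble(out)
}

#' Family means averaged over the two conditions
#'
#' Elementwise mean of the per-condition family-mean tables; the basis for
#' family scoring when trait behaviour is similar across conditions.
#'
#' @param data A long-layout trial tibble with exactly 2 conditions.
#' @return A tibble shaped like [family_means()].
#' @export
condition_average <- function(data) {
  conds <- first_seen(data$condition)
  if (length(conds) != 2L) {
    abort("condition_average() requires exactly 2 conditions.",
          class = "mahp_precondition_error")
  }
  m1 <- family_means(data, conds[1])
  m2 <- family_means(data, conds[2])
  out <- m1
  traits <- setdiff(names(m1), "family")
  out[traits] <- (m1[traits] + m2[traits]) / 2
  out
}
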