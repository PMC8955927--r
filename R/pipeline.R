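#' Load a per-trial report-error table
#'
#' Reads and validates the trial CSV schema (`subject_id`, `experiment`,
#' `report_condition`, `set_size`, `cue_delay_ms`, `error_deg`, optionally
#' `hidden_route`). Errors outside `(-180, 180]` are wrapped onto the domain
#' with a warning; malformed rows (non-numeric error, negative delay,
#' set size < 1, missing fields) are rejected with their line numbers.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated trial tibble.
#' @export
load_trials <- function(path) {
  raw <- tryCatch(
    suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                                     progress = FALSE)),
    error = function(e) abort(sprintf("cannot read '%s': %s", path,
                                      conditionMessage(e)),
                              class = "memmixr_parse_error")
  )
  if (nrow(raw) == 0) {
    abort(sprintf("'%s' contains no trials.", path),
          class = "memmixr_parse_error")
  }
  required <- c("subject_id", "experiment", "report_condition", "set_size",
                "cue_delay_ms", "error_deg")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "memmixr_parse_error")
  }
  err_num <- suppressWarnings(as.numeric(raw$error_deg))
  ss_num <- suppressWarnings(as.numeric(raw$set_size))
  cd_num <- suppressWarnings(as.numeric(raw$cue_delay_ms))
  bad <- which(!is.finite(err_num) | !is.finite(ss_num) | !is.finite(cd_num) |
                 ss_num < 1 | cd_num < 0 | is.na(raw$subject_id))
  if (length(bad) > 0) {
    abort(sprintf("malformed rows at data line(s): %s",
                  paste(head(bad, 20), collapse = ", ")),
          class = "memmixr_parse_error")
  }
  out_of_range <- err_num <= -180 | err_num > 180
  if (any(out_of_range)) {
    warn(sprintf("%d error(s) outside (-180, 180] wrapped onto the domain (first at data line %d).",
                 sum(out_of_range), which(out_of_range)[1]))
    err_num <- wrap_error(err_num)
  }
  dplyr::mutate(tibble::as_tibble(raw),
                error_deg = err_num,
                set_size = as.integer(ss_num),
                cue_delay_ms = cd_num)
}

#' Fit a mixture in every design cell
#'
#' Groups the trial table by the given keys and fits each cell
#' independently (no parameter sharing across delays or set sizes). The
#' per-cell seed is derived from `opts$seed` plus the cell index, so the
#' whole table is deterministic.
#'
#' @param trials A trial tibble (see [load_trials()]).
#' @param by Character vector of grouping columns.
#' @param opts A [fit_options()].
#' @return A tibble with one row per cell: the grouping keys, `n_obs`, a
#'   `fit` list column of `mixture_fit`s, and the [glance()] columns.
#' @export
fit_cells <- function(trials,
                      by = c("subject_id", "report_condition", "set_size",
                             "cue_delay_ms"),
                      opts = fit_options()) {
  by <- intersect(by, names(trials))
  nested <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  fits <- purrr::imap(nested$data, function(d, i) {
    o <- opts
    o$seed <- opts$seed + i
    suppressWarnings(fit_mixture(d$error_deg, o))
  })
  nested |>
    dplyr::mutate(n_obs = purrr::map_int(.data$data, nrow),
                  fit = fits) |>
    dplyr::select(-"data") |>
    dplyr::bind_cols(dplyr::bind_rows(purrr::map(fits, glance)) |>
                       dplyr::select(-"n_obs"))
}

#' Summarise a fitted cell as intake, precision and accuracy
#'
#' Extracts the leaky-flask quantities from a fit: intake (total Gaussian
#' weight, the proportion of trials answered from stored information), guess
#' rate (`1 - intake`), and the accuracy (mean), SD and precision (`1/SD`)
#' of a designated component (default the most precise one). A pure-uniform
#' fit has intake 0 and its precision/accuracy are reported as missing, not
#' zero.
#'
#' @param fit A `mixture_fit`.
#' @param keys Optional named list of condition identifiers prepended to the
#'   output row.
#' @param component Index of the designated component after SD-ascending
#'   sort (1 = most precise). Must not exceed the number of fitted
#'   components.
#' @return A one-row tibble: keys, `intake`, `guess_rate`, `accuracy`,
#'   `precision`, `sd`, `n_components`.
#' @export
summarize_condition <- function(fit, keys = list(), component = 1L) {
  stopifnot(inherits(fit, "mixture_fit"))
  cmp <- fit$spec$components
  n <- nrow(cmp)
  if (n > 0 && (component < 1 || component > n)) {
    abort(sprintf("component %d requested but fit has %d.", component, n),
          class = "memmixr_domain_error")
  }
  base <- if (n == 0) {
    tibble::tibble(intake = 0, guess_rate = 1, accuracy = NA_real_,
                   precision = NA_real_, sd = NA_real_, n_components = 0L)
  } else {
    tibble::tibble(intake = sum(cmp$weight),
                   guess_rate = fit$spec$uniform_weight,
                   accuracy = cmp$mu[component],
                   precision = 1 / cmp$sigma[component],
                   sd = cmp$sigma[component],
                   n_components = n)
  }
  dplyr::bind_cols(tibble::as_tibble(keys), base)
}

#' Intake/precision summaries for every cell
#'
#' Convenience wrapper: [fit_cells()] then [summarize_condition()] per row.
#'
#' @inheritParams fit_cells
#' @param component Designated component index (see
#'   [summarize_condition()]).
#' @return A tibble of per-cell summaries.
#' @export
condition_summaries <- function(trials,
                                by = c("subject_id", "report_condition",
                                       "set_size", "cue_delay_ms"),
                                opts = fit_options(n_components = 1),
                                component = 1L) {
  cells <- fit_cells(trials, by = by, opts = opts)
  by <- intersect(by, names(cells))
  purrr::pmap(cells, function(...) {
    row <- list(...)
    summarize_condition(row$fit, keys = row[by], component = component)
  }) |>
    dplyr::bind_rows()
}

#' BIC winner map over design cells
#'
#' Runs [compare_models()] in every cell and arranges winners and runners-up
#' as a grid over conditions x subjects, the standard display for asking how
#' many Gaussian components the data want. Cells whose comparison fails are
#' flagged and excluded from the tally.
#'
#' @inheritParams fit_cells
#' @param n_list Candidate component counts.
#' @return An object of class `winner_map`: a tibble with the grouping keys,
#'   `winner`, `runner_up`, `delta_bic` (runner-up BIC minus winner BIC),
#'   `n_obs` and `failed`; the attribute `"tally"` counts winners by n.
#' @export
winner_map <- function(trials,
                       by = c("subject_id", "report_condition", "set_size",
                              "cue_delay_ms"),
                       opts = fit_options(), n_list = 1:5) {
  by <- intersect(by, names(trials))
  nested <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  k <- min(10 * 3 * max(n_list), 200)
  res <- purrr::imap(nested$data, function(d, i) {
    if (nrow(d) < k) {
      warn(sprintf("cell %d has only %d trials; comparisons may be unstable.",
                   i, nrow(d)))
    }
    o <- opts
    o$seed <- opts$seed + 97L * i
    tryCatch(suppressWarnings(compare_models(d$error_deg, o, n_list)),
             error = function(e) NULL)
  })
  out <- nested |>
    dplyr::mutate(
      n_obs = purrr::map_int(.data$data, nrow),
      failed = purrr::map_lgl(res, is.null),
      winner = purrr::map_int(res, ~ if (is.null(.x)) NA_integer_ else .x$winner),
      runner_up = purrr::map_int(res, ~ if (is.null(.x)) NA_integer_ else
        as.integer(.x$runner_up)),
      delta_bic = purrr::map_dbl(res, ~ if (is.null(.x) || is.na(.x$runner_up))
        NA_real_ else .x$table$delta_bic[.x$table$n_components == .x$runner_up]),
      comparison = res
    ) |>
    dplyr::select(-"data")
  attr(out, "tally") <- out |>
    dplyr::filter(!.data$failed) |>
    dplyr::count(.data$winner, name = "cells")
  class(out) <- c("winner_map", class(out))
  out
}

#' Per-cell component SDs from two-Gaussian fits
#'
#' Long table of fitted component SDs labelled `sigma1`, `sigma2`, ... in
#' SD-ascending order, the input to [sigma_trend_test()].
#'
#' @param cell_fits Output of [fit_cells()].
#' @return A tibble with the grouping keys plus `component` and `sd`.
#' @export
component_sds <- function(cell_fits) {
  keys <- setdiff(names(cell_fits),
                  c("fit", "n_obs", "n_components", "log_likelihood", "bic",
                    "n_free_params", "converged", "boundary"))
  cell_fits |>
    dplyr::select(dplyr::all_of(keys), "fit") |>
    dplyr::mutate(comp = purrr::map(.data$fit, function(f) {
      cmp <- f$spec$components
      tibble::tibble(component = paste0("sigma", seq_len(nrow(cmp))),
                     sd = cmp$sigma, weight = cmp$weight)
    })) |>
    dplyr::select(-"fit") |>
    tidyr::unnest("comp")
}

#' Does a component SD depend on cue delay?
#'
#' One-way repeated-measures ANOVA of a fitted component SD across cue-delay
#' levels with subjects as blocks (sphericity uncorrected, giving the
#' conventional `F(levels - 1, (levels - 1) * (subjects - 1))`), plus a
#' seeded within-subject permutation test of monotone trend as a
#' distribution-free alternative for small samples. The permutation
#' statistic is the mean across subjects of the correlation between the SD
#' and the rank of the delay, which is insensitive to the occasional
#' degenerate cell fit; delay labels are permuted within each subject and
#' the p value is two-sided.
#'
#' @param sigma_df Long tibble with columns `subject_id`, `cue_delay_ms`,
#'   `component`, `sd` (see [component_sds()]); every subject must have one
#'   value at every delay for the chosen component.
#' @param component Which component to test (e.g. `"sigma1"`, `"sigma2"`).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation draw.
#' @return An object of class `trend_test`: a one-row tibble with
#'   `component`, `f_statistic`, `df1`, `df2`, `p_value`, `perm_p`,
#'   `trend_stat` (the observed mean rank correlation); the attribute
#'   `"sigma_matrix"` holds the subjects x delays wide table.
#' @export
sigma_trend_test <- function(sigma_df, component = "sigma2", n_perm = 2000,
                             seed = 1L) {
  d <- dplyr::filter(sigma_df, .data$component == !!component)
  wide <- tidyr::pivot_wider(d[, c("subject_id", "cue_delay_ms", "sd")],
                             names_from = "cue_delay_ms",
                             values_from = "sd")
  miss <- which(!complete.cases(wide))
  if (length(miss) > 0 || nrow(d) == 0) {
    missing_cells <- d |>
      tidyr::complete(.data$subject_id, .data$cue_delay_ms) |>
      dplyr::filter(is.na(.data$sd))
    abort(paste0("missing component '", component, "' fits for: ",
                 paste(sprintf("%s@%gms", missing_cells$subject_id,
                               missing_cells$cue_delay_ms), collapse = ", ")),
          class = "memmixr_domain_error")
  }
  d <- dplyr::mutate(d, subject_f = factor(.data$subject_id),
                     delay_f = factor(.data$cue_delay_ms))
  n_lvl <- nlevels(d$delay_f); n_sub <- nlevels(d$subject_f)
  fit <- aov(sd ~ delay_f + Error(subject_f), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  f_stat <- tab["delay_f", "F value"]
  p_val <- tab["delay_f", "Pr(>F)"]
  # permutation of monotone trend: mean per-subject correlation of the SD
  # with the delay rank (robust to single-cell fit degeneracies)
  delay_rank <- rank(unique(sort(as.numeric(as.character(d$delay_f)))))
  mat <- as.matrix(wide[, as.character(sort(as.numeric(setdiff(names(wide),
                                                               "subject_id"))))])
  trend_stat <- function(m) {
    mean(apply(m, 1, function(y) {
      if (stats::sd(y) < 1e-12) 0 else cor(delay_rank, y)
    }))
  }
  obs <- trend_stat(mat)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      trend_stat(t(apply(mat, 1, sample)))
    }, numeric(1))
  })
  perm_p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  out <- tibble::tibble(component = component, f_statistic = f_stat,
                        df1 = n_lvl - 1, df2 = (n_lvl - 1) * (n_sub - 1),
                        p_value = p_val, perm_p = perm_p,
                        trend_stat = obs)
  attr(out, "sigma_matrix") <- wide
  class(out) <- c("trend_test", class(out))
  out
}

#' Classify delay dependence of the two component SDs
#'
#' The SM/attention/STM architecture predicts exactly one of the two
#' component SDs depends on cue delay; the parallel-routes architecture
#' predicts both do. Given trend tests for `sigma1` and `sigma2` (per
#' condition), labels each condition `"C-consistent"` (exactly one
#' significant), `"D-consistent"` (both significant) or `"indeterminate"`
#' (neither), and records the evidence.
#'
#' @param trends A tibble binding [sigma_trend_test()] rows, with an
#'   optional `report_condition` column.
#' @param alpha Significance level (default 0.05).
#' @param use_permutation Base the calls on the permutation p instead of the
#'   ANOVA p.
#' @return A tibble with one row per condition: p values for each component,
#'   the significance calls and the `verdict`.
#' @export
model_c_vs_d_verdict <- function(trends, alpha = 0.05,
                                 use_permutation = FALSE) {
  pcol <- if (use_permutation) "perm_p" else "p_value"
  if (!"report_condition" %in% names(trends)) {
    trends$report_condition <- "all"
  }
  trends |>
    dplyr::mutate(p = .data[[pcol]]) |>
    dplyr::select("report_condition", "component", "p") |>
    tidyr::pivot_wider(names_from = "component", values_from = "p",
                       names_prefix = "p_") |>
    dplyr::mutate(
      sigma1_significant = .data$p_sigma1 < alpha,
      sigma2_significant = .data$p_sigma2 < alpha,
      verdict = dplyr::case_when(
        xor(.data$sigma1_significant, .data$sigma2_significant) ~ "C-consistent",
        .data$sigma1_significant & .data$sigma2_significant ~ "D-consistent",
        TRUE ~ "indeterminate"
      )
    )
}
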