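#' Tidy a cohort summary table
#'
#' Returns the paired-test rows of a `cohort_table` as a plain tibble, one
#' row per parameter and window, in broom-style column names.
#'
#' @param x A `cohort_table` from [summarize_cohort()].
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `window`, `mean_lv`, `sd_lv`,
#'   `mean_rv`, `sd_rv`, `statistic`, `df`, `p.value`, `p.holm`, `n_pairs`.
#' @export
tidy.cohort_table <- function(x, ...) {
  df <- as_tibble(x)
  df <- dplyr::filter(df, !is.na(.data$p_value))
  dplyr::select(df, "parameter", "window",
                "mean_lv", "sd_lv", "mean_rv", "sd_rv",
                statistic = "t", "df", p.value = "p_value",
                p.holm = "p_holm", "n_pairs")
}

#' Glance at a cohort summary table
#'
#' @param x A `cohort_table` from [summarize_cohort()].
#' @param ... Unused.
#' @return A one-row tibble: `n_parameters`, `n_windows`, `n_pairs`,
#'   `n_significant` (raw p < 0.05), `n_significant_holm`.
#' @export
glance.cohort_table <- function(x, ...) {
  df <- dplyr::filter(as_tibble(x), !is.na(.data$p_value))
  tibble(
    n_parameters = dplyr::n_distinct(df$parameter),
    n_windows = dplyr::n_distinct(df$window),
    n_pairs = if (nrow(df)) max(df$n_pairs) else NA_integer_,
    n_significant = sum(df$p_value < 0.05),
    n_significant_holm = sum(df$p_holm < 0.05)
  )
}

#' Tidy an estimator sweep
#'
#' @param x An `egm_sweep`.
#' @param ... Unused.
#' @return The sweep as a plain tibble in long format (one row per grid
#'   cell and measure, columns `measure` and `bits`).
#' @export
tidy.egm_sweep <- function(x, ...) {
  cols <- intersect(c("h_x", "h_y", "h_lv", "h_rv", "h_joint", "mi"), names(x))
  tidyr::pivot_longer(as_tibble(x), dplyr::all_of(cols),
                      names_to = "measure", values_to = "bits")
}

#' Glance at an estimator sweep
#'
#' @param x An `egm_sweep`.
#' @param ... Unused.
#' @return A one-row tibble with the grid extents and, for cardiac sweeps,
#'   whether the MI estimate reached a plateau.
#' @export
glance.egm_sweep <- function(x, ...) {
  tibble(
    kind = attr(x, "kind") %||% NA_character_,
    n_cells = nrow(x),
    binwidth_min = min(x$bin_width),
    binwidth_max = max(x$bin_width),
    n_min = if ("n" %in% names(x)) min(x$n) else NA_integer_,
    n_max = if ("n" %in% names(x)) max(x$n) else NA_integer_,
    plateau_reached = attr(x, "plateau_reached") %||% NA
  )
}
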