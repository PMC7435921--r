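#' Paired Student t-test
#'
#' Thin, validating wrapper around [stats::t.test()] with `paired = TRUE`:
#' `t = mean(a - b) / (sd(a - b) / sqrt(n))` on `n - 1` degrees of freedom,
#' two-sided p-value. All-zero (or constant) differences make the statistic
#' undefined and raise a "degenerate paired test" error.
#'
#' @param a,b Aligned numeric vectors of equal length n >= 2.
#' @return A one-row tibble: `estimate` (mean difference), `t`, `df`, `p`,
#'   `n_pairs`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 3, 5))
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2) abort("Need at least 2 pairs.")
  d <- a - b
  if (sd(d) <= 1e-10 * max(abs(d), 1)) {
    abort("Degenerate paired test: differences have zero variance.")
  }
  tt <- tryCatch(t.test(a, b, paired = TRUE), error = function(e) {
    abort(sprintf("Degenerate paired test: %s", conditionMessage(e)))
  })
  tibble(
    estimate = unname(tt$estimate),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    n_pairs = length(a)
  )
}

#' Collect spectral and information-theoretic parameters for a cohort
#'
#' Runs [extract_spectral_params()] for each pair and window and
#' [estimate_pair_info()] per pair, returning one long tibble of
#' per-patient parameter values ready for [summarize_cohort()]. Channelled
#' parameters (spectral set plus `h` from the entropy estimates) carry a
#' `channel`; pair-level measures (`h_joint`, `mi`) are labelled
#' `channel = "pair"`.
#'
#' @param pairs A named list of [egm_pair()] objects (as from
#'   [simulate_vf_cohort()]).
#' @param windows Character subset of `c("W1", "W2")`.
#' @param bin_width Shared histogram bin width for the entropy measures
#'   (applied to z-scored channels), default 0.4833.
#' @return A tibble: `patient`, `channel`, `window`, `parameter`, `value`.
#' @export
cohort_params <- function(pairs, windows = c("W1", "W2"), bin_width = 0.4833) {
  windows <- match.arg(windows, several.ok = TRUE)
  spec <- purrr::map_dfr(pairs, function(p) {
    purrr::map_dfr(windows, function(w) extract_spectral_params(p, w))
  })
  spec_long <- tidyr::pivot_longer(
    spec, -c("patient", "channel", "window"),
    names_to = "parameter", values_to = "value")
  info <- purrr::map_dfr(pairs, function(p) {
    purrr::map_dfr(windows, function(w) {
      dplyr::mutate(estimate_pair_info(segment_window(p, w), bin_width),
                    window = w)
    })
  })
  info_long <- dplyr::bind_rows(
    tibble(patient = info$patient, channel = "LV", window = info$window,
           parameter = "h", value = info$h_lv),
    tibble(patient = info$patient, channel = "RV", window = info$window,
           parameter = "h", value = info$h_rv),
    tibble(patient = info$patient, channel = "pair", window = info$window,
           parameter = "h_joint", value = info$h_joint),
    tibble(patient = info$patient, channel = "pair", window = info$window,
           parameter = "mi", value = info$mi)
  )
  dplyr::bind_rows(spec_long, info_long)
}

#' Cohort summary table with paired LV-vs-RV tests
#'
#' Aggregates long-format per-patient parameters into a summary in the
#' style of the cohort table: per parameter and window, mean and SD for
#' each channel and the paired Student t-test across patients. Patients
#' missing either channel for a parameter are dropped from that row with a
#' warning. Pair-level parameters (without an LV/RV split) are summarized
#' by mean and SD only. Raw two-sided p-values are reported (with an "ns"
#' text rendering at the 0.05 threshold); a Holm-adjusted column is added
#' for reference across the tested rows.
#'
#' @param params Long tibble from [cohort_params()] (columns `patient`,
#'   `channel`, `window`, `parameter`, `value`).
#' @return A tibble of class `cohort_table`: `parameter`, `window`,
#'   `mean_lv`, `sd_lv`, `mean_rv`, `sd_rv`, `t`, `df`, `p_value`,
#'   `p_holm`, `p_text`, `n_pairs`.
#' @export
summarize_cohort <- function(params) {
  needed <- c("patient", "channel", "window", "parameter", "value")
  if (!all(needed %in% names(params))) {
    abort(sprintf("`params` must have columns %s.",
                  paste(needed, collapse = ", ")))
  }
  if (dplyr::n_distinct(params$patient) < 2) {
    abort("Need at least 2 patients for a cohort summary.")
  }
  chan <- dplyr::filter(params, .data$channel %in% c("LV", "RV"))
  wide <- tidyr::pivot_wider(chan, names_from = "channel",
                             values_from = "value")
  dropped <- dplyr::filter(wide, is.na(.data$LV) | is.na(.data$RV))
  if (nrow(dropped) > 0) {
    warn(sprintf("Dropping %d patient-parameter rows with a missing channel (%s).",
                 nrow(dropped),
                 paste(unique(dropped$patient), collapse = ", ")))
    wide <- dplyr::filter(wide, !is.na(.data$LV) & !is.na(.data$RV))
  }
  tested <- wide |>
    dplyr::group_by(.data$parameter, .data$window) |>
    dplyr::summarise(
      mean_lv = mean(.data$LV), sd_lv = sd(.data$LV),
      mean_rv = mean(.data$RV), sd_rv = sd(.data$RV),
      test = list(paired_t_test(.data$LV, .data$RV)),
      .groups = "drop"
    ) |>
    tidyr::unnest("test") |>
    dplyr::select(-"estimate")
  tested$p_holm <- stats::p.adjust(tested$p, method = "holm")
  tested$p_text <- ifelse(tested$p >= 0.05, "ns",
                          formatC(tested$p, digits = 3, format = "g"))
  tested <- dplyr::rename(tested, p_value = "p")

  pairlevel <- dplyr::filter(params, .data$channel == "pair") |>
    dplyr::group_by(.data$parameter, .data$window) |>
    dplyr::summarise(
      mean_lv = NA_real_, sd_lv = NA_real_,
      mean_rv = NA_real_, sd_rv = NA_real_,
      t = NA_real_, df = NA_real_, p_value = NA_real_,
      p_holm = NA_real_, p_text = NA_character_,
      n_pairs = dplyr::n(),
      mean_pair = mean(.data$value), sd_pair = sd(.data$value),
      .groups = "drop"
    )
  out <- dplyr::bind_rows(
    dplyr::mutate(tested, mean_pair = NA_real_, sd_pair = NA_real_),
    pairlevel
  ) |>
    dplyr::arrange(.data$window, .data$parameter)
  structure(out, class = c("cohort_table", class(out)))
}

#' Render a cohort table as aligned text
#'
#' One line per parameter and window, mirroring the cohort-table layout:
#' `parameter  LV mean +/- sd  RV mean +/- sd  p` (with "ns" for p >= 0.05).
#'
#' @param tbl A `cohort_table` from [summarize_cohort()].
#' @return A character vector of report lines, invisibly printed.
#' @export
cohort_report <- function(tbl) {
  stopifnot(inherits(tbl, "cohort_table"))
  fmt <- function(m, s) {
    ifelse(is.na(m), "-", sprintf("%.3g ± %.2g", m, s))
  }
  lines <- sprintf("%-8s %-3s %16s %16s %8s",
                   tbl$parameter, tbl$window,
                   fmt(tbl$mean_lv, tbl$sd_lv),
                   fmt(tbl$mean_rv, tbl$sd_rv),
                   ifelse(is.na(tbl$p_text),
                          fmt(tbl$mean_pair, tbl$sd_pair), tbl$p_text))
  header <- sprintf("%-8s %-3s %16s %16s %8s",
                    "param", "win", "LV", "RV", "p")
  c(header, lines)
}
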