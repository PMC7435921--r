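#' Construct a single-channel electrogram recording
#'
#' An `egm_recording` is a tibble with columns `time` (seconds) and `value`
#' (amplitude in recorded units; device gain is arbitrary, so downstream
#' parameters must not assume calibrated millivolts). Sampling rate, patient
#' id and channel label travel as attributes.
#'
#' @param value Numeric vector of samples (finite, non-empty).
#' @param fs Sampling rate in Hz (> 0); the cohort convention is 200 Hz.
#' @param patient Patient identifier string.
#' @param channel `"LV"` or `"RV"`.
#' @return A tibble of class `egm_recording`.
#' @export
egm_recording <- function(value, fs = 200, patient = "P01",
                          channel = c("LV", "RV")) {
  channel <- match.arg(channel)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (length(value) == 0 || !is.numeric(value) || !all(is.finite(value))) {
    abort("`value` must be a non-empty numeric vector of finite samples.")
  }
  out <- tibble(time = (seq_along(value) - 1) / fs, value = as.numeric(value))
  structure(out,
            fs = fs, patient = patient, channel = channel,
            class = c("egm_recording", class(out)))
}

#' Construct a paired LV/RV electrogram recording
#'
#' An `egm_pair` holds two simultaneously recorded channels on a shared time
#' base, as a tibble with columns `time`, `lv`, `rv`.
#'
#' @param lv,rv Numeric sample vectors of equal length, or `egm_recording`
#'   objects with equal length, `fs` and patient id.
#' @param fs Sampling rate in Hz (ignored when recordings are supplied).
#' @param patient Patient identifier.
#' @return A tibble of class `egm_pair` with attributes `fs` and `patient`.
#' @examples
#' p <- egm_pair(sin(2 * pi * 5 * (0:599) / 200), rnorm(600), patient = "P01")
#' @export
egm_pair <- function(lv, rv, fs = 200, patient = "P01") {
  if (inherits(lv, "egm_recording")) {
    fs <- attr(lv, "fs"); patient <- attr(lv, "patient"); lv <- lv$value
  }
  if (inherits(rv, "egm_recording")) {
    if (!isTRUE(all.equal(attr(rv, "fs"), fs))) {
      abort("LV and RV recordings must share the same sampling rate.")
    }
    rv <- rv$value
  }
  if (length(lv) != length(rv)) {
    abort(sprintf("LV and RV must have equal length (got %d and %d).",
                  length(lv), length(rv)))
  }
  if (length(lv) == 0 || !all(is.finite(lv)) || !all(is.finite(rv))) {
    abort("Samples must be non-empty and finite.")
  }
  out <- tibble(time = (seq_along(lv) - 1) / fs,
                lv = as.numeric(lv), rv = as.numeric(rv))
  structure(out,
            fs = fs, patient = patient,
            class = c("egm_pair", class(out)))
}

#' Extract one channel of a pair as an `egm_recording`
#'
#' @param pair An [egm_pair()].
#' @param channel `"LV"` or `"RV"` (case-insensitive).
#' @return An [egm_recording()].
#' @export
egm_channel <- function(pair, channel = c("LV", "RV")) {
  channel <- match.arg(toupper(channel), c("LV", "RV"))
  stopifnot(inherits(pair, "egm_pair"))
  v <- if (channel == "LV") pair$lv else pair$rv
  egm_recording(v, fs = attr(pair, "fs"), patient = attr(pair, "patient"),
                channel = channel)
}

#' Read a paired electrogram from the package's ASCII dialect
#'
#' The dialect is whitespace-delimited plain text: optional header/comment
#' lines starting with `#` (`key=value`, e.g. `# fs=200`, `# patient=P01`),
#' then one row per sample with three numeric columns `time_s LV RV`.
#' The sampling rate defaults to 200 Hz when no `fs` header is present.
#'
#' @param path Path to an ASCII EGM file.
#' @return An [egm_pair()].
#' @export
read_egm_ascii <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  fs <- NA_real_
  patient <- NA_character_
  lv <- numeric(0); rv <- numeric(0)
  data_lines <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- trimws(sub("^#", "", ln))
      if (grepl("=", kv, fixed = TRUE)) {
        key <- trimws(sub("=.*$", "", kv))
        val <- trimws(sub("^[^=]*=", "", kv))
        if (key == "fs") fs <- suppressWarnings(as.numeric(val))
        if (key == "patient") patient <- val
      }
      next
    }
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(fields) != 3) {
      abort(sprintf(
        "Parse error at line %d of %s: expected 3 columns (time LV RV), got %d.",
        i, path, length(fields)))
    }
    num <- suppressWarnings(as.numeric(fields))
    if (anyNA(num)) {
      abort(sprintf("Parse error at line %d of %s: non-numeric cell.", i, path))
    }
    data_lines <- data_lines + 1L
    lv[data_lines] <- num[2]
    rv[data_lines] <- num[3]
  }
  if (data_lines == 0L) abort(sprintf("No sample rows found in %s.", path))
  if (is.na(fs)) fs <- 200
  if (is.na(patient)) {
    patient <- sub("\\.[^.]*$", "", basename(path))
  }
  egm_pair(lv, rv, fs = fs, patient = patient)
}

#' Write a paired electrogram in the package's ASCII dialect
#'
#' Values are printed with 6 decimal places; the write/read round trip is
#' lossless to that precision.
#'
#' @param pair An [egm_pair()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_egm_ascii <- function(pair, path) {
  stopifnot(inherits(pair, "egm_pair"))
  hdr <- c(sprintf("# fs=%s", format(attr(pair, "fs"))),
           sprintf("# patient=%s", attr(pair, "patient")))
  rows <- sprintf("%.6f %.6f %.6f", pair$time, pair$lv, pair$rv)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Extract one of the two 3-second analysis windows
#'
#' Windows are half-open in time: `W1` covers t in \[0 s, 3 s) and `W2`
#' covers t in \[3 s, 6 s), so at 200 Hz each window holds exactly 600
#' samples and the two windows partition the first six seconds with no
#' shared sample.
#'
#' @param pair An [egm_pair()].
#' @param window `"W1"` or `"W2"`.
#' @return An [egm_pair()] restricted to the window (time restarts at 0).
#' @export
segment_window <- function(pair, window = c("W1", "W2")) {
  window <- match.arg(window)
  stopifnot(inherits(pair, "egm_pair"))
  fs <- attr(pair, "fs")
  start_s <- if (window == "W1") 0 else 3
  end_s <- start_s + 3
  n_need <- round(end_s * fs)
  if (nrow(pair) < n_need) {
    abort(sprintf(
      "Recording too short for %s: need %.1f s (%d samples), have %.2f s (%d).",
      window, end_s, n_need, nrow(pair) / fs, nrow(pair)))
  }
  idx <- seq.int(round(start_s * fs) + 1L, n_need)
  egm_pair(pair$lv[idx], pair$rv[idx], fs = fs, patient = attr(pair, "patient"))
}
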