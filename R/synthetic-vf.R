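#' Configure the VF-like paired-signal generator
#'
#' The generator emulates near-periodic fibrillation electrograms as a
#' harmonic ladder: each channel is the sum over harmonic order k of
#' `envelope[k] * sin(2*pi*k*f0*t + phase_k(t))` plus broadband Gaussian
#' noise. `phase_k(t)` integrates a slowly varying relative frequency jitter
#' and starts from a random initial phase per harmonic. The jitter
#' trajectory, initial phases and noise are mixed between channels in
#' proportion to `coupling`: 0 gives independent stochastic components, 1
#' gives identical ones, and the mixing is variance-preserving
#' (`sqrt(coupling) * shared + sqrt(1 - coupling) * own`).
#'
#' Envelope entries whose harmonic frequency `k * f0` would reach the
#' Nyquist frequency are truncated with a warning.
#'
#' @param f0 Fundamental frequency in Hz (0 < f0 < fs/2). Default 4.74 Hz,
#'   the cohort-scale fundamental of induced VF.
#' @param duration Signal length in seconds (default 6, i.e. two 3-s
#'   analysis windows at 200 Hz).
#' @param fs Sampling rate in Hz (default 200).
#' @param envelope_lv,envelope_rv Non-negative relative harmonic amplitudes;
#'   element k belongs to harmonic k*f0.
#' @param jitter_sd Relative standard deviation of the instantaneous
#'   frequency fluctuation (unitless, e.g. 0.03 = 3%).
#' @param noise_sd_lv,noise_sd_rv Broadband noise standard deviations
#'   (signal units).
#' @param coupling Shared fraction of the stochastic components, in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A validated config list of class `vf_config`.
#' @export
vf_config <- function(f0 = 4.74, duration = 6, fs = 200,
                      envelope_lv = vf_envelope_preset("LV"),
                      envelope_rv = vf_envelope_preset("RV"),
                      jitter_sd = 0.03,
                      noise_sd_lv = 0.35, noise_sd_rv = 0.18,
                      coupling = 0.5, seed = NULL) {
  if (!is.numeric(f0) || f0 <= 0 || f0 >= fs / 2) {
    abort("`f0` must satisfy 0 < f0 < fs/2.")
  }
  if (coupling < 0 || coupling > 1) abort("`coupling` must lie in [0, 1].")
  if (any(envelope_lv < 0) || any(envelope_rv < 0)) {
    abort("Envelopes must be non-negative.")
  }
  if (jitter_sd < 0 || noise_sd_lv < 0 || noise_sd_rv < 0) {
    abort("`jitter_sd` and noise standard deviations must be non-negative.")
  }
  trunc_env <- function(env, which) {
    keep <- which(seq_along(env) * f0 < fs / 2)
    if (length(keep) < length(env)) {
      warn(sprintf("Truncating %s envelope to %d harmonics below Nyquist.",
                   which, length(keep)))
      env <- env[keep]
    }
    env
  }
  envelope_lv <- trunc_env(envelope_lv, "LV")
  envelope_rv <- trunc_env(envelope_rv, "RV")
  if (sum(envelope_lv) + sum(envelope_rv) == 0 &&
      noise_sd_lv == 0 && noise_sd_rv == 0) {
    abort("Degenerate silent signal: all-zero envelopes with zero noise.")
  }
  structure(list(f0 = f0, duration = duration, fs = fs,
                 envelope_lv = envelope_lv, envelope_rv = envelope_rv,
                 jitter_sd = jitter_sd,
                 noise_sd_lv = noise_sd_lv, noise_sd_rv = noise_sd_rv,
                 coupling = coupling, seed = seed),
            class = "vf_config")
}

#' Channel envelope presets emulating the cohort's spectral contrast
#'
#' The LV preset concentrates power at the fourth harmonic (a dominant
#' frequency well above the fundamental, high-pass envelope) while the RV
#' preset concentrates power at the fundamental (low-pass envelope, hence a
#' higher organization index and leakage). These reproduce the direction of
#' the cohort-level LV/RV contrasts, not their absolute magnitudes.
#'
#' @param channel `"LV"` or `"RV"`.
#' @return Numeric vector of relative harmonic amplitudes.
#' @export
vf_envelope_preset <- function(channel = c("LV", "RV")) {
  channel <- match.arg(channel)
  switch(channel,
    LV = c(0.55, 0.40, 0.50, 1.00, 0.45),
    RV = c(1.00, 0.35, 0.45, 0.28, 0.22)
  )
}

# Smoothed standard-normal trajectory (moving average, ~win_s seconds wide),
# renormalized to unit variance so jitter_sd keeps its meaning.
smooth_noise <- function(n, fs, win_s = 0.25) {
  w <- max(1L, round(win_s * fs))
  e <- rnorm(n + w - 1)
  u <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 1))
  u <- u[w:(n + w - 1)]
  u * sqrt(w)
}

#' Generate a coupled pair of VF-like electrograms
#'
#' @param config A [vf_config()].
#' @param patient Patient identifier attached to the pair.
#' @return An [egm_pair()] of `round(duration * fs)` samples.
#' @examples
#' pair <- simulate_vf_pair(vf_config(seed = 1))
#' @export
simulate_vf_pair <- function(config = vf_config(), patient = "P01") {
  stopifnot(inherits(config, "vf_config"))
  gen <- function() {
    n <- round(config$duration * config$fs)
    fs <- config$fs
    c_sh <- sqrt(config$coupling)
    c_own <- sqrt(1 - config$coupling)
    kmax <- max(length(config$envelope_lv), length(config$envelope_rv))

    # Shared and per-channel stochastic components, mixed variance-preserving.
    jit_shared <- smooth_noise(n, fs)
    jit_own <- list(lv = smooth_noise(n, fs), rv = smooth_noise(n, fs))
    ph0_shared <- runif(kmax, 0, 2 * pi)
    ph0_own <- list(lv = runif(kmax, -pi, pi), rv = runif(kmax, -pi, pi))
    noise_shared <- rnorm(n)
    noise_own <- list(lv = rnorm(n), rv = rnorm(n))

    channel <- function(env, noise_sd, ch) {
      jit <- c_sh * jit_shared + c_own * jit_own[[ch]]
      # instantaneous frequency f0 * (1 + jitter_sd * jit), phase by cumsum
      base_phase <- 2 * pi * cumsum(config$f0 * (1 + config$jitter_sd * jit)) / fs
      x <- numeric(n)
      for (k in seq_along(env)) {
        if (env[k] == 0) next
        ph0 <- ph0_shared[k] + (1 - config$coupling) * ph0_own[[ch]][k]
        x <- x + env[k] * sin(k * base_phase + ph0)
      }
      x + noise_sd * (c_sh * noise_shared + c_own * noise_own[[ch]])
    }
    lv <- channel(config$envelope_lv, config$noise_sd_lv, "lv")
    rv <- channel(config$envelope_rv, config$noise_sd_rv, "rv")
    egm_pair(lv, rv, fs = fs, patient = patient)
  }
  if (is.null(config$seed)) gen() else withr::with_seed(config$seed, gen())
}

#' Simulate a synthetic VF cohort standing in for the patient recordings
#'
#' Generates `n_patients` paired 6-second recordings at 200 Hz. Each
#' patient draws a fundamental frequency from N(4.74, 0.5) Hz (truncated to
#' \[3.2, 6.4\] Hz, matching the cohort-scale spread of the fundamental),
#' perturbs the channel envelope presets by lognormal factors (sd 0.15 on
#' the log scale), and jitters the noise levels by +/-20%. Per-patient seeds
#' are `seed + patient index`, so any subset of the cohort is reproducible.
#'
#' @param n_patients Number of patients (default 22).
#' @param seed Integer seed for the whole cohort.
#' @param coupling Inter-channel coupling shared by all patients.
#' @param f0_mean,f0_sd Mean and SD of the per-patient fundamental (Hz).
#' @param output_dir Optional directory; when given, each pair is written in
#'   the ASCII dialect (`P01.txt`, ...) together with `ground_truth.csv`.
#' @return A list with `pairs` (named list of [egm_pair()]) and
#'   `ground_truth` (tibble: patient, seed, f0, coupling, noise and
#'   envelope columns per channel).
#' @export
simulate_vf_cohort <- function(n_patients = 22, seed = 1, coupling = 0.5,
                               f0_mean = 4.74, f0_sd = 0.5,
                               output_dir = NULL) {
  ids <- sprintf("P%02d", seq_len(n_patients))
  pairs <- vector("list", n_patients)
  names(pairs) <- ids
  truth <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    seed_i <- seed + i
    par_i <- withr::with_seed(seed_i, {
      f0 <- min(max(rnorm(1, f0_mean, f0_sd), 3.2), 6.4)
      list(
        f0 = f0,
        env_lv = vf_envelope_preset("LV") * exp(rnorm(5, 0, 0.15)),
        env_rv = vf_envelope_preset("RV") * exp(rnorm(5, 0, 0.15)),
        noise_lv = 0.35 * runif(1, 0.8, 1.2),
        noise_rv = 0.18 * runif(1, 0.8, 1.2)
      )
    })
    cfg <- vf_config(
      f0 = par_i$f0,
      envelope_lv = par_i$env_lv, envelope_rv = par_i$env_rv,
      noise_sd_lv = par_i$noise_lv, noise_sd_rv = par_i$noise_rv,
      coupling = coupling, seed = seed_i + 1000L
    )
    pairs[[i]] <- simulate_vf_pair(cfg, patient = ids[i])
    truth[[i]] <- tibble(
      patient = ids[i], seed = seed_i, f0 = par_i$f0, coupling = coupling,
      noise_sd_lv = par_i$noise_lv, noise_sd_rv = par_i$noise_rv,
      env_lv = paste(signif(par_i$env_lv, 6), collapse = ";"),
      env_rv = paste(signif(par_i$env_rv, 6), collapse = ";")
    )
  }
  truth <- dplyr::bind_rows(truth)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids) {
      write_egm_ascii(pairs[[id]], file.path(output_dir, paste0(id, ".txt")))
    }
    readr::write_csv(truth, file.path(output_dir, "ground_truth.csv"))
  }
  list(pairs = pairs, ground_truth = truth)
}
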