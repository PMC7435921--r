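test_that("Welch estimator follows the 256/128/4096 segmentation contract", {
  set.seed(42)
  x <- rnorm(600)
  spec <- welch_psd(x, fs = 200)
  expect_equal(attr(spec, "n_segments"), 3L)   # floor((600-256)/128)+1
  expect_equal(attr(spec, "resolution"), 200 / 4096)
  expect_equal(attr(spec, "mainlobe"), 200 / 256)
  expect_equal(nrow(spec), 2049)
  expect_error(welch_psd(rnorm(255), fs = 200), "at least 256")
  expect_equal(attr(welch_psd(rnorm(1200), fs = 200), "n_segments"), 8L)
})

test_that("every spectrum integrates to unit area", {
  for (s in 1:3) {
    set.seed(s)
    spec <- welch_psd(rnorm(600 + 100 * s), fs = 200)
    expect_equal(sum(spec$pn) * attr(spec, "resolution"), 1, tolerance = 1e-9)
    expect_true(all(spec$pn >= 0))
  }
})

test_that("Welch matches a brute-force segment-loop DFT oracle to 1e-9", {
  set.seed(7)
  x <- sin(2 * pi * 4.7 * (0:599) / 200) + 0.5 * rnorm(600)
  spec <- welch_psd(x, fs = 200)
  oracle <- brute_welch(x, fs = 200)
  expect_equal(spec$freq, oracle$freq)
  expect_lt(max(abs(spec$pn - oracle$pn)) / max(oracle$pn), 1e-9)
})

test_that("a pure sinusoid peaks at its frequency", {
  spec <- welch_psd(egm_recording(sin(2 * pi * 5 * (0:599) / 200)))
  expect_lt(abs(spec$freq[which.max(spec$pn)] - 5), 200 / 256)
  expect_lt(abs(dominant_frequency(spec) - 5), 200 / 256)
  harm <- detect_harmonics(spec)
  expect_equal(attr(harm, "f0"), dominant_frequency(spec))
})

test_that("mean frequency is the in-band spectral centroid", {
  freq <- seq(0, 100, by = 0.05)
  two_peaks <- 1e-9 + (freq == 10) + (freq == 20)
  spec <- egm_spectrum(freq, two_peaks, fs = 200)
  expect_equal(mean_frequency(spec), 15, tolerance = 1e-6)

  flat <- egm_spectrum(freq, rep(1, length(freq)), fs = 200)
  expect_equal(mean_frequency(flat), 16, tolerance = 0.05)

  sine <- welch_psd(egm_recording(sin(2 * pi * 5 * (0:599) / 200)))
  expect_lt(abs(mean_frequency(sine) - 5), 0.5)
})

test_that("75% bandwidth interpolates crossings and flags one-sided walks", {
  freq <- seq(0, 50, by = 0.05)
  pn <- rep(1e-9, length(freq))
  pn[freq > 10 & freq < 12] <- 1
  pn[freq == 10 | freq == 12] <- 0.75
  spec <- egm_spectrum(freq, pn, fs = 100)
  bw <- bandwidth_75(spec, 11)
  expect_equal(as.numeric(bw), 2, tolerance = 1e-9)
  expect_false(attr(bw, "one_sided"))

  # monotone decay from the first bin: the left walk hits the spectrum edge
  dec <- egm_spectrum(freq, exp(-freq), fs = 100)
  expect_true(attr(bandwidth_75(dec, 0), "one_sided"))

  sine <- welch_psd(egm_recording(sin(2 * pi * 5 * (0:599) / 200)))
  expect_lt(as.numeric(bandwidth_75(sine, dominant_frequency(sine))), 1.5)
})

test_that("organization index matches the band-length ratio on flat spectra", {
  freq <- seq(0, 100, by = 0.05)
  spec <- egm_spectrum(freq, rep(1, length(freq)), fs = 200)
  fake_harm <- tibble::tibble(freq = 16)
  expect_lt(abs(organization_index(spec, fake_harm, half_width = 0.5) - 1 / 28),
            0.002)
  # default half-width is one mainlobe width
  expect_lt(abs(organization_index(spec, fake_harm) -
                  2 * attr(spec, "mainlobe") / 28), 0.002)
})

test_that("noiseless harmonic signals are highly organized", {
  pair <- simulate_vf_pair(quick_noiseless_cfg(seed = 31))
  spec <- welch_psd(egm_channel(segment_window(pair, "W1"), "LV"))
  expect_gt(organization_index(spec, detect_harmonics(spec)), 0.9)
})

test_that("OI and LK are invariant to amplitude scaling", {
  pair <- simulate_vf_pair(vf_config(seed = 15))
  rec <- egm_channel(segment_window(pair, "W1"), "LV")
  scaled <- egm_recording(7.3 * rec$value, fs = 200)
  s1 <- welch_psd(rec); s2 <- welch_psd(scaled)
  h1 <- detect_harmonics(s1); h2 <- detect_harmonics(s2)
  expect_equal(organization_index(s1, h1), organization_index(s2, h2),
               tolerance = 1e-9)
  expect_equal(leakage(rec, attr(h1, "f0")),
               leakage(scaled, attr(h2, "f0")), tolerance = 1e-9)
})

test_that("leakage has closed-form behaviour on sinusoids", {
  t <- (0:1199) / 200
  expect_equal(leakage(sin(2 * pi * 5 * t + 1.3), 5, fs = 200), 1,
               tolerance = 1e-6)
  # equal-power noise attenuates the correlation to sqrt(SNR/(1+SNR))
  set.seed(3)
  x <- sin(2 * pi * 5 * t) + sqrt(0.5) * rnorm(1200)
  expect_equal(leakage(x, 5, fs = 200), 1 / sqrt(2), tolerance = 0.05)
  expect_error(leakage(rep(1, 600), 5, fs = 200), "Zero-variance")
})

test_that("dominant frequency never falls below the comb base", {
  for (s in 1:10) {
    pair <- simulate_vf_pair(vf_config(seed = 400 + s))
    sp <- extract_spectral_params(pair, "W1")
    expect_true(all(sp$df_hz >= sp$f0 - 200 / 4096))
  }
})

test_that("broadband noise degrades organization monotonically", {
  med <- sapply(c(0, 0.3, 0.6), function(nsd) {
    vals <- sapply(1:20, function(s) {
      cfg <- vf_config(envelope_lv = vf_envelope_preset("RV"),
                       envelope_rv = vf_envelope_preset("RV"),
                       noise_sd_lv = nsd, noise_sd_rv = nsd, seed = 600 + s)
      rec <- egm_channel(segment_window(simulate_vf_pair(cfg), "W1"), "LV")
      spec <- welch_psd(rec)
      harm <- detect_harmonics(spec)
      c(oi = organization_index(spec, harm), lk = leakage(rec, attr(harm, "f0")))
    })
    apply(vals, 1, median)
  })
  expect_true(all(diff(med["oi", ]) <= 0))
  expect_true(all(diff(med["lk", ]) <= 0))
})

test_that("extract_spectral_params composes the full parameter vector", {
  cfg <- vf_config(f0 = 5, envelope_lv = 1, envelope_rv = 1, jitter_sd = 0,
                   noise_sd_lv = 0, noise_sd_rv = 0, seed = 44)
  sp <- extract_spectral_params(simulate_vf_pair(cfg), "W1")
  expect_equal(nrow(sp), 2)
  expect_named(sp, c("patient", "channel", "window", "f0", "df_hz", "f_mean",
                     paste0("pn_f", 0:5), "bw_f0", "bw_f1", "oi", "lk"))
  expect_equal(sp$f0, sp$df_hz)            # single-peak case
  expect_true(all(sp$oi > 0.9))
  expect_true(all(sp$lk > 0.999))

  # stationary synthetic: the two windows agree
  pair <- simulate_vf_pair(quick_noiseless_cfg(seed = 45))
  w1 <- extract_spectral_params(pair, "W1")
  w2 <- extract_spectral_params(pair, "W2")
  expect_lt(max(abs(w1$f0 - w2$f0)), 200 / 256)
  expect_lt(max(abs(w1$oi - w2$oi)), 0.05)
})
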