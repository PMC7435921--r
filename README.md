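# vfegm

Spectral and information-theoretic analysis of paired left- and
right-ventricular electrograms (EGMs) during ventricular fibrillation (VF).

During VF the two ventricles can behave very differently: a fast, relatively
organized driver in one chamber may coexist with passive, irregular
activation in the other. Biventricular defibrillator devices record both
chambers simultaneously at 200 Hz, and short (seconds-long) paired traces
are often all that is available. `vfegm` is aimed at cardiac
electrophysiology and biomedical signal-processing researchers who want to
characterize such paired recordings with two complementary toolboxes:

* **Welch-periodogram spectral parameters.** Each 3-second analysis window
  (W1 = 0–3 s, W2 = 3–6 s) is split into 256-sample segments with 50%
  overlap, tapered with a rectangular window, zero-padded to a 4096-point
  transform, averaged, and normalized to unit area, giving the power
  spectrum P_n(f) in 1/Hz. From it the package extracts, per channel: the
  fundamental frequency f0 (FF, found by comb-spacing maximization over the
  2–10 Hz range), the dominant frequency DF (global maximum of P_n in the
  2–30 Hz band), the mean frequency f_mean (spectral centroid of the band),
  the harmonic peak amplitudes P_n(f0)…P_n(f5) at f_k = (k+1)·f0, the 75%
  bandwidths BW(f0) and BW(f1), the organization index
  OI = ∫_harmonic bands P_n df / ∫_2–30 Hz P_n df, and the leakage
  LK = max_φ corr(x, sin(2π f0 t + φ)).
* **Histogram information measures.** Differential entropy
  H(x) = −Σ p̂ log2 p̂ + log2(Δb), joint entropy H(x, y) (square Δb×Δb
  cells) and mutual information MI = H(x) + H(y) − H(x, y), all in bits,
  with bin edges anchored at integer multiples of the bin width Δb so the
  corrections cancel exactly in MI. Bias diagnostics sweep the sample count
  N and Δb to expose the small-N saturation regime and the large-N plateau,
  and a per-recording Δb sweep (cohort grid 0.2336–0.6952, default
  Δb = 0.4833 on z-scored channels) reports estimate stability.

A synthetic-data module stands in for patient recordings: bivariate
Gaussian sample sets with known closed-form entropies/MI validate the
estimators, and a VF-like generator (harmonic ladder with channel-specific
envelopes, frequency jitter, broadband noise, and a tunable inter-channel
coupling) produces paired 6-second EGMs with known ground truth, including
a 22-patient emulated cohort whose LV/RV contrasts (higher DF in the LV,
higher OI and LK in the RV) can be tested with paired Student t-tests.

Everything is tidyverse-native: recordings, spectra and result tables are
tibbles, results have `tidy()`/`glance()` methods, and `autoplot()` draws
traces, spectra and sweep diagnostics.

## Worked example

```r
library(vfegm)

pair <- simulate_vf_pair(vf_config(seed = 42), patient = "P01")
extract_spectral_params(pair, "W1")
#>   patient channel window    f0 df_hz f_mean pn_f0  pn_f1 ... bw_f0 bw_f1    oi    lk
#> 1 P01     LV      W1      4.74 18.9   15.8  0.172 0.0869 ... 0.464 0.530 0.819 0.363
#> 2 P01     RV      W1      4.69  4.69   8.28 0.832 0.109  ... 0.453 0.431 0.889 0.805
```

Both channels share the ~4.7 Hz fundamental, but the LV envelope peaks at
the fourth harmonic (DF 18.9 Hz, low leakage 0.36) while the RV is
dominated by its fundamental (DF = f0, OI 0.89, LK 0.81) — the LV looks
fast and disorganized, the RV slow and sinusoid-like.

```r
estimate_pair_info(pair, bin_width = 0.4833)
#>   patient  h_lv  h_rv h_joint    mi bin_width n_samples n_occupied_bins
#> 1 P01      1.99  1.84    3.64 0.198     0.483      1200              94
```

At the shared bin width the two channels carry about 2 bits of differential
entropy each and share ~0.2 bits of mutual information (the generator's
coupling was 0.5).

A full cohort run writes CSV tables plus a manifest and is byte-reproducible
under its seed:

```r
res <- run_pipeline(simulate = list(n_patients = 22), seed = 7,
                    output_dir = "run")
writeLines(cohort_report(res$cohort))
#> param    win               LV               RV        p
#> f0       W1       4.6 ± 0.51     4.61 ± 0.51       ns
#> f_mean   W1       15.2 ± 1.7      8.02 ± 1.5 1.15e-18
#> oi       W1     0.82 ± 0.049   0.886 ± 0.013 1.58e-06
#> h        W1     1.99 ± 0.038     1.9 ± 0.078  7.7e-05
#> ...
```

f0 does not differ between chambers while DF, f_mean and the organization
measures do — the designed direction of the cohort contrasts. A thin CLI
wrapper lives at `inst/cli/vfegm-pipeline.R`
(`Rscript vfegm-pipeline.R --simulate --seed 7 --out run/`).

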