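# Independent brute-force oracles, deliberately naive implementations.

# Welch periodogram by explicit segment loop and explicit DFT sum.
brute_welch <- function(x, fs, seg_len = 256L, nfft = 4096L) {
  x <- x - mean(x)
  hop <- seg_len %/% 2L
  n_seg <- (length(x) - seg_len) %/% hop + 1L
  half <- nfft %/% 2L + 1L
  acc <- numeric(half)
  tt <- 0:(seg_len - 1L)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1L) * hop + 1L):((s - 1L) * hop + seg_len)]
    for (k in 0:(half - 1L)) {
      X <- sum(seg * exp(-2i * pi * k * tt / nfft))
      acc[k + 1L] <- acc[k + 1L] + Mod(X)^2
    }
  }
  p <- acc / n_seg
  freq <- (0:(half - 1L)) * fs / nfft
  list(freq = freq, pn = p / (sum(p) * (fs / nfft)))
}

# Plug-in differential entropy by per-sample tallying.
brute_entropy <- function(x, bw) {
  idx <- floor(x / bw)
  n <- length(x)
  H <- 0
  for (u in unique(idx)) {
    p <- sum(idx == u) / n
    H <- H - p * log2(p)
  }
  H + log2(bw)
}

brute_joint_entropy <- function(x, y, bw) {
  key <- paste(floor(x / bw), floor(y / bw))
  n <- length(x)
  H <- 0
  for (u in unique(key)) {
    p <- sum(key == u) / n
    H <- H - p * log2(p)
  }
  H + 2 * log2(bw)
}

gauss_h <- 0.5 * log2(2 * pi * exp(1))   # differential entropy of N(0,1), bits

quick_noiseless_cfg <- function(f0 = 4.74, seed = 3) {
  vf_config(f0 = f0, envelope_lv = rep(1, 5), envelope_rv = rep(1, 5),
            jitter_sd = 0, noise_sd_lv = 0, noise_sd_rv = 0, seed = seed)
}
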