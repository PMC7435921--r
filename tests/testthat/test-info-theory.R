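test_that("entropy estimates recover closed forms for standard densities", {
  set.seed(1)
  e <- estimate_entropy(rnorm(1e5), 0.05)
  expect_equal(e$value, gauss_h, tolerance = 0.05 / gauss_h)
  expect_equal(e$n_samples, 1e5)

  u <- estimate_entropy(runif(1e5), 0.1)   # h(U(0,1)) = 0 bits
  expect_lt(abs(u$value), 0.01)
})

test_that("small samples at tiny bins collapse to the saturation bias", {
  set.seed(2)
  e <- estimate_entropy(rnorm(100), 1e-3)
  # nearly every sample in its own bin: value ~ log2(n) + log2(bw)
  expect_equal(e$value, log2(100) + log2(1e-3), tolerance = 0.1)
  expect_gt(abs(e$value - gauss_h), 3)
})

test_that("joint entropy is additive for independence and degenerate for y = x", {
  g <- simulate_bivariate_gaussian(2e5, diag(2), seed = 3)
  j <- estimate_joint_entropy(g$x, g$y, 0.25)
  expect_equal(j$value, 2 * gauss_h, tolerance = 0.05 / (2 * gauss_h))

  x <- g$x[1:5000]
  hx <- estimate_entropy(x, 0.25)
  jd <- estimate_joint_entropy(x, x, 0.25)
  expect_equal(jd$value, hx$value + log2(0.25), tolerance = 1e-12)
  expect_equal(jd$n_occupied_bins, hx$n_occupied_bins)

  g2 <- simulate_bivariate_gaussian(2e5, cov_preset("correlated"), seed = 4)
  j2 <- estimate_joint_entropy(g2$x, g2$y, 0.25)
  expect_equal(j2$value, 2 * gauss_h + 0.5 * log2(0.75), tolerance = 0.05 / 3.887)
})

test_that("MI recovers the Gaussian closed form and independence", {
  g <- simulate_bivariate_gaussian(2e5, cov_preset("correlated"), seed = 5)
  m <- estimate_mi(g$x, g$y, 0.25)
  expect_lt(abs(m$mi - (-0.5 * log2(0.75))), 0.03)

  gi <- simulate_bivariate_gaussian(2e5, diag(2), seed = 6)
  expect_lt(abs(estimate_mi(gi$x, gi$y, 0.25)$mi), 0.02)

  # self-information: MI(x, x) equals the plug-in discrete entropy of x
  x <- g$x[1:2000]
  ms <- estimate_mi(x, x, 0.25)
  expect_equal(ms$mi, ms$h_x - log2(0.25), tolerance = 1e-12)
  expect_gt(ms$n_occupied_bins, 10)
})

test_that("the entropy identity, symmetry and nonnegativity hold on every run", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(100:2000, 1)
    rho <- runif(1, -0.9, 0.9)
    g <- simulate_bivariate_gaussian(n, matrix(c(1, rho, rho, 1), 2, 2))
    bw <- runif(1, 0.05, 1)
    m <- estimate_mi(g$x, g$y, bw)
    expect_equal(m$mi, m$h_x + m$h_y - m$h_joint, tolerance = 1e-9)
    expect_gte(m$mi, -1e-9)
    m_swap <- estimate_mi(g$y, g$x, bw)
    expect_identical(m$mi, m_swap$mi)
    # plug-in bound
    expect_lte(m$h_x, log2(n) + log2(bw) + 1e-9)
    expect_lte(m$h_joint, log2(n) + 2 * log2(bw) + 1e-9)
    # correction-cancellation: recompute MI from raw plug-in entropies
    raw <- (m$h_x - log2(bw)) + (m$h_y - log2(bw)) - (m$h_joint - 2 * log2(bw))
    expect_equal(m$mi, raw, tolerance = 1e-9)
  }
})

test_that("MI is invariant to shifts aligned with the bin grid", {
  g <- simulate_bivariate_gaussian(1e4, cov_preset("correlated"), seed = 8)
  bw <- 0.25
  m0 <- estimate_mi(g$x, g$y, bw)
  m_aligned <- estimate_mi(g$x + 7 * bw, g$y, bw)
  expect_identical(m0$mi, m_aligned$mi)
  m_arbitrary <- estimate_mi(g$x + pi, g$y, bw)
  expect_lt(abs(m0$mi - m_arbitrary$mi), 0.02)
})

test_that("plug-in estimates match a per-sample tally oracle exactly", {
  set.seed(9)
  x <- rnorm(500); y <- 0.5 * x + rnorm(500)
  for (bw in c(0.1, 0.4833)) {
    expect_equal(estimate_entropy(x, bw)$value, brute_entropy(x, bw),
                 tolerance = 1e-12)
    expect_equal(estimate_joint_entropy(x, y, bw)$value,
                 brute_joint_entropy(x, y, bw), tolerance = 1e-12)
  }
})

test_that("constant sequences are flagged degenerate, invalid input rejected", {
  e <- estimate_entropy(rep(3.2, 50), 0.1)
  expect_true(e$degenerate)
  expect_equal(e$value, log2(0.1))
  expect_error(estimate_entropy(1, 0.1), "at least 2")
  expect_error(estimate_entropy(rnorm(10), 0), "positive")
  expect_error(estimate_joint_entropy(rnorm(5), rnorm(4), 0.1), "equal length")
})

test_that("the N/bin-width sweep populates its grid with fresh sub-seeded draws", {
  sw <- sweep_n_and_binwidth(n_grid = c(100, 1000, 10000),
                             binwidth_grid = c(0.05, 0.1, 0.25, 0.5, 1),
                             seed = 10)
  expect_equal(nrow(sw), 15)
  expect_equal(dplyr::n_distinct(sw$seed), 3)
  expect_true(all(table(sw$n) == 5))
  sw2 <- sweep_n_and_binwidth(n_grid = c(100, 1000, 10000),
                              binwidth_grid = c(0.05, 0.1, 0.25, 0.5, 1),
                              seed = 10)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
  expect_error(sweep_n_and_binwidth(n_grid = numeric(0)), "non-empty")
  expect_error(sweep_n_and_binwidth(n_grid = c(100, 50)), "increasing")
})

test_that("the cardiac bin-width sweep reports per-width measures and stability", {
  pair <- simulate_vf_pair(vf_config(seed = 11))
  sw <- sweep_binwidth_cardiac(pair)
  expect_equal(nrow(sw), 4)
  expect_equal(sw$bin_width, c(0.2336, 0.3360, 0.4833, 0.6952))
  expect_true(is.logical(sw$plateau))
  expect_true(is.na(sw$mi_rel_change[1]))
  expect_true(all(sw$mi >= -1e-9))
})

test_that("MI increases with the generator's inter-channel coupling", {
  mi_at <- function(coup) {
    pair <- simulate_vf_pair(vf_config(coupling = coup, seed = 12))
    estimate_pair_info(pair, 0.4833)$mi
  }
  m <- sapply(c(0, 0.5, 1), mi_at)
  expect_true(all(diff(m) > 0))
  # fully coupled pair maximal at every grid width
  full <- sweep_binwidth_cardiac(simulate_vf_pair(vf_config(coupling = 1, seed = 12)))
  none <- sweep_binwidth_cardiac(simulate_vf_pair(vf_config(coupling = 0, seed = 12)))
  expect_true(all(full$mi > none$mi))
})

test_that("uncoupled pairs keep a small positive plug-in MI that shrinks with bin width", {
  pair <- simulate_vf_pair(vf_config(coupling = 0, seed = 13))
  sw <- sweep_binwidth_cardiac(pair)
  expect_true(all(sw$mi > 0))
  expect_lt(sw$mi[nrow(sw)], sw$mi[1])   # largest width less biased
  expect_true(all(sw$mi < 0.5))          # bias-scale, far below real coupling
})
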