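#' Named covariance presets for the bivariate Gaussian validation experiment
#'
#' Two 2x2 covariance matrices used throughout the estimator-validation
#' experiments: `"dependent"` is the degenerate rank-1 case in which both
#' coordinates are identical (totally dependent signals), `"correlated"` is
#' a unit-variance pair with correlation 0.5.
#'
#' @param name `"dependent"` or `"correlated"`.
#' @return A 2x2 symmetric covariance matrix.
#' @examples
#' cov_preset("correlated")
#' @export
cov_preset <- function(name = c("correlated", "dependent")) {
  name <- match.arg(name)
  switch(name,
    dependent  = matrix(c(1, 1, 1, 1), 2, 2),
    correlated = matrix(c(1, 0.5, 0.5, 1), 2, 2)
  )
}

check_covariance <- function(covariance, tol = 1e-10) {
  if (!is.matrix(covariance) || !identical(dim(covariance), c(2L, 2L)) ||
      !is.numeric(covariance)) {
    abort("`covariance` must be a numeric 2x2 matrix.")
  }
  if (abs(covariance[1, 2] - covariance[2, 1]) > tol) {
    abort("`covariance` must be symmetric.")
  }
  ev <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    abort(sprintf(
      "`covariance` is not positive semi-definite (min eigenvalue %.3e).",
      min(ev)
    ))
  }
  invisible(covariance)
}

#' Simulate a bivariate Gaussian sample set
#'
#' Draws `n` paired samples from a bivariate Gaussian with the given mean and
#' covariance. The sampler is eigendecomposition-based so that positive
#' *semi*-definite covariances are accepted: the rank-1 "dependent" preset
#' yields two elementwise-identical sequences, which is exactly the totally
#' dependent configuration used to validate the entropy and mutual-information
#' estimators.
#'
#' @param n Number of sample pairs (>= 2).
#' @param covariance 2x2 symmetric positive semi-definite matrix
#'   (signal-units squared). See [cov_preset()].
#' @param mean Length-2 mean vector.
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return A tibble with columns `x` and `y`, one row per sample pair.
#' @examples
#' g <- simulate_bivariate_gaussian(1000, cov_preset("correlated"), seed = 1)
#' cor(g$x, g$y)
#' @export
simulate_bivariate_gaussian <- function(n, covariance = cov_preset("correlated"),
                                        mean = c(0, 0), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    abort("`n` must be a single integer >= 2.")
  }
  n <- as.integer(n)
  check_covariance(covariance)
  if (length(mean) != 2 || !is.numeric(mean)) {
    abort("`mean` must be a numeric vector of length 2.")
  }
  draw <- function() {
    ed <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
    root <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), 2)
    z <- matrix(rnorm(2L * n), nrow = 2L)
    xy <- root %*% z
    tibble(x = xy[1, ] + mean[1], y = xy[2, ] + mean[2])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
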