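# Generalized Gaussian marginals and the Gaussianizing activation.
#
# ICA responses on natural-image input are sparse and symmetric, well
# approximated by a generalized Gaussian density
#   f(s; sigma, theta) = theta / (2 sigma Gamma(1/theta)) exp{-(|s|/sigma)^theta},
# Laplace at theta = 1, Gaussian at theta = 2 (with sigma = sqrt(2) sd).
# Discarding signs and mapping |s| through its own folded cdf and then the
# standard-normal quantile yields standard-normal marginals, the input
# contract of the next ICA layer.

#' Generalized Gaussian parameters
#'
#' @param sigma scale parameter (> 0, units of the response)
#' @param theta shape parameter (> 0, dimensionless); 1 = Laplace,
#'   2 = Gaussian
#' @return an object of class `ggd_params`
#' @export
ggd_params <- function(sigma, theta) {
  if (!is.finite(sigma) || sigma <= 0) .stopf("sigma must be > 0")
  if (!is.finite(theta) || theta <= 0) .stopf("theta must be > 0")
  structure(list(sigma = sigma, theta = theta), class = "ggd_params")
}

#' @export
print.ggd_params <- function(x, ...) {
  cat(sprintf("<ggd_params sigma = %.4g, theta = %.4g>\n", x$sigma, x$theta))
  invisible(x)
}

#' Generalized Gaussian density
#'
#' @param s evaluation point(s)
#' @param params a [ggd_params()]
#' @return density value(s); symmetric in `s`, integrates to 1
#' @examples
#' ggd_pdf(0, ggd_params(sqrt(2), 2))  # standard normal at 0: 1/sqrt(2*pi)
#' @export
ggd_pdf <- function(s, params) {
  stopifnot(inherits(params, "ggd_params"))
  th <- params$theta; sg <- params$sigma
  exp(log(th) - log(2 * sg) - lgamma(1 / th) - (abs(s) / sg)^th)
}

# Moment ratio m1^2/m2 = Gamma(2/t)^2 / (Gamma(1/t) Gamma(3/t)),
# strictly increasing in t.
.ggd_moment_ratio <- function(th) exp(2 * lgamma(2 / th) - lgamma(1 / th) - lgamma(3 / th))

#' Fit a generalized Gaussian by moment matching
#'
#' Solves `m1^2 / m2 = Gamma(2/theta)^2 / (Gamma(1/theta) Gamma(3/theta))`
#' for the shape `theta` (root-bracketing on \[0.1, 10\]), with
#' `m1 = E|s|`, `m2 = E s^2`, then sets
#' `sigma = m1 * Gamma(1/theta) / Gamma(2/theta)`.  Ratios outside the
#' attainable range clamp `theta` to the bounds with a warning.
#'
#' @param samples numeric vector (>= 100 values, not all zero)
#' @return a [ggd_params()]
#' @examples
#' set.seed(1)
#' fit_ggd(rnorm(1e4))  # theta near 2, sigma near sqrt(2)
#' @export
fit_ggd <- function(samples) {
  samples <- as.vector(samples)
  if (length(samples) < 100L) .stopf("need at least 100 samples")
  m1 <- mean(abs(samples))
  m2 <- mean(samples^2)
  if (m2 <= 0) .stopf("all samples are zero")
  r <- m1^2 / m2
  lo <- .ggd_moment_ratio(0.1); hi <- .ggd_moment_ratio(10)
  if (r <= lo || r >= hi) {
    th <- if (r <= lo) 0.1 else 10
    warning(sprintf("moment ratio %.4g outside attainable range; clamping theta to %g",
                    r, th), call. = FALSE)
  } else {
    th <- stats::uniroot(function(t) .ggd_moment_ratio(t) - r,
                         c(0.1, 10), tol = 1e-10)$root
  }
  sigma <- m1 * exp(lgamma(1 / th) - lgamma(2 / th))
  ggd_params(sigma, th)
}

#' Folded (absolute-value) generalized Gaussian cdf
#'
#' For `v = |s| >= 0` the cdf of the folded density is the regularized lower
#' incomplete gamma ratio `P(1/theta, (v/sigma)^theta)`; strictly increasing
#' with `u(0) = 0` and `u(Inf) = 1`.
#'
#' @param v non-negative value(s)
#' @param params a [ggd_params()]
#' @return probabilities in \[0, 1\]
#' @examples
#' ggd_folded_cdf(1, ggd_params(sqrt(2), 2))  # folded std normal: 2*pnorm(1)-1
#' @export
ggd_folded_cdf <- function(v, params) {
  stopifnot(inherits(params, "ggd_params"))
  if (any(v < 0)) .stopf("v must be >= 0")
  stats::pgamma((v / params$sigma)^params$theta, shape = 1 / params$theta)
}

#' Gaussianizing activation
#'
#' The sign-discarding coordinate-wise nonlinearity
#' `g(s) = Phi^{-1}(folded_cdf(|s|))`: samples from the fitted generalized
#' Gaussian map to a standard normal.  Tail probabilities are clipped to
#' `[eps_u, 1 - eps_u]` with `eps_u = max(1e-6, 1/(2 length(s)))` before the
#' normal quantile, so extreme responses stay finite.  Even in `s` and
#' strictly increasing in `|s|`.
#'
#' @param s responses (vector or matrix; shape preserved)
#' @param params a [ggd_params()] fitted on the same dimension
#' @return Gaussianized value(s)
#' @export
ggd_activation <- function(s, params) {
  u <- ggd_folded_cdf(abs(s), params)
  eps_u <- max(1e-6, 1 / (2 * length(s)))
  out <- stats::qnorm(pmin(pmax(u, eps_u), 1 - eps_u))
  if (is.matrix(s)) out <- matrix(out, nrow(s), ncol(s))
  out
}

#' Histogram-based Gaussianizing activation
#'
#' Nonparametric alternative to [ggd_activation()]: the cdf of `|s|` is
#' estimated from a histogram on `[b_min, b_max]` with bin width `b`,
#' linearly interpolated, clipped to `[1/(2n), 1 - 1/(2n)]` and mapped
#' through the standard-normal quantile.  Rank-preserving in `|s|`.  If all
#' mass falls into one bin the parametric path is used instead (with a
#' warning).
#'
#' @param s responses for one dimension (vector)
#' @param b_min,b_max histogram range; defaults 0 and the 99.9th percentile
#'   of `|s|`
#' @param b bin width; default spans the range with 1000 bins
#' @return Gaussianized vector, same length as `s`
#' @export
empirical_activation <- function(s, b_min = 0, b_max = NULL, b = NULL) {
  s <- as.vector(s)
  n <- length(s)
  v <- abs(s)
  if (is.null(b_max)) b_max <- as.numeric(stats::quantile(v, 0.999))
  if (b_max <= b_min) b_max <- b_min + max(max(v) - b_min, 1e-12)
  if (is.null(b)) b <- (b_max - b_min) / 1000
  if (b <= 0) .stopf("bin width b must be > 0")
  edges <- seq(b_min, b_max + b, by = b)
  cnt <- tabulate(pmin(pmax(floor((v - b_min) / b), 0), length(edges) - 2L) + 1L,
                  nbins = length(edges) - 1L)
  if (sum(cnt > 0) < 2L) {
    warning("all samples fall in a single histogram bin; falling back to the parametric activation",
            call. = FALSE)
    return(ggd_activation(s, fit_ggd(s)))
  }
  cdf_at_edges <- c(0, cumsum(cnt)) / n
  u <- stats::approx(edges, cdf_at_edges, xout = pmin(pmax(v, b_min), b_max + b),
                     rule = 2)$y
  u <- pmin(pmax(u, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(u)
}

#' Sample from a generalized Gaussian
#'
#' If `G ~ Gamma(1/theta, 1)` then `sign * sigma * G^{1/theta}` has the
#' generalized Gaussian law — the standard sampler used by the simulation
#' fixtures.
#'
#' @param n number of draws
#' @param params a [ggd_params()]
#' @param seed optional integer seed (local RNG; caller state is preserved)
#' @return numeric vector of length `n`
#' @export
rggd <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "ggd_params"))
  .with_seed(seed, {
    g <- stats::rgamma(n, shape = 1 / params$theta)
    sign <- sample(c(-1, 1), n, replace = TRUE)
    sign * params$sigma * g^(1 / params$theta)
  })
}
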