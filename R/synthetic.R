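# Seeded synthetic fixtures: every statistical structure the pipeline
# assumes (1/f spectra, sparse oriented components, known ICA mixtures,
# underwater degradation), plus the standard BSS recovery metric.

#' Generate 1/f ("pink") noise image
#'
#' Fourier synthesis: white Gaussian noise is filtered so its amplitude
#' spectrum is proportional to 1/f (power ~ 1/f^2), the canonical
#' natural-image spectrum; normalized to zero mean, unit variance.
#'
#' @param size side length (>= 64); output is `size x size`
#' @param seed integer seed (bit-reproducible output)
#' @return numeric matrix, mean 0 and population variance 1
#' @export
gen_pink_noise <- function(size, seed = 1L) {
  size <- as.integer(size)
  if (size < 64L) .stopf("size must be >= 64")
  .with_seed(seed, {
    wn <- matrix(stats::rnorm(size^2), size, size)
    fr <- .fftfreq(size)
    f <- sqrt(outer(fr^2, fr^2, `+`))
    amp <- ifelse(f > 0, 1 / f, 0)
    y <- Re(stats::fft(stats::fft(wn) * amp, inverse = TRUE)) / size^2
    y <- y - mean(y)
    y / sqrt(mean(y^2))
  })
}

# One Gabor atom on its own support, unit L2 norm.
.gabor_atom <- function(lambda, ori, phase, gamma = 0.5) {
  sigma <- 0.5 * lambda
  r <- max(2L, ceiling(2.5 * sigma))
  g <- expand.grid(x = -r:r, y = -r:r)
  xr <- g$x * cos(ori) + g$y * sin(ori)
  yr <- -g$x * sin(ori) + g$y * cos(ori)
  a <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2)) *
    cos(2 * pi * xr / lambda + phase)
  a <- a - mean(a)
  m <- matrix(a, 2 * r + 1, 2 * r + 1)
  m / sqrt(sum(m^2))
}

#' Generate a sparse-Gabor composite image
#'
#' Superimposes `sparsity_k` randomly placed elements drawn from a Gabor
#' dictionary (default 4 scales x 8 orientations x 2 phases = 64 atoms) with
#' Laplace-distributed amplitudes, plus a small Gaussian noise floor — the
#' sparse oriented structure under which ICA learns Gabor-like bases.  The
#' pixel distribution is leptokurtic (positive excess kurtosis) for
#' `sparsity_k` much smaller than the pixel count.
#'
#' @param size canvas side (pixels)
#' @param dict_size number of dictionary atoms (scales x orientations x 2
#'   phases; must be a multiple of 16)
#' @param sparsity_k number of placed elements (`<< size^2`)
#' @param seed integer seed
#' @param noise_sd standard deviation of the additive noise floor
#' @return a list: `image` (a [raw_image()], min–max rescaled to \[0, 1\]),
#'   `dictionary` (list of atom matrices), `canvas` (the un-rescaled field)
#' @export
gen_sparse_gabor <- function(size, dict_size = 64L, sparsity_k = 300L,
                             seed = 1L, noise_sd = 0.02) {
  size <- as.integer(size)
  if (dict_size %% 16L != 0L) .stopf("dict_size must be a multiple of 16")
  if (sparsity_k >= size^2 / 4) .stopf("sparsity_k must be << size^2")
  n_sc <- dict_size %/% 16L                       # scales x 8 orientations x 2 phases
  lambdas <- 3 * 2^seq(0, 2, length.out = n_sc)   # wavelengths ~3..12 px
  oris <- pi * (0:7) / 8
  phases <- c(0, pi / 2)
  dict <- list()
  for (la in lambdas) for (o in oris) for (ph in phases)
    dict[[length(dict) + 1L]] <- .gabor_atom(la, o, ph)
  .with_seed(seed, {
    canvas <- matrix(stats::rnorm(size^2, sd = noise_sd), size, size)
    if (sparsity_k > 0) {
      for (k in seq_len(sparsity_k)) {
        a <- dict[[sample.int(length(dict), 1L)]]
        r <- nrow(a)
        amp <- stats::rexp(1) * sample(c(-1, 1), 1)  # Laplace amplitude
        i0 <- sample.int(size - r + 1L, 1L)
        j0 <- sample.int(size - r + 1L, 1L)
        canvas[i0:(i0 + r - 1L), j0:(j0 + r - 1L)] <-
          canvas[i0:(i0 + r - 1L), j0:(j0 + r - 1L)] + amp * a
      }
    }
    rng <- range(canvas)
    img <- if (diff(rng) > 0) (canvas - rng[1]) / diff(rng) else canvas * 0 + 0.5
    list(image = raw_image(img), dictionary = dict, canvas = canvas)
  })
}

#' Generate a known-mixing ICA test set
#'
#' Sources are i.i.d. generalized Gaussian rows (`GGD(1, theta_src)`;
#' Laplace by default, the sparse prior), mixed by a seeded random
#' orthogonal matrix: `X = A_true S_true`.
#'
#' @param q number of sources (>= 2)
#' @param n number of samples (>= 100 q)
#' @param theta_src source shape parameter; `theta_src = 2` (Gaussian
#'   sources, non-identifiable) triggers a warning
#' @param seed integer seed
#' @return list with `X` (`q x n`), `A_true` (`q x q` orthogonal), `S_true`
#' @export
gen_ica_mixture <- function(q, n, theta_src = 1, seed = 1L) {
  q <- as.integer(q); n <- as.integer(n)
  if (q < 2L) .stopf("q must be >= 2")
  if (n < 100L * q) .stopf("n must be >= 100 q")
  if (abs(theta_src - 2) < 1e-8)
    warning("Gaussian sources (theta_src = 2) are not identifiable by ICA",
            call. = FALSE)
  .with_seed(seed, {
    M <- matrix(stats::rnorm(q * q), q, q)
    qr_ <- qr(M)
    A <- qr.Q(qr_)
    A <- A %*% diag(sign(diag(qr.R(qr_))), q)
    S <- matrix(rggd(q * n, ggd_params(1, theta_src)), q, n)
    list(X = A %*% S, A_true = A, S_true = S)
  })
}

#' Amari index of separation quality
#'
#' Permutation- and scale-invariant distance between an estimated demixing
#' `W` and the true mixing `A_true`, based on `P = W A_true`:
#' \deqn{\frac{1}{2q(q-1)}\left[\sum_i\left(\sum_j \frac{|P_{ij}|}{\max_k |P_{ik}|} - 1\right)
#'   + \sum_j\left(\sum_i \frac{|P_{ij}|}{\max_k |P_{kj}|} - 1\right)\right]}
#' 0 means perfect recovery (P a signed scaled permutation); 1 is the
#' worst case.
#'
#' @param W estimated `q x q` demixing matrix
#' @param A_true true `q x q` mixing matrix
#' @return scalar in \[0, 1\]
#' @export
amari_index <- function(W, A_true) {
  if (!all(dim(W) == dim(A_true)) || nrow(W) != ncol(W))
    .stopf("W and A_true must be square with equal dimensions")
  P <- abs(W %*% A_true)
  q <- nrow(P)
  rmax <- apply(P, 1, max)
  cmax <- apply(P, 2, max)
  if (any(rmax == 0) || any(cmax == 0)) .stopf("singular input")
  (sum(sweep(P, 1, rmax, "/")) - q + sum(sweep(P, 2, cmax, "/")) - q) /
    (2 * q * (q - 1))
}

#' Generate a paired clean/degraded underwater scene
#'
#' The clean scene is a sparse-Gabor texture modulated by a smooth seeded
#' illumination field (the multiplicative illumination-reflectance model);
#' the degraded partner is [simulate_underwater()] applied to it.
#'
#' @param size canvas side
#' @param params a [degradation_params()]
#' @param seed integer seed
#' @return list with `clean` and `degraded` [raw_image()]s
#' @export
gen_underwater_scene <- function(size, params = degradation_params(), seed = 1L) {
  sg <- gen_sparse_gabor(size, sparsity_k = max(50L, size^2 %/% 900L), seed = seed)
  refl <- 0.15 + 0.85 * sg$image$pixels
  illum <- .with_seed(seed + 1L, {
    cx <- stats::runif(1, 0.25, 0.75) * size
    cy <- stats::runif(1, 0.25, 0.75) * size
    gg <- expand.grid(x = seq_len(size), y = seq_len(size))
    bump <- exp(-((gg$x - cx)^2 + (gg$y - cy)^2) / (2 * (0.6 * size)^2))
    matrix(0.45 + 0.55 * bump, size, size)
  })
  clean <- raw_image(.clip01(illum * refl))
  list(clean = clean,
       degraded = simulate_underwater(clean, params, seed = seed + 2L))
}
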