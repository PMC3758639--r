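# Shared fixture builders (all generated in code; no stored data).

# Checkerboard reflectance modulated by a smooth illumination ramp:
# the canonical homomorphic-filtering test scene.
make_illum_checker <- function(size = 64, period = 8) {
  ij <- expand.grid(i = seq_len(size), j = seq_len(size))
  checker <- 0.35 + 0.5 * ((ij$i %/% period + ij$j %/% period) %% 2)
  illum <- 0.35 + 0.65 * ij$j / size
  matrix(pmin(checker * illum, 1), size, size)
}

# Centred 2 x n matrix whose sample covariance is EXACTLY diag(vars):
# orthonormalized centred noise, rescaled.  Independent of the whitening
# code under test.
make_exact_cov <- function(vars, n = 200, seed = 42) {
  set.seed(seed)
  M <- matrix(rnorm(n * length(vars)), n)
  M <- sweep(M, 2, colMeans(M))     # columns orthogonal to 1 after QR
  Q <- qr.Q(qr(M))
  t(Q) * sqrt(vars * (n - 1))
}

# Radial log-log power-spectrum slope over a frequency band.
spectrum_slope <- function(img, fmin, fmax) {
  n1 <- nrow(img); n2 <- ncol(img)
  P <- Mod(stats::fft(img))^2
  fr <- hica_fftfreq(n1); fc <- hica_fftfreq(n2)
  f <- sqrt(outer(fr^2, fc^2, `+`))
  sel <- f > fmin & f < fmax
  unname(stats::coef(stats::lm(log(P[sel]) ~ log(f[sel])))[2])
}

hica_fftfreq <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / n
}
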