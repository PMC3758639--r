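# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls never perturb user RNG.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

# DFT sample frequencies in cycles/sample (same layout as the usual fftfreq).
.fftfreq <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / n
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# Separable Gaussian blur with reflected edges; sigma in pixels.
.gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
  conv_cols <- function(m) {
    n <- nrow(m)
    mp <- m[pad_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[(i - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(mat))))
}

# Mean of `mat` over a (2r+1)x(2r+1) box around each pixel, edge-renormalized,
# via 2-D cumulative sums.
.box_mean <- function(mat, r) {
  n <- nrow(mat); m <- ncol(mat)
  cs <- apply(apply(mat, 2, cumsum), 1, cumsum)  # cs[j, i] = sum mat[1:i, 1:j]
  cs <- t(cs)
  csp <- matrix(0, n + 1, m + 1)
  csp[-1, -1] <- cs
  i1 <- pmax(seq_len(n) - r, 1L); i2 <- pmin(seq_len(n) + r, n)
  j1 <- pmax(seq_len(m) - r, 1L); j2 <- pmin(seq_len(m) + r, m)
  S <- csp[i2 + 1, j2 + 1, drop = FALSE] - csp[i1, j2 + 1, drop = FALSE] -
    csp[i2 + 1, j1, drop = FALSE] + csp[i1, j1, drop = FALSE]
  cnt <- outer(i2 - i1 + 1L, j2 - j1 + 1L)
  S / cnt
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
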