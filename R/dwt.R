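# Periodized orthogonal 2-D discrete wavelet transform.
#
# The enhancement filter operates per wavelet subband, so the package carries
# its own critically-sampled separable DWT with circular (periodic) boundary
# handling.  Only even side lengths are supported at each level; depth is
# validated by the caller.  The filter bank is the Daubechies least-asymmetric
# ("symlet") family of order 8 — a nearly symmetric orthogonal wavelet — whose
# analysis lowpass taps are standard published constants.

.sym8_lo <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
  0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
  0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
  -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
  0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
  0.0018899503327594609)

# Conjugate quadrature highpass: g[m] = (-1)^m h[L-1-m], m 0-based.
.sym8_hi <- {
  L <- length(.sym8_lo)
  rev(.sym8_lo) * (-1)^(seq_len(L) - 1)
}

.wavelet_filters <- function(name = "sym8") {
  if (!identical(name, "sym8"))
    .stopf("unknown wavelet '%s' (available: sym8)", name)
  list(lo = .sym8_lo, hi = .sym8_hi)
}

# One analysis step along the row dimension (all columns filtered jointly).
# X is N x M with N even; returns N/2 x M lowpass and highpass parts.
.dwt_step_cols <- function(X, lo, hi) {
  N <- nrow(X)
  if (N %% 2L != 0L) .stopf("signal length must be even (got %d)", N)
  K <- N %/% 2L
  A <- matrix(0, K, ncol(X))
  D <- matrix(0, K, ncol(X))
  base <- 2L * (seq_len(K) - 1L)
  for (m in seq_along(lo)) {
    idx <- ((base + (m - 1L)) %% N) + 1L
    Xs <- X[idx, , drop = FALSE]
    A <- A + lo[m] * Xs
    D <- D + hi[m] * Xs
  }
  list(lo = A, hi = D)
}

# Adjoint (= inverse, by orthogonality) of .dwt_step_cols.
.idwt_step_cols <- function(A, D, lo, hi) {
  K <- nrow(A)
  N <- 2L * K
  X <- matrix(0, N, ncol(A))
  base <- 2L * (seq_len(K) - 1L)
  for (m in seq_along(lo)) {
    idx <- ((base + (m - 1L)) %% N) + 1L
    X[idx, ] <- X[idx, ] + lo[m] * A + hi[m] * D
  }
  X
}

#' Multi-level 2-D wavelet decomposition
#'
#' Critically-sampled separable orthogonal DWT with periodic boundaries.
#' Each level halves both sides; sides must stay even throughout.
#'
#' @param x numeric matrix
#' @param levels decomposition depth (>= 1)
#' @param wavelet filter family name (currently `"sym8"`)
#' @return a list of class `dwt2` with `approx` (the level-`levels` lowpass
#'   band) and `detail`, a per-level list of subbands `hl` (highpass along
#'   width), `lh` (highpass along height) and `hh` (diagonal)
#' @seealso [idwt2()]
#' @export
dwt2 <- function(x, levels, wavelet = "sym8") {
  flt <- .wavelet_filters(wavelet)
  levels <- as.integer(levels)
  if (levels < 1L) .stopf("levels must be >= 1")
  cur <- x
  detail <- vector("list", levels)
  for (j in seq_len(levels)) {
    if (nrow(cur) %% 2L || ncol(cur) %% 2L)
      .stopf("image sides must be divisible by 2^levels for levels = %d", levels)
    rows <- .dwt_step_cols(cur, flt$lo, flt$hi)          # along height
    loww <- .dwt_step_cols(t(rows$lo), flt$lo, flt$hi)   # along width
    highw <- .dwt_step_cols(t(rows$hi), flt$lo, flt$hi)
    detail[[j]] <- list(hl = t(loww$hi), lh = t(highw$lo), hh = t(highw$hi))
    cur <- t(loww$lo)
  }
  structure(list(approx = cur, detail = detail, levels = levels,
                 wavelet = wavelet), class = "dwt2")
}

#' Inverse of [dwt2()]
#'
#' @param w a `dwt2` object
#' @return the reconstructed matrix (exact up to floating-point error)
#' @export
idwt2 <- function(w) {
  flt <- .wavelet_filters(w$wavelet)
  cur <- w$approx
  for (j in rev(seq_len(w$levels))) {
    d <- w$detail[[j]]
    lo <- t(.idwt_step_cols(t(cur), t(d$hl), flt$lo, flt$hi))
    hi <- t(.idwt_step_cols(t(d$lh), t(d$hh), flt$lo, flt$hi))
    cur <- .idwt_step_cols(lo, hi, flt$lo, flt$hi)
  }
  cur
}
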