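#' Centre a sample matrix
#'
#' Subtracts the per-row (per-dimension) mean from a `d x n` sample matrix:
#' `Xbar = X - M` with `M` the matrix whose columns all equal the mean
#' vector `m = (1/n) sum x_i`.
#'
#' @param X a `d x n` numeric matrix or a `patch_matrix`
#' @return a list with `Xbar` (centred matrix, row means 0) and `mean`
#'   (the d-vector of row means)
#' @export
center_columns <- function(X) {
  if (inherits(X, "patch_matrix")) X <- X$X
  if (!is.matrix(X)) .stopf("X must be a matrix or patch_matrix")
  if (ncol(X) < 2L) .stopf("need at least 2 samples to centre")
  m <- rowMeans(X)
  list(Xbar = X - m, mean = m)
}

#' Fit a PCA whitening model
#'
#' Eigendecomposes the sample covariance `C = Xbar Xbar^T / (n-1) =
#' U Lambda U^T`, sorts eigenpairs in descending order, retains the leading
#' `q` and forms the whitening matrix `V = Lambda^{-1/2} U^T` (`q x d`),
#' which maps centred data to uncorrelated unit-variance components.
#'
#' @param Xbar centred `d x n` matrix (see [center_columns()])
#' @param q retained dimension: a positive integer, or a fraction in (0, 1)
#'   interpreted as the smallest `q` whose eigenvalues capture that share of
#'   total variance
#' @param eps_reg relative eigenvalue floor (eigenvalues are floored at
#'   `eps_reg * lambda_max` so `Lambda^{-1/2}` stays finite)
#' @param mean optional mean vector stored alongside the model
#' @return an object of class `whitening_model`: fields `mean`, `eigvals`
#'   (length `q`, descending), `eigvecs` (`d x q`, orthonormal columns),
#'   `V` (`q x d`), `q`, `d`, `eps_reg`
#' @export
fit_whitening <- function(Xbar, q = 0.95, eps_reg = 1e-10, mean = NULL) {
  if (!is.matrix(Xbar)) .stopf("Xbar must be a matrix")
  d <- nrow(Xbar); n <- ncol(Xbar)
  if (n < 2L) .stopf("need at least 2 samples")
  C <- tcrossprod(Xbar) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  lam <- eig$values
  if (lam[1] <= 0) .stopf("degenerate data: covariance is identically zero")
  total_var <- sum(pmax(lam, 0))
  if (q < 1) {
    share <- cumsum(pmax(lam, 0)) / sum(pmax(lam, 0))
    q <- which(share >= q)[1]
  }
  q <- as.integer(q)
  if (q < 1L || q > d) .stopf("q must be in 1..d")
  lam <- pmax(lam[seq_len(q)], eps_reg * lam[1])
  U <- eig$vectors[, seq_len(q), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(q)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  V <- (1 / sqrt(lam)) * t(U)
  structure(list(mean = mean, eigvals = lam, eigvecs = U, V = V,
                 q = q, d = d, eps_reg = eps_reg, total_var = total_var),
            class = "whitening_model")
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf("<whitening_model d = %d -> q = %d, variance share %.1f%%>\n",
              x$d, x$q, 100 * sum(x$eigvals) / x$total_var))
  invisible(x)
}

#' Whiten centred data
#'
#' `Z = V Xbar` (`q x n`): components are uncorrelated with unit variance
#' when evaluated on the fitting data.
#'
#' @param Xbar centred `d x n` matrix
#' @param model a [fit_whitening()] model
#' @return the whitened `q x n` matrix
#' @export
whiten <- function(Xbar, model) {
  stopifnot(inherits(model, "whitening_model"))
  if (nrow(Xbar) != model$d)
    .stopf("Xbar has %d rows, model expects %d", nrow(Xbar), model$d)
  model$V %*% Xbar
}

#' Rise response dimensionality back to the data space
#'
#' Maps a `q x n` response matrix back to `d x n` with the transpose of the
#' same whitening matrix, `S_d = V^T S` — the "whiten again" step that makes
#' layer outputs dimensionally compatible with the next layer's input.
#'
#' @param S a `q x n` response matrix
#' @param model the layer's [fit_whitening()] model
#' @return the risen `d x n` matrix (rank <= q)
#' @export
rise_dimensionality <- function(S, model) {
  stopifnot(inherits(model, "whitening_model"))
  if (nrow(S) != model$q)
    .stopf("S has %d rows, model expects q = %d", nrow(S), model$q)
  crossprod(model$V, S)
}
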