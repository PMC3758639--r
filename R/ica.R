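# Fixed-point ICA with deflation.
#
# On whitened data the ICA demixing matrix B is orthogonal, so components are
# estimated one at a time: each column is driven to a fixed point of the
# negentropy-maximizing update and re-orthogonalized against the columns
# already found (Gram-Schmidt deflation).

#' One fixed-point ICA update
#'
#' `b_new = E[z f(b'z)] - E[f'(b'z)] b` with the contrast derivative
#' `f(x) = tanh(x)` (equivalently `(e^{2x}-1)/(e^{2x}+1)`) and
#' `f'(x) = 1 - tanh(x)^2`; expectations are sample means over the columns
#' of `Z`.  The result is not normalized.
#'
#' @param b unit-norm q-vector
#' @param Z whitened `q x n` data
#' @return the un-normalized updated q-vector
#' @export
fixed_point_update <- function(b, Z) {
  if (length(b) != nrow(Z)) .stopf("b has length %d, Z has %d rows",
                                   length(b), nrow(Z))
  y <- as.vector(crossprod(Z, b))
  fy <- tanh(y)
  as.vector(Z %*% fy) / ncol(Z) - mean(1 - fy^2) * b
}

#' Gram–Schmidt orthogonalization against found components
#'
#' Subtracts the projections `sum_j <b, b_j> b_j` onto the previously found
#' unit vectors and normalizes: `b <- (b - B_prev B_prev' b) / ||.||`.
#'
#' @param b q-vector
#' @param previous matrix with orthonormal columns (or a list of q-vectors,
#'   or `NULL` for none)
#' @return the orthonormalized unit q-vector
#' @export
gram_schmidt <- function(b, previous = NULL) {
  if (is.list(previous)) previous <- do.call(cbind, previous)
  if (!is.null(previous) && ncol(previous) > 0)
    b <- b - previous %*% crossprod(previous, b)
  nb <- sqrt(sum(b^2))
  if (nb < 1e-12)
    stop(structure(class = c("hica_restart", "error", "condition"),
                   list(message = "vector lies in the span of previous components",
                        call = NULL)))
  as.vector(b) / nb
}

#' Fixed-point ICA (deflation)
#'
#' Estimates the orthogonal demixing matrix `B` (`q x q`) from whitened data
#' by deflation: for each component, iterate [fixed_point_update()] followed
#' by [gram_schmidt()] until `|<b(t+1), b(t)>| > 1 - tol` or `iters`
#' iterations.  Initial vectors are seeded standard-normal draws, so the run
#' is deterministic given `seed`.  Components whose loop does not converge
#' keep the last iterate with a warning.
#'
#' @param Z whitened `q x n` matrix (validated: max deviation of `cov(t(Z))`
#'   from the identity must be <= 0.1)
#' @param iters maximum iterations per component
#' @param tol convergence tolerance on the update cosine
#' @param seed integer RNG seed for initialization
#' @return orthogonal `q x q` matrix `B` (columns are components;
#'   `t(B) %*% B = I`)
#' @examples
#' mix <- gen_ica_mixture(2, 2000, theta_src = 1, seed = 1)
#' ct <- center_columns(mix$X); wm <- fit_whitening(ct$Xbar, q = 2)
#' B <- fastica(whiten(ct$Xbar, wm), seed = 1)
#' @export
fastica <- function(Z, iters = 200L, tol = 1e-6, seed = NULL) {
  q <- nrow(Z); n <- ncol(Z)
  if (n <= q) .stopf("need n > q samples")
  dev <- max(abs(stats::cov(t(Z)) - diag(q)))
  if (dev > 0.1)
    .stopf("Z is not white (covariance deviates from I by %.3f > 0.1)", dev)
  .with_seed(seed, {
    B <- matrix(0, q, q)
    for (i in seq_len(q)) {
      prev <- if (i > 1) B[, seq_len(i - 1), drop = FALSE] else NULL
      converged <- FALSE
      restarts <- 0L
      b <- gram_schmidt(stats::rnorm(q), prev)
      for (t in seq_len(iters)) {
        bn <- fixed_point_update(b, Z)
        bn <- tryCatch(gram_schmidt(bn, prev), hica_restart = function(e) NULL)
        if (is.null(bn)) {
          if ((restarts <- restarts + 1L) > 10L)
            .stopf("component %d: repeated degenerate updates", i)
          b <- gram_schmidt(stats::rnorm(q), prev)
          next
        }
        done <- abs(sum(bn * b)) > 1 - tol
        b <- bn
        if (done) { converged <- TRUE; break }
      }
      if (!converged)
        warning(sprintf("component %d did not converge in %d iterations; keeping last iterate",
                        i, iters), call. = FALSE)
      B[, i] <- b
    }
    B
  })
}

#' Basis matrix from the whitening model and demixing matrix
#'
#' The generative basis is `A = V^{-1} B`, realized through the
#' pseudo-inverse of the whitening matrix: `A = U Lambda^{1/2} B` (`d x q`),
#' exact when `q = d`.
#'
#' @param model a [fit_whitening()] model
#' @param B orthogonal `q x q` demixing matrix
#' @return the `d x q` basis matrix `A` (satisfies `V A = B`)
#' @export
compute_basis <- function(model, B) {
  stopifnot(inherits(model, "whitening_model"))
  if (nrow(B) != model$q) .stopf("B has %d rows, model q = %d", nrow(B), model$q)
  model$eigvecs %*% (sqrt(model$eigvals) * B)
}

#' ICA responses
#'
#' Feature coefficients `S = B^T Z` (`q x n`).
#'
#' @param B orthogonal demixing matrix
#' @param Z whitened data
#' @return the `q x n` response matrix
#' @export
ica_responses <- function(B, Z) {
  if (nrow(B) != nrow(Z)) .stopf("dimension mismatch")
  crossprod(B, Z)
}

#' Reconstruct data from basis and responses
#'
#' `Xtilde = A S`; algebraically equal to the rank-q PCA reconstruction
#' `U U^T Xbar` of the centred data the layer was fitted on.
#'
#' @param A `d x q` basis matrix
#' @param S `q x n` response matrix
#' @return the `d x n` reconstruction
#' @export
ica_reconstruct <- function(A, S) {
  if (ncol(A) != nrow(S)) .stopf("dimension mismatch")
  A %*% S
}
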