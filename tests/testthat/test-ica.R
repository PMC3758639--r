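test_that("fixed-point update matches direct evaluation on listed samples", {
  Z <- cbind(c(1, 0), c(-1, 0), c(2, 0), c(-2, 0))
  b <- c(1, 0)
  # direct arithmetic: E[z tanh(b'z)] - E[1 - tanh(b'z)^2] b over the 4 columns
  y <- c(1, -1, 2, -2)
  expected <- c(mean(y * tanh(y)), 0) - mean(1 - tanh(y)^2) * b
  expect_equal(fixed_point_update(b, Z), expected, tolerance = 1e-14)
  # update is equivariant under column permutation
  expect_equal(fixed_point_update(b, Z[, c(3, 1, 4, 2)]),
               fixed_point_update(b, Z))
  # along a direction where Z is symmetric-zero the first term vanishes
  expect_equal(fixed_point_update(c(0, 1), Z)[1], 0, tolerance = 1e-14)
})

test_that("Gram-Schmidt orthogonalizes and normalizes", {
  expect_equal(gram_schmidt(c(3, 0)), c(1, 0))
  expect_equal(gram_schmidt(c(1, 1) / sqrt(2), matrix(c(1, 0), 2)), c(0, 1))
  set.seed(31)
  prev <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:3]
  out <- gram_schmidt(rnorm(6), prev)
  expect_lt(max(abs(crossprod(prev, out))), 1e-10)
  expect_equal(sum(out^2), 1, tolerance = 1e-12)
  expect_error(gram_schmidt(prev[, 1], prev), class = "hica_restart")
})

test_that("fastica returns an orthogonal matrix and validates whiteness", {
  set.seed(3)
  Z <- matrix(rnorm(4 * 3000), 4)
  Z[1, ] <- sign(Z[1, ]) * abs(Z[1, ])^1.5   # some non-Gaussianity
  Zw <- whiten(center_columns(Z)$Xbar, fit_whitening(center_columns(Z)$Xbar, q = 4))
  B <- suppressWarnings(fastica(Zw, seed = 1))
  expect_lt(max(abs(crossprod(B) - diag(4))), 1e-8)
  expect_error(fastica(2 * Zw, seed = 1), "not white")
})

test_that("fastica recovers a known orthogonal mixing (Amari index)", {
  med <- vapply(1:3, function(s) {
    mix <- gen_ica_mixture(4, 8000, theta_src = 1, seed = s)
    ct <- center_columns(mix$X)
    wm <- fit_whitening(ct$Xbar, q = 4)
    B <- fastica(whiten(ct$Xbar, wm), seed = s)
    amari_index(t(B) %*% wm$V, mix$A_true)
  }, 0)
  expect_lt(median(med), 0.05)
})

test_that("fastica on already-independent Laplace sources returns a signed permutation", {
  # unit-variance Laplace rows are white up to sampling error
  set.seed(8)
  q <- 3; n <- 60000   # large n keeps the sample covariance close to I
  Z <- matrix(rggd(q * n, ggd_params(1 / sqrt(2), 1)), q, n)
  B <- fastica(Z, seed = 2)
  offpeak <- apply(abs(B), 2, function(col) sort(col, decreasing = TRUE)[2])
  expect_lt(max(offpeak), 0.1)
})

test_that("basis, responses and reconstruction satisfy the PCA identities", {
  set.seed(19)
  X <- matrix(rnorm(16 * 2000), 16) * runif(16, 0.3, 2)
  ct <- center_columns(X)
  wm <- fit_whitening(ct$Xbar, q = 10)
  Z <- whiten(ct$Xbar, wm)
  B <- suppressWarnings(fastica(Z, iters = 30, seed = 5))
  A <- compute_basis(wm, B)
  S <- ica_responses(B, Z)
  # V A = B on the retained subspace
  expect_lt(max(abs(wm$V %*% A - B)), 1e-10)
  # B = I gives S = Z; orthogonal invariance keeps cov(S) = I
  expect_equal(ica_responses(diag(10), Z), Z)
  expect_lt(max(abs(stats::cov(t(S)) - diag(10))), 1e-6)
  expect_equal(unname(apply(S, 1, var)), rep(1, 10), tolerance = 5e-2)
  # reconstruction equals the rank-q PCA projection
  rec <- ica_reconstruct(A, S)
  proj <- wm$eigvecs %*% crossprod(wm$eigvecs, ct$Xbar)
  expect_lt(max(abs(rec - proj)), 1e-8)
  # residual energy is the discarded eigenvalue mass
  lam_all <- eigen(tcrossprod(ct$Xbar) / (ncol(X) - 1), symmetric = TRUE,
                   only.values = TRUE)$values
  expect_equal(sum((ct$Xbar - rec)^2), sum(lam_all[-(1:10)]) * (ncol(X) - 1),
               tolerance = 0.02)
  # full-rank case: exact reconstruction
  wmf <- fit_whitening(ct$Xbar, q = 16)
  Bf <- suppressWarnings(fastica(whiten(ct$Xbar, wmf), iters = 30, seed = 5))
  recf <- ica_reconstruct(compute_basis(wmf, Bf),
                          ica_responses(Bf, whiten(ct$Xbar, wmf)))
  expect_lt(max(abs(recf - ct$Xbar)), 1e-8)
})

test_that("relabelling sources leaves the Amari index at zero", {
  set.seed(23)
  mix <- gen_ica_mixture(5, 1000, theta_src = 1, seed = 9)
  W <- t(mix$A_true)                        # exact inverse (orthogonal)
  expect_equal(amari_index(W, mix$A_true), 0, tolerance = 1e-12)
  perm <- diag(5)[sample(5), ] * sample(c(-1, 1), 5, replace = TRUE)
  expect_equal(amari_index(perm %*% W, mix$A_true), 0, tolerance = 1e-12)
})
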