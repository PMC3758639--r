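make_corpus <- function(n = 4, size = 128, seed0 = 0) {
  lapply(seq_len(n), function(i) gen_sparse_gabor(size, seed = seed0 + i)$image)
}

test_that("train_layer preserves shape and Gaussianizes each risen dimension", {
  mix <- gen_ica_mixture(16, 4000, theta_src = 1, seed = 1)
  tl <- suppressWarnings(train_layer(mix$X, layer_config(q = 16, seed = 1)))
  expect_equal(dim(tl$X_next), dim(mix$X))
  expect_lt(max(abs(crossprod(tl$layer$B) - diag(16))), 1e-8)
  D <- apply(tl$X_next[c(1, 5, 9, 16), ], 1, function(r)
    unname(suppressWarnings(stats::ks.test(r, pnorm))$statistic))
  expect_true(all(D < 0.05))
  # bit-identical re-run under the same seed
  tl2 <- suppressWarnings(train_layer(mix$X, layer_config(q = 16, seed = 1)))
  expect_identical(tl$layer$B, tl2$layer$B)
  expect_identical(tl$X_next, tl2$X_next)
})

test_that("hica trains a multi-layer model with constant patch geometry", {
  fit <- suppressWarnings(hica(make_corpus(4), layers = 3, p = 8, m = 8,
                               q = 16, seed = 2))
  expect_s3_class(fit, "hica")
  expect_length(fit$layers, 3L)
  for (L in fit$layers) {
    expect_equal(dim(L$A), c(64L, 16L))          # d = p^2 = 64 each layer
    expect_equal(L$whitening$d, 64L)
    expect_length(L$ggd, 64L)
  }
  # (128 - 16)/8 = 14 tiles per side, 4 images
  expect_equal(fit$n, 4L * 14L * 14L)
  expect_output(print(fit), "3 layer")
  expect_output(print(summary(fit)), "GGD shape")
  expect_equal(coef(fit, 2), fit$layers[[2]]$A)
})

test_that("training is bit-reproducible and the model round-trips serialization", {
  corpus <- make_corpus(3)
  f1 <- suppressWarnings(hica(corpus, layers = 2, p = 8, m = 4, q = 12, seed = 5))
  f2 <- suppressWarnings(hica(corpus, layers = 2, p = 8, m = 4, q = 12, seed = 5))
  expect_identical(f1$layers, f2$layers)
  path <- tempfile(fileext = ".rds")
  hica_save(f1, path)
  expect_identical(hica_load(path)$layers, f1$layers)
  unlink(path)
})

test_that("prediction maps patches onto the tile grid with stored parameters", {
  corpus <- make_corpus(3, size = 128)
  fit <- suppressWarnings(hica(corpus, layers = 2, p = 8, m = 8, q = 12, seed = 3))
  maps <- predict(fit, corpus[[1]])
  expect_length(maps, 2L)
  expect_equal(maps[[1]]$grid_dim, c(14L, 14L))  # floor((128-16)/8)
  expect_equal(dim(maps[[1]]$grid), c(14L, 14L))
  expect_equal(nrow(maps[[1]]$responses), 12L)
  # training-corpus patches reproduce the training responses exactly
  n_tile <- 14L * 14L
  expect_equal(maps[[1]]$responses,
               fit$layers[[1]]$responses[, seq_len(n_tile)], tolerance = 1e-12)
  expect_error(predict(fit, matrix(0.5, 20, 20)), "larger than")
})

test_that("a constant image yields near-zero first-layer responses without pre-whitening", {
  fit <- suppressWarnings(hica(make_corpus(3), layers = 1, p = 8, m = 8,
                               q = 12, seed = 4, prewhiten = FALSE))
  maps <- predict(fit, matrix(0.5, 64, 64), prewhiten = FALSE)
  # centred constant patches differ from 0 only through the stored mean:
  # every tile's response equals B' V (0.5 - mean) exactly
  L <- fit$layers[[1]]
  s0 <- as.vector(crossprod(L$B, L$whitening$V %*% (0.5 - L$whitening$mean)))
  expect_equal(maps[[1]]$responses,
               matrix(s0, length(s0), ncol(maps[[1]]$responses)),
               tolerance = 1e-10)
  expect_equal(as.vector(maps[[1]]$grid),
               rep(sqrt(sum(s0^2)), length(maps[[1]]$grid)), tolerance = 1e-10)
})

test_that("basis mosaics tile columns with separators", {
  A <- diag(16)                       # one-hot basis, d = q = 16, p = 4
  mos <- render_basis_mosaic(A, 4)
  expect_equal(dim(as.matrix(mos)), c(4L * 5L + 1L, 4L * 5L + 1L))
  m1 <- render_basis_mosaic(A[, 1, drop = FALSE], 4)
  expect_equal(dim(as.matrix(m1)), c(6L, 6L))
  # each one-hot tile holds exactly one bright pixel
  tile1 <- as.matrix(mos)[2:5, 2:5]
  expect_equal(sum(tile1 == 1), 1L)
  expect_error(render_basis_mosaic(matrix(0, 15, 4), 4), "expected")
})

test_that("layer-1 bases learned from sparse Gabor corpora are bandpass-oriented", {
  imgs <- lapply(1:4, function(i)
    gen_sparse_gabor(192, sparsity_k = 120, seed = 10 + i)$image)
  fit <- suppressWarnings(hica(imgs, layers = 1, p = 8, m = 8, q = 24, seed = 6))
  expect_gte(basis_bandpass_fraction(coef(fit, 1), 8), 0.6)
})

test_that("sparseness survives transfer to an unseen corpus", {
  fit <- suppressWarnings(hica(make_corpus(3, seed0 = 20), layers = 1, p = 8,
                               m = 8, q = 12, seed = 8))
  other <- gen_sparse_gabor(128, seed = 99)$image
  maps <- predict(fit, other)
  kurt <- apply(maps[[1]]$responses, 1, function(x) mean(x^4) / mean(x^2)^2 - 3)
  expect_gt(median(kurt), 0)
})
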