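test_that("luminance conversion follows BT.601 weights", {
  px <- function(r, g, b) as.matrix(rgb_to_luminance(array(c(r, g, b), c(1, 1, 3))))[1, 1]
  expect_equal(px(1, 1, 1), 1)
  expect_equal(px(0, 0, 0), 0)
  expect_equal(px(1, 0, 0), 0.299)
  expect_equal(px(0, 1, 0), 0.587)
  expect_error(rgb_to_luminance(array(0, c(2, 2, 4))), "RGB")
})

test_that("filter gain hits its limits and midpoint", {
  cfg <- enhancement_config(r_h = 2, r_l = 0.5, k_c = 1, c_sharp = 1, order_n = 1)
  expect_equal(filter_gain(1, 1e8, 1e8, cfg), 2, tolerance = 1e-12)
  expect_equal(filter_gain(1, 0, 0, cfg), 0.5, tolerance = 1e-15)
  # radial frequency * 2^j equal to k_c * c: denominator is 2
  expect_equal(filter_gain(1, 0.5, 0, cfg), (2 + 0.5) / 2, tolerance = 1e-12)
  expect_error(filter_gain(1, -0.1, 0, cfg), "non-negative")
})

test_that("filter gain is bounded by [r_l, r_h] and monotone in radial frequency", {
  cfg <- enhancement_config(r_h = 1.8, r_l = 0.4, k_c = 2, c_sharp = 0.7, order_n = 2)
  r <- seq(0, 4, length.out = 200)
  g <- filter_gain(1, r, 0, cfg)
  expect_true(all(g >= 0.4 - 1e-12 & g <= 1.8 + 1e-12))
  expect_true(all(diff(g) >= -1e-12))
  # same radial frequency, any direction: same gain
  expect_equal(filter_gain(2, 0.3, 0.4, cfg), filter_gain(2, 0.5, 0, cfg))
})

test_that("bivariate shrinkage matches the closed-form rule", {
  # direct evaluation of the rule on (w1, w2) = (5, 5), sigma_n = 1, sigma_s = 2
  R <- sqrt(5^2 + 5^2)
  expect_equal(bivariate_shrink(5, 5, 1, 2), (R - sqrt(3) / 2) / R * 5,
               tolerance = 1e-12)
  expect_equal(bivariate_shrink(5, 5, 1, 2), 4.3876, tolerance = 1e-4)
  # hard-kill region: magnitude below the threshold
  expect_equal(bivariate_shrink(0.1, 0, 1, 1), 0)
  # no noise: coefficient unchanged
  expect_equal(bivariate_shrink(0.7, -0.2, 0, 1), 0.7)
  # degenerate: no signal
  expect_equal(bivariate_shrink(3, 1, 1, 0), 0)
})

test_that("bivariate shrinkage never increases magnitude and preserves sign", {
  set.seed(5)
  ch <- rnorm(500, sd = 2); pa <- rnorm(500, sd = 2)
  out <- bivariate_shrink(ch, pa, sigma_n = 0.8, sigma_s = 1.3)
  expect_true(all(abs(out) <= abs(ch) + 1e-12))
  expect_true(all(out * ch >= 0))
})

test_that("unit-gain enhancement without shrinkage is the identity", {
  set.seed(21)
  img <- matrix(runif(64 * 64), 64, 64)
  img[1] <- 0; img[2] <- 1  # span the full range so the rescale is neutral
  cfg <- enhancement_config(r_h = 1, r_l = 1, shrink = FALSE, levels_J = 3)
  out <- homomorphic_wavelet_enhance(img, cfg)
  expect_lt(max(abs(as.matrix(out) - img)), 1e-6)
})

test_that("enhancement maps a constant image to a constant image", {
  out <- homomorphic_wavelet_enhance(matrix(0.42, 64, 64), enhancement_config())
  expect_equal(as.matrix(out), matrix(0.42, 64, 64))
})

test_that("enhancement raises RMS contrast of an illumination-degraded scene", {
  img <- make_illum_checker(64)
  out <- homomorphic_wavelet_enhance(img, enhancement_config(r_h = 2, r_l = 0.5))
  expect_gt(rms_contrast(out), rms_contrast(img))
})

test_that("enhancement rejects too-deep decompositions", {
  expect_error(homomorphic_wavelet_enhance(matrix(0.5, 32, 32),
                                           enhancement_config(levels_J = 5)),
               "too deep")
})

test_that("underwater simulator follows the attenuation law", {
  img <- matrix(runif(32 * 32), 32, 32)
  p0 <- degradation_params(attenuation_c = 0.7, distance_d = 0, backscatter_b = 0,
                           forward_blur = 0, snow_density = 0)
  expect_equal(as.matrix(simulate_underwater(img, p0, seed = 1)), img)
  # uniform unit image, c*d = 1: direct component is exp(-1)
  p1 <- degradation_params(attenuation_c = 0.5, distance_d = 2, backscatter_b = 0,
                           forward_blur = 0, snow_density = 0)
  out1 <- as.matrix(simulate_underwater(matrix(1, 16, 16), p1, seed = 1))
  expect_equal(unique(round(as.vector(out1), 10)), round(exp(-1), 10))
  # pure backscatter on a black image
  p2 <- degradation_params(attenuation_c = 0, distance_d = 5, backscatter_b = 0.2,
                           forward_blur = 0, snow_density = 0)
  out2 <- as.matrix(simulate_underwater(matrix(0, 16, 16), p2, seed = 1))
  expect_equal(unique(as.vector(out2)), 0.2)
})

test_that("underwater simulator is seed-deterministic and intensity-monotone", {
  set.seed(9)
  a <- matrix(runif(32 * 32, 0, 0.6), 32, 32)
  b <- pmin(a + runif(32 * 32, 0, 0.3), 1)
  pp <- degradation_params(snow_density = 0.02)
  da <- simulate_underwater(a, pp, seed = 4)
  db <- simulate_underwater(b, pp, seed = 4)
  expect_identical(as.matrix(da),
                   as.matrix(simulate_underwater(a, pp, seed = 4)))
  expect_true(all(as.matrix(db) >= as.matrix(da) - 1e-12))
})
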