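#' Enhancement configuration
#'
#' Parameters of the homomorphic wavelet enhancement filter.  The transfer
#' function applied to the wavelet subband at level `j` with centre
#' frequencies `(omega_h, omega_l)` (cycles/pixel) is
#' \deqn{H(j,\omega_h,\omega_l) = (r_h - r_l)\,
#'   \frac{1}{1 + \left(k_c c / (\sqrt{\omega_h^2+\omega_l^2}\, 2^j)\right)^{2n}} + r_l,}
#' a Butterworth-style high-boost profile: low spatial frequencies
#' (illumination) are attenuated towards `r_l`, high frequencies
#' (reflectance, edges) amplified towards `r_h`.
#'
#' @param r_h high-frequency gain (typically > 1)
#' @param r_l low-frequency gain (typically in (0, 1\]); must satisfy
#'   `r_h >= r_l > 0`
#' @param k_c stopping coefficient (> 0), sets the cutoff radius
#' @param c_sharp sharpening constant (> 0) controlling the transition
#' @param order_n positive integer filter order (transition steepness)
#' @param levels_J wavelet decomposition depth (>= 1); must satisfy
#'   `levels_J <= log2(min(height, width)) - 2` for the image it is applied to
#' @param wavelet orthogonal wavelet family (currently `"sym8"`)
#' @param shrink logical; apply bivariate interscale shrinkage denoising to
#'   the detail coefficients
#' @param sigma_n noise standard deviation in the log domain, or `NULL` to
#'   estimate it as `MAD(finest diagonal subband) / 0.6745`
#' @return an object of class `enhancement_config`
#' @seealso [homomorphic_wavelet_enhance()], [filter_gain()]
#' @export
enhancement_config <- function(r_h = 2.0, r_l = 0.5, k_c = 1.0, c_sharp = 1.0,
                               order_n = 1L, levels_J = 3L, wavelet = "sym8",
                               shrink = TRUE, sigma_n = NULL) {
  if (!(r_h >= r_l && r_l > 0)) .stopf("need r_h >= r_l > 0")
  if (k_c <= 0 || c_sharp <= 0) .stopf("k_c and c_sharp must be > 0")
  order_n <- as.integer(order_n)
  if (order_n < 1L) .stopf("order_n must be a positive integer")
  levels_J <- as.integer(levels_J)
  if (levels_J < 1L) .stopf("levels_J must be >= 1")
  if (!is.null(sigma_n) && sigma_n < 0) .stopf("sigma_n must be >= 0")
  .wavelet_filters(wavelet)
  structure(list(r_h = r_h, r_l = r_l, k_c = k_c, c_sharp = c_sharp,
                 order_n = order_n, levels_J = levels_J, wavelet = wavelet,
                 shrink = isTRUE(shrink), sigma_n = sigma_n),
            class = "enhancement_config")
}

#' Subband gain of the homomorphic enhancement filter
#'
#' Evaluates the high-boost transfer function (see [enhancement_config()])
#' at wavelet level `level_j` and subband centre frequencies
#' `(omega_h, omega_l)`.  The gain is bounded by `[r_l, r_h]` and is monotone
#' non-decreasing in the radial frequency `sqrt(omega_h^2+omega_l^2) * 2^j`;
#' at zero radial frequency it equals `r_l` (pure illumination band), and it
#' approaches `r_h` as the radial frequency grows.
#'
#' @param level_j wavelet level (integer >= 1); vectorized
#' @param omega_h,omega_l horizontal / vertical frequency weights (>= 0,
#'   cycles/pixel); vectorized
#' @param cfg an [enhancement_config()]
#' @return gain value(s) in `[r_l, r_h]`
#' @examples
#' cfg <- enhancement_config(r_h = 2, r_l = 0.5)
#' filter_gain(1, 0, 0, cfg)          # r_l at zero frequency
#' filter_gain(1, 10, 10, cfg)        # -> r_h in the high-frequency limit
#' @export
filter_gain <- function(level_j, omega_h, omega_l, cfg) {
  stopifnot(inherits(cfg, "enhancement_config"))
  if (any(omega_h < 0) || any(omega_l < 0))
    .stopf("frequency weights must be non-negative")
  if (any(level_j < 1)) .stopf("level_j must be >= 1")
  r <- sqrt(omega_h^2 + omega_l^2) * 2^level_j
  out <- rep(cfg$r_l, length.out = max(length(r), 1L))
  pos <- r > 0
  out[pos] <- (cfg$r_h - cfg$r_l) /
    (1 + (cfg$k_c * cfg$c_sharp / r[pos])^(2 * cfg$order_n)) + cfg$r_l
  out
}

#' Bivariate interscale wavelet shrinkage
#'
#' The bivariate shrinkage rule couples a wavelet coefficient `w1` with its
#' parent `w2` at the next coarser scale:
#' \deqn{\hat w_1 = \frac{\left(\sqrt{w_1^2+w_2^2} -
#'   \sqrt{3}\,\sigma_n^2/\sigma_s\right)_+}{\sqrt{w_1^2+w_2^2}}\, w_1.}
#' Magnitude never increases and the sign is preserved (or the output is 0).
#'
#' @param child coefficient(s) at the current scale
#' @param parent corresponding coefficient(s) at the next coarser scale
#'   (recycled to the length of `child`)
#' @param sigma_n noise standard deviation (>= 0)
#' @param sigma_s local signal standard deviation (> 0; 0 returns 0, the
#'   degenerate no-signal limit); may be per-coefficient
#' @return shrunken coefficient(s), same shape as `child`
#' @examples
#' bivariate_shrink(5, 5, sigma_n = 1, sigma_s = 2)  # ~ 4.3876
#' @export
bivariate_shrink <- function(child, parent, sigma_n, sigma_s) {
  if (any(sigma_n < 0)) .stopf("sigma_n must be >= 0")
  if (any(sigma_s < 0)) .stopf("sigma_s must be >= 0")
  R <- sqrt(child^2 + parent^2)
  thr <- sqrt(3) * sigma_n^2 / ifelse(sigma_s > 0, sigma_s, Inf)
  fac <- ifelse(R > 0, pmax(R - thr, 0) / R, 0)
  fac <- ifelse(sigma_s > 0, fac, 0)
  out <- fac * child
  if (is.matrix(child)) out <- matrix(out, nrow(child), ncol(child))
  out
}

# Nearest-neighbour 2x upsampling of a parent band to the child grid.
.expand2 <- function(mat, nr, nc) {
  ri <- pmin(ceiling(seq_len(nr) / 2), nrow(mat))
  ci <- pmin(ceiling(seq_len(nc) / 2), ncol(mat))
  mat[ri, ci, drop = FALSE]
}

#' Homomorphic wavelet image enhancement
#'
#' Log-domain homomorphic filtering merged with an orthogonal wavelet
#' decomposition.  The image is modelled as illumination times reflectance,
#' `I = i * r`; taking logs makes the product additive, after which each
#' detail subband at level `j` is scaled by the high-boost gain
#' [filter_gain()] evaluated at the subband centre frequencies
#' `(0, 2^(-j-1))`, `(2^(-j-1), 0)` or `(2^(-j-1), 2^(-j-1))` cycles/pixel,
#' and the level-`J` approximation band by `r_l`.  Optional bivariate
#' interscale shrinkage denoises the detail coefficients.  The result is
#' exponentiated back and min–max rescaled to \[0, 1\].
#'
#' A small offset `1e-3` is added before the log to keep it finite; the final
#' rescale removes it.
#'
#' @param image a [raw_image()] or numeric matrix in \[0, 1\]
#' @param cfg an [enhancement_config()]
#' @return the enhanced [raw_image()], same dimensions
#' @examples
#' img <- matrix(rep(c(0.2, 0.8), length.out = 64 * 64), 64, 64)
#' out <- homomorphic_wavelet_enhance(img, enhancement_config(levels_J = 2))
#' @export
homomorphic_wavelet_enhance <- function(image, cfg = enhancement_config()) {
  stopifnot(inherits(cfg, "enhancement_config"))
  x <- .px(image)
  J <- cfg$levels_J
  if (J > floor(log2(min(dim(x))) - 2))
    .stopf("levels_J = %d too deep for a %d x %d image (max %d)",
           J, nrow(x), ncol(x), floor(log2(min(dim(x))) - 2))
  z <- log(x + 1e-3)
  w <- dwt2(z, J, cfg$wavelet)

  # noise level from the finest diagonal band, before any gain is applied
  sn <- cfg$sigma_n
  if (is.null(sn)) {
    d1 <- w$detail[[1]]$hh
    sn <- stats::median(abs(d1 - stats::median(d1))) / 0.6745
  }

  f <- function(j) 2^(-j - 1)
  gains <- lapply(seq_len(J), function(j) list(
    hl = filter_gain(j, f(j), 0, cfg),
    lh = filter_gain(j, 0, f(j), cfg),
    hh = filter_gain(j, f(j), f(j), cfg)))
  for (j in seq_len(J))
    for (b in c("hl", "lh", "hh"))
      w$detail[[j]][[b]] <- w$detail[[j]][[b]] * gains[[j]][[b]]
  w$approx <- w$approx * cfg$r_l

  if (cfg$shrink && sn > 0) {
    for (j in seq_len(J)) {
      for (b in c("hl", "lh", "hh")) {
        ch <- w$detail[[j]][[b]]
        pa <- if (j < J) .expand2(w$detail[[j + 1]][[b]], nrow(ch), ncol(ch))
              else matrix(0, nrow(ch), ncol(ch))
        sn_b <- sn * gains[[j]][[b]]  # gain rescales the noise floor too
        ss2 <- pmax(.box_mean(ch^2, 3L) - sn_b^2, 1e-12)
        w$detail[[j]][[b]] <- bivariate_shrink(ch, pa, sn_b, sqrt(ss2))
      }
    }
  }

  s <- idwt2(w)
  out <- exp(s)
  rng <- range(out)
  # a (near-)constant image stays itself: a monotone map of a constant,
  # and min-max rescaling would only amplify float noise
  if (diff(rng) <= 1e-8 * max(abs(rng))) return(raw_image(x))
  raw_image((out - rng[1]) / diff(rng))
}

#' Underwater degradation parameters
#'
#' Forward model of underwater image formation: the total irradiance is the
#' sum of a direct component, a forward-scattered component and backscatter.
#' The direct component decays exponentially with path length
#' (`L(d) = L0 * exp(-c d)`); forward scatter is a blurred copy of the
#' attenuated direct signal; backscatter is an additive veil; marine snow is
#' sparse bright speckle.
#'
#' @param attenuation_c attenuation coefficient (>= 0, 1/distance)
#' @param distance_d path length (>= 0, distance units)
#' @param backscatter_b additive backscatter level in \[0, 1)
#' @param forward_blur Gaussian blur width (pixels, >= 0) of the
#'   forward-scatter term; 0 disables forward scatter entirely
#' @param forward_weight weight of the forward-scatter term relative to the
#'   attenuated direct component
#' @param snow_density fraction in \[0, 1) of pixels replaced by bright
#'   marine-snow speckle
#' @return an object of class `degradation_params`
#' @seealso [simulate_underwater()]
#' @export
degradation_params <- function(attenuation_c = 0.5, distance_d = 2,
                               backscatter_b = 0.3, forward_blur = 1.5,
                               forward_weight = 0.2, snow_density = 0.01) {
  if (attenuation_c < 0 || distance_d < 0) .stopf("c and d must be >= 0")
  if (backscatter_b < 0 || backscatter_b >= 1) .stopf("backscatter_b in [0, 1)")
  if (forward_blur < 0) .stopf("forward_blur must be >= 0")
  if (forward_weight < 0) .stopf("forward_weight must be >= 0")
  if (snow_density < 0 || snow_density >= 1) .stopf("snow_density in [0, 1)")
  structure(list(attenuation_c = attenuation_c, distance_d = distance_d,
                 backscatter_b = backscatter_b, forward_blur = forward_blur,
                 forward_weight = forward_weight, snow_density = snow_density),
            class = "degradation_params")
}

#' Simulate underwater image degradation
#'
#' Applies the additive three-component underwater formation model (direct +
#' forward scatter + backscatter) to a clean image:
#' `out = clip(I * exp(-c d) + w_f * blur(I * exp(-c d)) + b, 0, 1)`,
#' with optional seeded marine-snow speckle.  The forward-scatter term is
#' present only when `forward_blur > 0`.  Deterministic given `seed`.
#'
#' @param image a [raw_image()] or numeric matrix in \[0, 1\]
#' @param params a [degradation_params()]
#' @param seed integer RNG seed for the marine-snow speckle
#' @return the degraded [raw_image()]
#' @examples
#' img <- matrix(runif(64^2), 64, 64)
#' deg <- simulate_underwater(img, degradation_params(snow_density = 0), seed = 1)
#' @export
simulate_underwater <- function(image, params = degradation_params(), seed = 1L) {
  stopifnot(inherits(params, "degradation_params"))
  x <- .px(image)
  direct <- x * exp(-params$attenuation_c * params$distance_d)
  out <- direct + params$backscatter_b
  if (params$forward_blur > 0)
    out <- out + params$forward_weight * .gauss_blur(direct, params$forward_blur)
  if (params$snow_density > 0) {
    out <- .with_seed(seed, {
      npix <- length(out)
      k <- round(params$snow_density * npix)
      if (k > 0) {
        idx <- sample.int(npix, k)
        out[idx] <- stats::runif(k, 0.85, 1)
      }
      out
    })
  }
  raw_image(.clip01(out))
}
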