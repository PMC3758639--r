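# Orchestration: the recursive multi-layer ICA architecture.
#
# Layer pipeline (one layer): centre -> PCA whitening -> fixed-point ICA ->
# responses -> rise dimensionality -> per-dimension generalized-Gaussian fit
# -> sign-discarding Gaussianizing activation, whose output feeds the next
# layer.  Bases learned on one corpus transfer to new images as pure linear
# maps (stored means, whitening and demixing; no refitting).

#' Layer configuration
#'
#' @param q retained dimension (integer) or variance fraction in (0, 1)
#' @param iters maximum fixed-point iterations per component
#' @param tol convergence tolerance
#' @param seed integer RNG seed for the layer's ICA initialization
#' @param activation `"parametric"` (generalized-Gaussian cdf) or
#'   `"empirical"` (histogram cdf)
#' @return an object of class `layer_config`
#' @export
layer_config <- function(q = 0.95, iters = 200L, tol = 1e-6, seed = 1L,
                         activation = c("parametric", "empirical")) {
  activation <- match.arg(activation)
  structure(list(q = q, iters = as.integer(iters), tol = tol,
                 seed = as.integer(seed), activation = activation),
            class = "layer_config")
}

#' Train one ICA layer
#'
#' Runs the full single-layer pipeline on a `d x n` input matrix and returns
#' the fitted layer together with the Gaussianized `d x n` input for the
#' next layer.  Deterministic given `cfg$seed`.
#'
#' @param X `d x n` input matrix (or `patch_matrix`)
#' @param cfg a [layer_config()]
#' @return a list with `layer` (fields `whitening`, `B`, `A`, `ggd` — one
#'   [ggd_params()] per risen dimension — `responses`, `config`) and
#'   `X_next` (`d x n` Gaussianized output)
#' @export
train_layer <- function(X, cfg = layer_config()) {
  stopifnot(inherits(cfg, "layer_config"))
  if (inherits(X, "patch_matrix")) X <- X$X
  ct <- center_columns(X)
  wm <- fit_whitening(ct$Xbar, q = cfg$q, mean = ct$mean)
  Z <- whiten(ct$Xbar, wm)
  B <- fastica(Z, iters = cfg$iters, tol = cfg$tol, seed = cfg$seed)
  A <- compute_basis(wm, B)
  S <- ica_responses(B, Z)
  Sr <- rise_dimensionality(S, wm)
  d <- nrow(Sr)
  ggd <- vector("list", d)
  Xn <- matrix(0, d, ncol(Sr))
  for (i in seq_len(d)) {
    ggd[[i]] <- fit_ggd(Sr[i, ])
    Xn[i, ] <- if (cfg$activation == "empirical")
      empirical_activation(Sr[i, ]) else ggd_activation(Sr[i, ], ggd[[i]])
  }
  layer <- structure(list(whitening = wm, B = B, A = A, ggd = ggd,
                          responses = S, config = cfg),
                     class = "ica_layer")
  list(layer = layer, X_next = Xn)
}

#' Fit a hierarchical ICA model to an image corpus
#'
#' The first layer is trained on `p x p` patches tiled from the
#' boundary-cropped, 1/f pre-whitened corpus images; each subsequent layer
#' is trained on the Gaussianized, sign-discarded responses of the previous
#' one.  The result is a reusable feature hierarchy: layer-1 bases are
#' Gabor-like oriented bandpass elements, higher layers respond to texture
#' structure.
#'
#' @param images list of [raw_image()] objects or numeric matrices
#' @param layers number of ICA layers (>= 1)
#' @param p patch side (pixels)
#' @param m boundary crop per side (pixels)
#' @param q retained dimension per layer: integer, variance fraction in
#'   (0, 1), or a vector with one entry per layer
#' @param iters,tol fixed-point iteration budget and tolerance
#' @param seed integer seed; layer `l` uses `seed + l - 1`
#' @param prewhiten logical; apply [prewhiten_image()] to each image first
#' @param f0_fraction pre-whitening cutoff (fraction of Nyquist)
#' @param activation `"parametric"` or `"empirical"` Gaussianization
#' @return an object of class `hica`: fields `layers` (list of trained
#'   layers), `p`, `m`, `prewhiten`, `f0_fraction`, `seed`, `n`, `call`
#' @examples
#' imgs <- lapply(1:2, function(i) gen_sparse_gabor(128, seed = i)$image)
#' fit <- hica(imgs, layers = 1, p = 8, m = 4, q = 16, seed = 1)
#' fit
#' @export
hica <- function(images, layers = 3L, p = 16L, m = 16L, q = 0.95,
                 iters = 200L, tol = 1e-6, seed = 1L, prewhiten = TRUE,
                 f0_fraction = 0.8, activation = "parametric") {
  layers <- as.integer(layers)
  if (layers < 1L) .stopf("layers must be >= 1")
  qs <- rep(q, length.out = layers)
  if (!is.list(images) || inherits(images, "raw_image")) images <- list(images)
  pre <- lapply(images, function(im) {
    im <- crop_boundary(im, 0L)  # validates the container
    if (prewhiten) prewhiten_image(im, f0_fraction) else .px(im)
  })
  pm <- extract_patches(pre, p = p, m = m)
  if (pm$n <= pm$d)
    warning(sprintf("only n = %d patches for d = %d dimensions; corpus may be too small",
                    pm$n, pm$d), call. = FALSE)
  X <- pm$X
  fitted <- vector("list", layers)
  for (l in seq_len(layers)) {
    cfg <- layer_config(q = qs[l], iters = iters, tol = tol,
                        seed = as.integer(seed) + l - 1L,
                        activation = activation)
    tl <- train_layer(X, cfg)
    fitted[[l]] <- tl$layer
    X <- tl$X_next
  }
  structure(list(layers = fitted, p = as.integer(p), m = as.integer(m),
                 prewhiten = isTRUE(prewhiten), f0_fraction = f0_fraction,
                 seed = as.integer(seed), n = pm$n, d = pm$d,
                 call = match.call()),
            class = "hica")
}

#' @export
print.hica <- function(x, ...) {
  cat(sprintf("Hierarchical ICA model: %d layer(s), p = %d, m = %d, n = %d patches (d = %d)\n",
              length(x$layers), x$p, x$m, x$n, x$d))
  for (l in seq_along(x$layers)) {
    wm <- x$layers[[l]]$whitening
    cat(sprintf("  layer %d: q = %d (%.1f%% variance retained)\n",
                l, wm$q, 100 * sum(wm$eigvals) / wm$total_var))
  }
  invisible(x)
}

#' @export
summary.hica <- function(object, ...) {
  th <- lapply(object$layers, function(L) vapply(L$ggd, `[[`, 0, "theta"))
  out <- list(layers = length(object$layers), p = object$p, m = object$m,
              n = object$n, d = object$d,
              q = vapply(object$layers, function(L) L$whitening$q, 0L),
              theta_median = vapply(th, stats::median, 0))
  class(out) <- "summary.hica"
  out
}

#' @export
print.summary.hica <- function(x, ...) {
  cat(sprintf("Hierarchical ICA model (%d layers)\n", x$layers))
  cat(sprintf("  patches: p = %d, m = %d, n = %d, d = %d\n", x$p, x$m, x$n, x$d))
  cat(sprintf("  retained q per layer: %s\n", paste(x$q, collapse = ", ")))
  cat(sprintf("  median GGD shape per layer: %s\n",
              paste(sprintf("%.2f", x$theta_median), collapse = ", ")))
  invisible(x)
}

#' @export
coef.hica <- function(object, layer = 1L, ...) object$layers[[layer]]$A

#' Apply a fitted hierarchy to a new image
#'
#' Pure feed-forward transfer: patches are extracted with the model's
#' geometry, centred with the stored training means, projected with the
#' stored whitening and demixing matrices, and per-layer response maps are
#' returned.  No refitting occurs, so the learned bases act as common
#' features shared across corpora.
#'
#' @param object a fitted [hica()] model
#' @param image a [raw_image()] or numeric matrix (sides > `p + 2m`)
#' @param prewhiten logical; default mirrors the training preprocessing
#' @param ... unused
#' @return a list of per-layer `activation_map` objects: fields `grid`
#'   (per-tile L2 response norm, `floor((H-2m)/p) x floor((W-2m)/p)`),
#'   `responses` (`q x n_tiles`), `layer`
#' @export
predict.hica <- function(object, image, prewhiten = object$prewhiten, ...) {
  if (min(dim(.px(image))) <= object$p + 2L * object$m)
    .stopf("image must be larger than p + 2m = %d", object$p + 2L * object$m)
  x <- if (prewhiten) prewhiten_image(image, object$f0_fraction) else .px(image)
  pm <- extract_patches(list(x), p = object$p, m = object$m)
  gh <- length(seq(0L, pm$cropped_dims[1, 1] - object$p, by = object$p))
  gw <- length(seq(0L, pm$cropped_dims[1, 2] - object$p, by = object$p))
  X <- pm$X
  maps <- vector("list", length(object$layers))
  for (l in seq_along(object$layers)) {
    L <- object$layers[[l]]
    Xbar <- X - L$whitening$mean
    Z <- whiten(Xbar, L$whitening)
    S <- ica_responses(L$B, Z)
    grid <- matrix(sqrt(colSums(S^2)), gh, gw)
    maps[[l]] <- structure(list(grid = grid, responses = S, layer = l,
                                grid_dim = c(gh, gw)),
                           class = "activation_map")
    Sr <- rise_dimensionality(S, L$whitening)
    Xn <- matrix(0, nrow(Sr), ncol(Sr))
    for (i in seq_len(nrow(Sr)))
      Xn[i, ] <- ggd_activation(Sr[i, ], L$ggd[[i]])
    X <- Xn
  }
  maps
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map layer %d, grid %d x %d, q = %d>\n",
              x$layer, x$grid_dim[1], x$grid_dim[2], nrow(x$responses)))
  invisible(x)
}

#' @export
plot.activation_map <- function(x, component = NULL, ...) {
  g <- if (is.null(component)) x$grid
       else matrix(x$responses[component, ], x$grid_dim[1], x$grid_dim[2])
  cols <- grDevices::hcl.colors(256, "RdYlBu", rev = TRUE)  # red max, blue min
  graphics::image(t(g)[, nrow(g):1, drop = FALSE], col = cols, axes = FALSE, ...)
  invisible(x)
}

#' Render a basis matrix as a tiled mosaic
#'
#' Reshapes each column of `A` (`d = p^2`) to a `p x p` tile, min–max
#' normalizes each tile independently and lays the tiles on a
#' `ceiling(sqrt(q))`-wide grid with 1-pixel separators — the standard
#' visual check that layer-1 bases are Gabor-like.
#'
#' @param A `d x q` basis matrix with `d` a perfect square
#' @param p patch side (`p^2 = d`)
#' @return a [raw_image()] of side `ceiling(sqrt(q)) * (p + 1) + 1`
#' @export
render_basis_mosaic <- function(A, p) {
  p <- as.integer(p)
  if (nrow(A) != p * p) .stopf("A has %d rows; expected p^2 = %d", nrow(A), p * p)
  qn <- ncol(A)
  g <- ceiling(sqrt(qn))
  side_r <- ceiling(qn / g)
  out <- matrix(0, side_r * (p + 1) + 1, g * (p + 1) + 1)
  for (k in seq_len(qn)) {
    tile <- matrix(A[, k], p, p)
    rng <- range(tile)
    tile <- if (diff(rng) > 0) (tile - rng[1]) / diff(rng) else tile * 0 + 0.5
    r0 <- ((k - 1) %/% g) * (p + 1) + 1
    c0 <- ((k - 1) %% g) * (p + 1) + 1
    out[r0 + seq_len(p), c0 + seq_len(p)] <- tile
  }
  raw_image(out)
}

#' @export
plot.hica <- function(x, layer = 1L, ...) {
  plot(render_basis_mosaic(coef(x, layer), x$p), ...)
}

#' Fraction of bandpass-oriented basis columns
#'
#' Spectral concentration test for Gabor-likeness: a column passes when more
#' than `power_frac` of its (DC-removed) 2-D spectral power lies inside a
#' wedge of `+/- wedge_deg` degrees around its peak orientation and within
#' one octave of its peak radial frequency.
#'
#' @param A `d x q` basis matrix, `d = p^2`
#' @param p patch side
#' @param power_frac concentration threshold (default 0.5)
#' @param wedge_deg angular half-width of the wedge in degrees
#' @return fraction of columns passing, in \[0, 1\]
#' @export
basis_bandpass_fraction <- function(A, p, power_frac = 0.5, wedge_deg = 30) {
  p <- as.integer(p)
  if (nrow(A) != p * p) .stopf("A has %d rows; expected p^2 = %d", nrow(A), p * p)
  fr <- .fftfreq(p)
  fx <- matrix(fr, p, p)        # along rows
  fy <- matrix(fr, p, p, byrow = TRUE)
  rad <- sqrt(fx^2 + fy^2)
  ang <- atan2(fy, fx) %% pi
  wedge <- wedge_deg * pi / 180
  pass <- vapply(seq_len(ncol(A)), function(k) {
    tile <- matrix(A[, k], p, p)
    tile <- tile - mean(tile)
    P <- Mod(stats::fft(tile))^2
    tot <- sum(P)
    if (tot <= 0) return(FALSE)
    pk <- which.max(P)
    dphi <- abs(ang - ang[pk])
    dphi <- pmin(dphi, pi - dphi)
    mask <- dphi <= wedge & rad >= rad[pk] / 2 & rad <= 2 * rad[pk]
    sum(P[mask]) / tot > power_frac
  }, logical(1))
  mean(pass)
}

#' RMS contrast of an image
#'
#' Standard deviation of the pixel values — the contrast measure used to
#' quantify enhancement gains.
#'
#' @param image a [raw_image()] or numeric matrix
#' @return non-negative scalar
#' @export
rms_contrast <- function(image) stats::sd(as.vector(.px(image)))

#' Save / load a fitted model
#'
#' Serializes the full model container (all layers: means, eigenpairs,
#' demixing and basis matrices, per-dimension generalized-Gaussian
#' parameters, patch geometry and seeds) with a pinned serialization
#' version, so a reloaded model is bit-identical.
#'
#' @param model a [hica()] model
#' @param path file path
#' @return `hica_save` returns `path` invisibly; `hica_load` returns the
#'   model
#' @export
hica_save <- function(model, path) {
  stopifnot(inherits(model, "hica"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname hica_save
#' @export
hica_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "hica"))
  model
}
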