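#' Number of adaptive manifolds
#'
#' The manifold count is derived from the two filter scales and is independent
#' of the signal dimensionality: `K = 2 + max(2, ceiling(H_S * L_R))`, where
#' `H_S = max(1, ceiling(log2(sigma_s)) - 1)` is a tree height implied by the
#' spatial scale and `L_R = 1 - sigma_r` is a linear correction from the range
#' scale (on the normalized unit intensity range). The `max(2, .)` clamp means
#' at least four manifolds are always used.
#'
#' @param sigma_s spatial standard deviation in pixels (> 0).
#' @param sigma_r range standard deviation in normalized intensity units,
#'   in (0, 1].
#' @return integer K >= 4.
#' @examples
#' compute_num_manifolds(14, 0.10)  # 5
#' compute_num_manifolds(2, 0.5)    # 4
#' @export
compute_num_manifolds <- function(sigma_s, sigma_r) {
  if (!is.numeric(sigma_s) || length(sigma_s) != 1L || !is.finite(sigma_s) ||
      sigma_s <= 0)
    stop("`sigma_s` must be a single positive number", call. = FALSE)
  if (!is.numeric(sigma_r) || length(sigma_r) != 1L || !is.finite(sigma_r) ||
      sigma_r <= 0 || sigma_r > 1)
    stop("`sigma_r` must lie in (0, 1]", call. = FALSE)
  hs <- max(1, ceiling(log2(sigma_s)) - 1)
  lr <- 1 - sigma_r
  as.integer(2L + max(2, ceiling(hs * lr)))
}

# Unnormalized Gaussian kernel phi_Sigma(x) = exp(-x^2 / (2 var)); the
# normalizing constant cancels in the gather ratio. The projection and gather
# weights use variance sigma_r^2 / 2 (covariance Sigma_R / 2).
phi_gauss <- function(x, var) exp(-x^2 / (2 * var))

#' First adaptive manifold
#'
#' The root manifold is the spatial low-pass of the image itself:
#' `eta_1 = h_SigmaS * f`, a unit-gain Gaussian of standard deviation
#' `sigma_s` with reflect boundary handling.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param sigma_s spatial standard deviation in pixels.
#' @return matrix of the same shape (the manifold's per-pixel value field).
#' @export
build_first_manifold <- function(image, sigma_s) {
  image <- validate_gray(image)
  gauss_blur(image, sigma_s)
}

#' Project an image onto a manifold
#'
#' Gaussian distance-weighted projection: at each pixel the weight is
#' `w = phi_{SigmaR/2}(eta - f) = exp(-(eta - f)^2 / sigma_r^2)` and the
#' projected signal carries both `w * f` and `w` so the later gather can form
#' a normalized ratio.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param manifold per-pixel manifold value field, same shape as `image`.
#' @param sigma_r range standard deviation (> 0).
#' @return list with elements `weighted_values` (`w * f`) and `weights`
#'   (`w`, strictly positive).
#' @export
project_onto_manifold <- function(image, manifold, sigma_r) {
  stopifnot(is.matrix(image), is.matrix(manifold))
  check_same_shape(image, manifold, "image and manifold")
  if (sigma_r <= 0) stop("`sigma_r` must be positive", call. = FALSE)
  w <- phi_gauss(manifold - image, sigma_r^2 / 2)
  list(weighted_values = w * image, weights = w)
}

#' Blur a projected signal over its manifold
#'
#' The joint-space Gaussian blur (spatial covariance `Sigma_S`, range
#' covariance `Sigma_R / 2`) restricted to one manifold. Because each
#' manifold is a smooth, low-pass surface, range distances between its points
#' are negligible inside the spatial support, and the blur reduces to a
#' unit-gain spatial Gaussian applied to both fields of the projected signal.
#'
#' @param projected list with `weighted_values` and `weights`
#'   (as from [project_onto_manifold()]).
#' @param manifold the manifold value field (used for shape validation of the
#'   joint-space contract).
#' @param sigma_s spatial standard deviation in pixels.
#' @param sigma_r range standard deviation (unused by the spatial reduction;
#'   retained for the joint-space signature).
#' @return list of the same structure; weights stay strictly positive and
#'   their total is preserved (DC gain 1).
#' @export
blur_on_manifold <- function(projected, manifold, sigma_s, sigma_r = NULL) {
  stopifnot(is.list(projected),
            is.matrix(projected$weighted_values), is.matrix(projected$weights))
  check_same_shape(projected$weighted_values, projected$weights,
                   "projected fields")
  if (!is.null(manifold))
    check_same_shape(projected$weights, manifold, "projected signal and manifold")
  list(weighted_values = gauss_blur(projected$weighted_values, sigma_s),
       weights = gauss_blur(projected$weights, sigma_s))
}

#' Gather the final filter response from all manifolds
#'
#' Per pixel, `g_i = sum_k w_ki * Psi2_k(values) / sum_k w_ki *
#' Psi2_k(weights)`, where `w_ki` are the projection weights and `Psi2_k` the
#' blurred projected signals. The ratio interpolates the blurred values across
#' manifolds; pixels whose denominator underflows fall back to the supplied
#' reference field rather than producing NaN.
#'
#' @param blurred_list list of blurred projected signals (each a list with
#'   `weighted_values` and `weights`).
#' @param weight_list list of per-pixel projection-weight fields `w_ki`,
#'   parallel to `blurred_list`.
#' @param fallback optional matrix used where the total weight underflows
#'   (default: error on degenerate pixels).
#' @return numeric matrix, clipped to \[0, 1\].
#' @export
gather_manifolds <- function(blurred_list, weight_list, fallback = NULL) {
  stopifnot(length(blurred_list) >= 1L,
            length(blurred_list) == length(weight_list))
  num <- 0; den <- 0
  shp <- dim(blurred_list[[1L]]$weighted_values)
  for (k in seq_along(blurred_list)) {
    bk <- blurred_list[[k]]; wk <- weight_list[[k]]
    stopifnot(identical(dim(bk$weighted_values), shp),
              identical(dim(bk$weights), shp), identical(dim(wk), shp))
    num <- num + wk * bk$weighted_values
    den <- den + wk * bk$weights
  }
  bad <- den <= .Machine$double.xmin
  if (any(bad)) {
    if (is.null(fallback))
      stop("degenerate gather: total weight underflows at ",
           sum(bad), " pixel(s)", call. = FALSE)
    den[bad] <- 1
  }
  g <- num / den
  if (any(bad)) g[bad] <- fallback[bad]
  pmin(pmax(g, 0), 1)
}

#' Split pixels by the sign of the manifold residual
#'
#' Partitions the pixel grid into the pixels at or above the manifold
#' (`f - eta >= 0`) and those strictly below it; the two child manifolds of
#' the hierarchy are built from these sides.
#'
#' @param image numeric matrix.
#' @param manifold manifold value field, same shape.
#' @return list of two disjoint logical masks, `above` and `below`, whose
#'   union covers the grid.
#' @export
segment_pixels <- function(image, manifold) {
  stopifnot(is.matrix(image), is.matrix(manifold))
  check_same_shape(image, manifold, "image and manifold")
  above <- (image - manifold) >= 0
  list(above = above, below = !above)
}

# Child manifold from one side of the split: normalized masked low-pass of
# the residual, added back to the parent. An empty side falls back to the
# parent manifold.
child_manifold <- function(image, parent_eta, mask, sigma_s) {
  if (!any(mask)) return(parent_eta)
  m <- mask * 1
  num <- gauss_blur((image - parent_eta) * m, sigma_s)
  den <- gauss_blur(m, sigma_s)
  parent_eta + ifelse(den > 1e-12, num / den, 0)
}

# Breadth-first manifold hierarchy: eta_1 is the low-pass of the image; each
# node spawns two children (one per residual sign) until K manifolds exist.
build_manifold_tree <- function(image, sigma_s, num_manifolds) {
  eta1 <- gauss_blur(image, sigma_s)
  manifolds <- list(eta1)
  queue <- list(eta1)
  while (length(manifolds) < num_manifolds && length(queue) > 0L) {
    eta <- queue[[1L]]; queue <- queue[-1L]
    seg <- segment_pixels(image, eta)
    for (mask in list(seg$above, seg$below)) {
      if (length(manifolds) >= num_manifolds) break
      child <- child_manifold(image, eta, mask, sigma_s)
      manifolds[[length(manifolds) + 1L]] <- child
      queue[[length(queue) + 1L]] <- child
    }
  }
  manifolds
}

#' Edge-preserving adaptive manifold filter
#'
#' Approximates high-dimensional (bilateral-type) Gaussian filtering of a
#' grayscale image by projecting the signal onto a small hierarchy of smooth
#' manifolds in the joint space-range domain, blurring along each manifold,
#' and gathering the blurred values as a normalized, distance-weighted ratio.
#' Homogeneous regions are smoothed at scale `sigma_s` while intensity
#' discontinuities larger than a few `sigma_r` are preserved. The filter is
#' deterministic and exact on constant images.
#'
#' @param image numeric matrix with values in \[0, 1\].
#' @param sigma_s spatial standard deviation in pixels (default 14).
#' @param sigma_r range standard deviation on the normalized intensity scale
#'   (default 0.10). Values above 1 are allowed and drive the filter toward a
#'   plain spatial Gaussian blur.
#' @param num_manifolds `"auto"` (default) to derive K from the scales via
#'   [compute_num_manifolds()], or an explicit integer >= 1. When `sigma_r`
#'   exceeds the unit intensity range, `"auto"` uses the minimum K = 4: with
#'   effectively unbounded range support all manifolds coincide in effect.
#' @return filtered matrix, same shape, values in \[0, 1\].
#' @examples
#' img <- matrix(rep(c(0.2, 0.8), each = 32 * 16), 32, 32)
#' out <- amf_filter(img, sigma_s = 4, sigma_r = 0.1)
#' @export
amf_filter <- function(image, sigma_s = 14, sigma_r = 0.10,
                       num_manifolds = "auto") {
  image <- validate_gray(image)
  if (!is.numeric(sigma_s) || sigma_s <= 0)
    stop("`sigma_s` must be positive", call. = FALSE)
  if (!is.numeric(sigma_r) || sigma_r <= 0)
    stop("`sigma_r` must be positive", call. = FALSE)
  if (identical(num_manifolds, "auto")) {
    K <- if (sigma_r > 1) 4L else compute_num_manifolds(sigma_s, sigma_r)
  } else {
    K <- as.integer(num_manifolds)
    if (is.na(K) || K < 1L)
      stop("`num_manifolds` must be \"auto\" or a positive integer",
           call. = FALSE)
  }
  manifolds <- build_manifold_tree(image, sigma_s, K)
  blurred <- vector("list", length(manifolds))
  weights <- vector("list", length(manifolds))
  for (k in seq_along(manifolds)) {
    proj <- project_onto_manifold(image, manifolds[[k]], sigma_r)
    blurred[[k]] <- blur_on_manifold(proj, manifolds[[k]], sigma_s, sigma_r)
    weights[[k]] <- proj$weights
  }
  gather_manifolds(blurred, weights, fallback = manifolds[[1L]])
}
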