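#' Spatial frequency of a window
#'
#' Root-mean-square first-difference activity along rows and columns:
#' `SF = sqrt(RF^2 + CF^2)` with `RF^2 = (1/MN) * sum_{i, j>=2}
#' (I(i,j) - I(i,j-1))^2` and `CF^2 = (1/MN) * sum_{i>=2, j}
#' (I(i,j) - I(i-1,j))^2`, each difference summed over exactly its valid
#' index range.
#'
#' @param window numeric matrix, at least 2 x 2.
#' @return nonnegative scalar; 0 for constant windows and homogeneous of
#'   degree 1 in intensity.
#' @export
spatial_frequency <- function(window) {
  stopifnot(is.matrix(window), is.numeric(window))
  if (nrow(window) < 2L || ncol(window) < 2L)
    stop("window must be at least 2 x 2", call. = FALSE)
  m <- nrow(window); n <- ncol(window)
  rf2 <- sum((window[, -1L, drop = FALSE] - window[, -n, drop = FALSE])^2) / (m * n)
  cf2 <- sum((window[-1L, , drop = FALSE] - window[-m, , drop = FALSE])^2) / (m * n)
  sqrt(rf2 + cf2)
}

#' Diagonal frequency of a window
#'
#' The diagonal complement of [spatial_frequency()]:
#' `DF = sqrt((1/MN) * sum_{i>=2, j>=2} ((I(i,j) - I(i-1,j-1))^2 +
#' (I(i-1,j) - I(i,j-1))^2))`, covering both diagonal directions.
#'
#' @inheritParams spatial_frequency
#' @return nonnegative scalar.
#' @export
diagonal_frequency <- function(window) {
  stopifnot(is.matrix(window), is.numeric(window))
  if (nrow(window) < 2L || ncol(window) < 2L)
    stop("window must be at least 2 x 2", call. = FALSE)
  m <- nrow(window); n <- ncol(window)
  a <- window[-1L, -1L, drop = FALSE] - window[-m, -n, drop = FALSE]
  b <- window[-m, -1L, drop = FALSE] - window[-1L, -n, drop = FALSE]
  sqrt((sum(a^2) + sum(b^2)) / (m * n))
}

#' Per-pixel modified spatial frequency map
#'
#' Evaluates `MSF = sqrt(SF^2 + DF^2)` on the `(2r+1) x (2r+1)` neighborhood
#' centered at every pixel (reflect padding at the border), so the map has
#' the image's shape. This local detail measure is the high-frequency term of
#' the modified local contrast; the default 3 x 3 window is the smallest that
#' supports all four difference directions.
#'
#' Implemented with summed-area tables over the squared-difference planes of
#' the padded image; identical, up to float roundoff, to extracting each
#' window and calling [spatial_frequency()] / [diagonal_frequency()].
#'
#' @param image numeric matrix in \[0, 1\].
#' @param window_radius window radius r >= 1 in pixels (default 1).
#' @return nonnegative matrix of the image's shape.
#' @export
msf_map <- function(image, window_radius = 1L) {
  image <- validate_gray(image)
  r <- as.integer(window_radius)
  if (is.na(r) || r < 1L) stop("`window_radius` must be >= 1", call. = FALSE)
  m <- nrow(image); n <- ncol(image)
  P <- pad_reflect(image, r)
  mp <- nrow(P); np <- ncol(P)
  w <- 2L * r + 1L

  dh <- cbind(0, (P[, -1L, drop = FALSE] - P[, -np, drop = FALSE])^2)
  dv <- rbind(0, (P[-1L, , drop = FALSE] - P[-mp, , drop = FALSE])^2)
  d1 <- (P[-1L, -1L, drop = FALSE] - P[-mp, -np, drop = FALSE])^2
  d2 <- (P[-mp, -1L, drop = FALSE] - P[-1L, -np, drop = FALSE])^2
  dd <- rbind(0, cbind(0, d1 + d2))

  # window at pixel (i,j) spans padded rows i..i+2r, cols j..j+2r; the
  # horizontal differences live at cols >= j+1, vertical at rows >= i+1,
  # diagonal at both.
  rf2 <- sat_rect(sat2d(dh), m, n, 0L, 2L * r, 1L, 2L * r)
  cf2 <- sat_rect(sat2d(dv), m, n, 1L, 2L * r, 0L, 2L * r)
  df2 <- sat_rect(sat2d(dd), m, n, 1L, 2L * r, 1L, 2L * r)
  sqrt(pmax(rf2 + cf2 + df2, 0)) / w
}

#' Modified local contrast
#'
#' Elementwise ratio of local detail to local background brightness:
#' `MLC = MSF / AMF` where the filter response is nonzero, and `MLC = MSF`
#' where it is exactly zero. Dividing by the edge-preserving low-pass makes
#' the saliency a contrast (Weber-like) quantity rather than raw activity, so
#' detail on dark backgrounds competes fairly with detail on bright ones.
#'
#' @param msf nonnegative matrix (modified spatial frequency map).
#' @param amf matrix of the same shape (adaptive-manifold filter response,
#'   the local background term).
#' @return nonnegative finite matrix.
#' @export
modified_local_contrast <- function(msf, amf) {
  stopifnot(is.matrix(msf), is.matrix(amf))
  check_same_shape(msf, amf, "MSF and AMF maps")
  if (min(msf) < 0) stop("`msf` must be nonnegative", call. = FALSE)
  ifelse(amf == 0, msf, msf / amf)
}

#' All saliency maps for one source image
#'
#' Convenience wrapper computing the three per-pixel maps used by the fusion
#' rule: the adaptive-manifold filter response (local background), the
#' modified spatial frequency (local detail), and their ratio, the modified
#' local contrast.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param sigma_s,sigma_r adaptive manifold filter scales
#'   (see [amf_filter()]).
#' @param window_radius MSF window radius (see [msf_map()]).
#' @param num_manifolds manifold count (see [amf_filter()]).
#' @return object of class `saliency_maps`: list with matrices `msf`, `amf`,
#'   `mlc`.
#' @export
saliency_maps <- function(image, sigma_s = 14, sigma_r = 0.10,
                          window_radius = 1L, num_manifolds = "auto") {
  image <- validate_gray(image)
  amf <- amf_filter(image, sigma_s, sigma_r, num_manifolds)
  msf <- msf_map(image, window_radius)
  structure(list(msf = msf, amf = amf,
                 mlc = modified_local_contrast(msf, amf)),
            class = "saliency_maps")
}

#' @export
print.saliency_maps <- function(x, ...) {
  cat(sprintf("saliency_maps: %d x %d; MSF in [%.4g, %.4g]; MLC in [%.4g, %.4g]\n",
              nrow(x$msf), ncol(x$msf), min(x$msf), max(x$msf),
              min(x$mlc), max(x$mlc)))
  invisible(x)
}
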