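#' Validate a grayscale intensity image
#'
#' The package represents a grayscale image as a plain numeric matrix with
#' intensities normalized to the unit interval. All pipeline stages (filtering,
#' saliency, fusion, metrics) operate on this representation; file readers map
#' native bit depths onto it.
#'
#' @param x object to validate.
#' @param arg name used in error messages.
#' @return `x`, invisibly coerced to a plain numeric matrix.
#' @keywords internal
validate_gray <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop(sprintf("`%s` must be at least 2 x 2 (got %d x %d)",
                 arg, nrow(x), ncol(x)), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
    stop(sprintf("`%s` must be normalized to [0, 1] (range %.4g .. %.4g)",
                 arg, min(x), max(x)), call. = FALSE)
  storage.mode(x) <- "double"
  invisible(x)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s differ in shape: %d x %d vs %d x %d", what,
                 nrow(a), ncol(a), nrow(b), ncol(b)), call. = FALSE)
  invisible(TRUE)
}

#' Reflect (mirror) index into 1..n
#'
#' Folds arbitrary integer indices into the valid range by symmetric
#' reflection with edge repetition (`... b a | a b c d | d c ...`), the
#' boundary rule used by every spatial operation in the package. Handles
#' kernels wider than the image by repeated folding.
#'
#' @param i integer vector of (possibly out-of-range) indices.
#' @param n extent of the dimension.
#' @keywords internal
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

#' Pad a matrix by symmetric reflection
#'
#' @param x numeric matrix.
#' @param r nonnegative integer pad radius applied on all four sides.
#' @return `(nrow + 2r) x (ncol + 2r)` matrix.
#' @export
pad_reflect <- function(x, r) {
  r <- as.integer(r)
  stopifnot(is.matrix(x), r >= 0L)
  if (r == 0L) return(x)
  ri <- reflect_index(seq.int(1L - r, nrow(x) + r), nrow(x))
  ci <- reflect_index(seq.int(1L - r, ncol(x) + r), ncol(x))
  x[ri, ci, drop = FALSE]
}

#' Normalized 1-D Gaussian kernel
#'
#' Truncated at `ceiling(3 * sigma)` and normalized to unit sum (DC gain 1).
#'
#' @param sigma standard deviation in pixels (> 0).
#' @return odd-length numeric vector summing to 1.
#' @export
gauss_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# One-dimensional blur operator as a dense n x n matrix: row i carries the
# kernel centered at i with out-of-range taps folded back by reflection.
# Row sums are exactly the kernel sum (1), so constants are preserved.
blur_matrix <- function(n, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (t in seq_along(k)) {
    src <- reflect_index(seq_len(n) + (t - 1L - r), n)
    B[cbind(seq_len(n), src)] <- B[cbind(seq_len(n), src)] + k[t]
  }
  B
}

.blur_cache <- new.env(parent = emptyenv())

blur_matrix_cached <- function(n, sigma) {
  key <- sprintf("%d_%.10g", n, sigma)
  B <- .blur_cache[[key]]
  if (is.null(B)) {
    B <- blur_matrix(n, sigma)
    .blur_cache[[key]] <- B
  }
  B
}

#' Separable Gaussian blur with reflect boundary
#'
#' Low-pass filters a matrix with a truncated, unit-sum Gaussian applied along
#' rows and columns, using symmetric (edge-repeated) reflection at the image
#' border. Equivalent to zero-phase 2-D Gaussian convolution of the reflected
#' extension; implemented as two banded-matrix products so repeated calls at a
#' fixed size and sigma reuse the operator.
#'
#' @param x numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return matrix of the same shape; exact for constant inputs.
#' @export
gauss_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), is.numeric(x))
  Bv <- blur_matrix_cached(nrow(x), sigma)
  Bh <- blur_matrix_cached(ncol(x), sigma)
  Bv %*% x %*% t(Bh)
}

# Summed-area table with a leading zero row/column, so that
# sum(x[a1:a2, b1:b2]) = S[a2+1,b2+1] - S[a1,b2+1] - S[a2+1,b1] + S[a1,b1].
sat2d <- function(x) {
  S <- apply(x, 2L, cumsum)
  S <- t(apply(S, 1L, cumsum))
  if (nrow(x) == 1L) S <- matrix(S, nrow = 1L)  # apply() drops to vector
  rbind(0, cbind(0, S))
}

# Sliding rectangle sums over a padded plane: for every original pixel (i,j)
# (mapped to padded coordinates), the sum of `S`'s source over padded rows
# i+a1 .. i+a2 and cols j+b1 .. j+b2. Offsets are relative to the window's
# top-left anchor, i.e. the padded row index equals the original row index.
sat_rect <- function(S, m, n, a1, a2, b1, b2) {
  ri <- seq_len(m); ci <- seq_len(n)
  S[ri + a2 + 1L, ci + b2 + 1L, drop = FALSE] -
    S[ri + a1, ci + b2 + 1L, drop = FALSE] -
    S[ri + a2 + 1L, ci + b1, drop = FALSE] +
    S[ri + a1, ci + b1, drop = FALSE]
}
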