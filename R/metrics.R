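#' Configuration for the objective fusion metrics
#'
#' Bundles the histogram bin count used by mutual information and the
#' sigmoid constants of the edge-preservation index. The sigmoid defaults are
#' the reference values of the Xydeas-Petrovic metric (edge strength:
#' Gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5; orientation:
#' Gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8); they are exposed here so
#' they are auditable rather than hard-coded. With these constants the index
#' has a ceiling of `Qg(1) * Qa(1) ~= 0.9748` at perfect edge preservation.
#'
#' @param bins number of gray-level histogram bins L >= 2 (default 256,
#'   matching 8-bit sources).
#' @param gamma_g,kappa_g,sigma_g edge-strength sigmoid constants.
#' @param gamma_a,kappa_a,sigma_a orientation sigmoid constants.
#' @param edge_weight_exponent exponent applied to the source edge strength
#'   when forming the per-pixel weight omega (default 1).
#' @return object of class `metric_config`.
#' @export
metric_config <- function(bins = 256L,
                          gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5,
                          gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8,
                          edge_weight_exponent = 1) {
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  if (gamma_g <= 0 || gamma_g > 1 || gamma_a <= 0 || gamma_a > 1)
    stop("Gamma constants must lie in (0, 1]", call. = FALSE)
  if (sigma_g <= 0 || sigma_g >= 1 || sigma_a <= 0 || sigma_a >= 1)
    stop("sigma constants must lie in (0, 1)", call. = FALSE)
  structure(list(bins = bins,
                 gamma_g = gamma_g, kappa_g = kappa_g, sigma_g = sigma_g,
                 gamma_a = gamma_a, kappa_a = kappa_a, sigma_a = sigma_a,
                 edge_weight_exponent = edge_weight_exponent),
            class = "metric_config")
}

# Quantize unit-interval intensities into 1..L bin indices; exact for values
# that originated from an (L-level) integer raster.
quantize_bins <- function(x, bins) {
  idx <- as.integer(round(x * (bins - 1L))) + 1L
  pmin.int(pmax.int(idx, 1L), bins)
}

#' Joint gray-level histogram of two images
#'
#' @param t,f images of equal shape, values in \[0, 1\].
#' @param bins number of bins L per axis.
#' @return list with `counts` (L x L integer table, rows index `t`) and
#'   `normalized` (same table scaled to sum 1, whose marginals are the two
#'   images' normalized 1-D histograms).
#' @export
joint_histogram <- function(t, f, bins = 256L) {
  t <- validate_gray(t); f <- validate_gray(f)
  check_same_shape(t, f, "images")
  bins <- as.integer(bins)
  bt <- quantize_bins(t, bins); bf <- quantize_bins(f, bins)
  counts <- matrix(tabulate((bf - 1L) * bins + bt, nbins = bins * bins),
                   bins, bins)
  list(counts = counts, normalized = counts / sum(counts))
}

#' Mutual information between two images (bits)
#'
#' `MI(t:F) = sum_{u,v} h_{t,F}(u,v) log2( h_{t,F}(u,v) / (h_t(u) h_F(v)) )`
#' over the normalized joint gray-level histogram; cells with zero joint mass
#' contribute nothing. Symmetric in its arguments and equal to the Shannon
#' entropy of `t` when `f = t`.
#'
#' @param t,f images of equal shape, values in \[0, 1\].
#' @param config a [metric_config()] (only `bins` is used).
#' @return nonnegative scalar in bits.
#' @export
mutual_information <- function(t, f, config = metric_config()) {
  jh <- joint_histogram(t, f, config$bins)$normalized
  pt <- rowSums(jh); pf <- colSums(jh)
  nz <- which(jh > 0)
  p <- jh[nz]
  outer_p <- pt[((nz - 1L) %% config$bins) + 1L] *
    pf[((nz - 1L) %/% config$bins) + 1L]
  max(sum(p * log2(p / outer_p)), 0)
}

#' Shannon entropy of an image's gray-level histogram (bits)
#'
#' @inheritParams mutual_information
#' @param x image, values in \[0, 1\].
#' @return nonnegative scalar in bits.
#' @export
shannon_entropy <- function(x, config = metric_config()) {
  x <- validate_gray(x)
  p <- tabulate(quantize_bins(x, config$bins), nbins = config$bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Total fusion mutual information
#'
#' `MI = MI(x:F) + MI(y:F)`: how much gray-level information the fused image
#' carries about the two sources together. Symmetric under exchange of the
#' sources; larger is better.
#'
#' @param x,y source images; `f` fused image; all equal shape.
#' @param config a [metric_config()].
#' @return nonnegative scalar in bits.
#' @export
fusion_mutual_information <- function(x, y, f, config = metric_config()) {
  mutual_information(x, f, config) + mutual_information(y, f, config)
}

# Sobel gradients with reflect boundary: returns strength g and orientation
# alpha in (-pi/2, pi/2].
sobel_gradient <- function(x) {
  P <- pad_reflect(x, 1L)
  m <- nrow(x); n <- ncol(x)
  sh <- function(di, dj) P[seq_len(m) + 1L + di, seq_len(n) + 1L + dj,
                           drop = FALSE]
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  gy <- (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))
  g <- sqrt(gx^2 + gy^2)
  alpha <- atan(ifelse(gx == 0, ifelse(gy == 0, 0, sign(gy) * Inf), gy / gx))
  list(g = g, alpha = alpha)
}

# Per-pixel edge preservation of one source in the fused image.
edge_preservation <- function(src, fus, cfg) {
  # relative edge strength: the weaker of the two ratios, so over- and
  # under-shooting both count as loss
  G <- ifelse(src$g > fus$g,
              ifelse(src$g > 0, fus$g / src$g, 0),
              ifelse(fus$g > 0, src$g / fus$g, 0))
  A <- 1 - abs(src$alpha - fus$alpha) / (pi / 2)
  qg <- cfg$gamma_g / (1 + exp(cfg$kappa_g * (G - cfg$sigma_g)))
  qa <- cfg$gamma_a / (1 + exp(cfg$kappa_a * (A - cfg$sigma_a)))
  q <- qg * qa
  # both gradients zero: nothing to preserve, credit the maximum
  qmax <- (cfg$gamma_g / (1 + exp(cfg$kappa_g * (1 - cfg$sigma_g)))) *
    (cfg$gamma_a / (1 + exp(cfg$kappa_a * (1 - cfg$sigma_a))))
  q[src$g == 0 & fus$g == 0] <- qmax
  q
}

#' Edge-based fusion quality index Q^AB/F
#'
#' Measures how well the edge strength and orientation of the two sources are
#' transferred into the fused image. Sobel gradients give per-pixel edge
#' strength and orientation; relative strength and orientation agreement are
#' mapped through sigmoids to preservation scores `Q_g` and `Q_alpha`, whose
#' product is each source's per-pixel preservation; the index is their
#' average weighted by source edge strength. Range \[0, 1\], larger is
#' better; symmetric under exchange of the sources.
#'
#' If both sources are perfectly flat (all weights zero) the index is defined
#' as 1 by convention and a warning is emitted.
#'
#' @param x,y source images; `f` fused image; all equal shape, values in
#'   \[0, 1\].
#' @param config a [metric_config()] carrying the sigmoid constants.
#' @return scalar in \[0, 1\].
#' @export
edge_similarity <- function(x, y, f, config = metric_config()) {
  x <- validate_gray(x); y <- validate_gray(y); f <- validate_gray(f)
  check_same_shape(x, y, "source images")
  check_same_shape(x, f, "source and fused images")
  gx <- sobel_gradient(x); gy <- sobel_gradient(y); gf <- sobel_gradient(f)
  qx <- edge_preservation(gx, gf, config)
  qy <- edge_preservation(gy, gf, config)
  wx <- gx$g^config$edge_weight_exponent
  wy <- gy$g^config$edge_weight_exponent
  den <- sum(wx) + sum(wy)
  if (den == 0) {
    warning("both sources are perfectly flat; Q^AB/F defined as 1")
    return(1)
  }
  min(max(sum(qx * wx + qy * wy) / den, 0), 1)
}
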