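# Smooth step from 0 to 1 over [-halfwidth, halfwidth] of the signed
# distance d; gives structures a ~1-2 px anti-aliased edge.
smoothstep <- function(d, halfwidth) {
  t <- pmin(pmax((d + halfwidth) / (2 * halfwidth), 0), 1)
  t * t * (3 - 2 * t)
}

# 3x3 local variance of a field (reflect boundary), used to certify which
# source dominates where.
local_variance3 <- function(x) {
  P <- pad_reflect(x, 1L)
  m <- nrow(x); n <- ncol(x)
  s1 <- sat_rect(sat2d(P), m, n, 0L, 2L, 0L, 2L)
  s2 <- sat_rect(sat2d(P^2), m, n, 0L, 2L, 0L, 2L)
  pmax(s2 / 9 - (s1 / 9)^2, 0)
}

#' Generate a co-registered multimodal phantom pair
#'
#' Builds two perfectly registered grayscale "modalities" of the same
#' synthetic anatomy, emulating a CT/MRI-style pair in which complementary
#' structure dominates in disjoint regions. Modality A carries a bright
#' bone-like ring plus two dense blobs in the left part of the frame;
#' modality B carries an oriented sinusoidal soft-tissue texture and a sharp
#' rectangular edge structure on the right. A smooth, low-contrast shared
#' background (a broad tissue blob on a mid-gray base) appears in both, so
#' the fusion problem is nontrivial. Independent Gaussian noise of standard
#' deviation `noise_sigma` is added to each modality.
#'
#' Ground-truth dominance masks are derived from the noise-free images:
#' `mask_x` marks pixels where the 3 x 3 local variance of clean modality A
#' exceeds four times that of clean modality B (and a small absolute floor),
#' and symmetrically for `mask_y`; the masks are therefore disjoint by
#' construction and certify, before noise, where each modality is the locally
#' more informative one.
#'
#' @param size side length in pixels (>= 64; default 256).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and does not disturb the caller's RNG state.
#' @param noise_sigma Gaussian noise standard deviation on the normalized
#'   intensity scale, in \[0, 0.1\] (default 0.01).
#' @param ring_radius ring radius as a fraction of `size` (default 0.16).
#' @param texture_freq cycles of the oriented texture across the frame
#'   (default 10).
#' @return object of class `phantom_pair`: list with matrices `img_x`,
#'   `img_y` (noisy modalities), `clean_x`, `clean_y` (noise-free versions),
#'   logical masks `mask_x`, `mask_y`, and the `seed` and `noise_sigma` used.
#' @examples
#' p <- generate_phantom_pair(size = 64, seed = 7)
#' sum(p$mask_x & p$mask_y)  # masks are disjoint: 0
#' @export
generate_phantom_pair <- function(size = 256L, seed = 1L, noise_sigma = 0.01,
                                  ring_radius = 0.16, texture_freq = 10) {
  size <- as.integer(size)
  if (is.na(size) || size < 64L) stop("`size` must be >= 64", call. = FALSE)
  if (!is.numeric(noise_sigma) || noise_sigma < 0 || noise_sigma > 0.1)
    stop("`noise_sigma` must lie in [0, 0.1]", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)

  u <- (seq_len(size) - 0.5) / size
  X <- matrix(rep(u, each = size), size, size)        # column coordinate
  Y <- matrix(rep(u, times = size), size, size)       # row coordinate
  edge <- 1.2 / size                                   # ~1 px soft edge

  # shared low-contrast anatomy: mid-gray base, broad tissue blob, gentle
  # vertical shading
  bg <- 0.30 + 0.10 * exp(-((X - 0.50)^2 + (Y - 0.55)^2) / (2 * 0.22^2)) +
    0.04 * (Y - 0.5)

  # modality A: bright ring + a dense trabecular-textured disc + a small
  # blob (left). The concentric texture gives A's dominance region an
  # interior, not just edge ribbons.
  rA <- sqrt((X - 0.30)^2 + (Y - 0.45)^2)
  ring <- smoothstep(rA - (ring_radius - 0.025), edge) *
    smoothstep((ring_radius + 0.025) - rA, edge)
  rT <- sqrt((X - 0.24)^2 + (Y - 0.74)^2)
  disc_a <- smoothstep(0.085 - rT, edge)
  trab <- disc_a * (0.30 + 0.16 * sin(2 * pi * 16 * rT))
  blob2 <- smoothstep(0.038 - sqrt((X - 0.40)^2 + (Y - 0.18)^2), edge)
  struct_x <- 0.55 * ring + trab + 0.40 * blob2

  # modality B: oriented sinusoid inside a disc + sharp bright bar (right)
  rB <- sqrt((X - 0.73)^2 + (Y - 0.40)^2)
  disc <- smoothstep(0.17 - rB, edge)
  theta <- pi / 6
  tex <- 0.30 * sin(2 * pi * texture_freq * (X * cos(theta) + Y * sin(theta)))
  bar <- smoothstep(X - 0.62, edge) * smoothstep(0.86 - X, edge) *
    smoothstep(Y - 0.70, edge) * smoothstep(0.80 - Y, edge)
  struct_y <- tex * disc + 0.40 * bar

  clean_x <- pmin(pmax(bg + struct_x, 0), 1)
  clean_y <- pmin(pmax(bg + struct_y, 0), 1)

  vx <- local_variance3(clean_x)
  vy <- local_variance3(clean_y)
  vfloor <- 1e-4
  mask_x <- vx > 4 * vy & vx > vfloor
  mask_y <- vy > 4 * vx & vy > vfloor

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  img_x <- pmin(pmax(clean_x + matrix(stats::rnorm(size^2, 0, noise_sigma),
                                      size, size), 0), 1)
  img_y <- pmin(pmax(clean_y + matrix(stats::rnorm(size^2, 0, noise_sigma),
                                      size, size), 0), 1)

  structure(list(img_x = img_x, img_y = img_y,
                 clean_x = clean_x, clean_y = clean_y,
                 mask_x = mask_x, mask_y = mask_y,
                 seed = seed, noise_sigma = noise_sigma),
            class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf(paste0("phantom_pair: %d x %d, seed %d, noise sigma %.3g; ",
                     "mask_x %.1f%%, mask_y %.1f%% of pixels\n"),
              nrow(x$img_x), ncol(x$img_x), x$seed, x$noise_sigma,
              100 * mean(x$mask_x), 100 * mean(x$mask_y)))
  invisible(x)
}

# Binary erosion by a (2r+1)^2 square structuring element (border pixels are
# eroded away).
erode_mask <- function(mask, r) {
  r <- as.integer(r)
  if (r <= 0L) return(mask)
  m <- nrow(mask); n <- ncol(mask)
  P <- matrix(0, m + 2L * r, n + 2L * r)
  P[seq_len(m) + r, seq_len(n) + r] <- mask * 1
  sat_rect(sat2d(P), m, n, 0L, 2L * r, 0L, 2L * r) >= (2L * r + 1L)^2 - 0.5
}

#' Decision-map agreement with the ground-truth dominance masks
#'
#' Fraction of interior ground-truth pixels on which a decision map picks the
#' modality that truly dominates there: `D = 1` inside `mask_x` and `D = 0`
#' inside `mask_y`, after eroding both masks by `erode_radius` so pixels
#' whose saliency window straddles a dominance boundary are not scored.
#'
#' @param decision binary decision map (1 selects modality A).
#' @param mask_x,mask_y disjoint logical ground-truth masks
#'   (from [generate_phantom_pair()]).
#' @param erode_radius erosion radius in pixels (default 2: the MSF window
#'   radius plus one).
#' @return scalar in \[0, 1\].
#' @export
decision_accuracy <- function(decision, mask_x, mask_y, erode_radius = 2L) {
  stopifnot(is.matrix(decision))
  check_same_shape(decision, mask_x, "decision map and mask")
  ex <- erode_mask(mask_x, erode_radius)
  ey <- erode_mask(mask_y, erode_radius)
  total <- sum(ex) + sum(ey)
  if (total == 0) stop("eroded masks are empty", call. = FALSE)
  (sum(decision[ex] == 1L) + sum(decision[ey] == 0L)) / total
}
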