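# Independent brute-force oracles. These deliberately use naive scalar loops
# and dense sums, sharing no code path with the package's vectorized
# implementations.

# Dense 2-D Gaussian convolution with symmetric-reflect padding.
oracle_gauss_conv <- function(x, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  K2 <- outer(k, k)
  P <- pad_reflect(x, r)
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      out[i, j] <- sum(K2 * P[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

# O(n^2) joint-space Gaussian mean over (pixel position, manifold value);
# spatial variance sigma_s^2, range variance sigma_r^2 / 2.
oracle_joint_blur <- function(field, eta, sigma_s, sigma_r) {
  m <- nrow(field); n <- ncol(field)
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    W <- 0; V <- 0
    for (a in seq_len(m)) for (b in seq_len(n)) {
      w <- exp(-((i - a)^2 + (j - b)^2) / (2 * sigma_s^2)) *
        exp(-(eta[i, j] - eta[a, b])^2 / (2 * (sigma_r^2 / 2)))
      W <- W + w
      V <- V + w * field[a, b]
    }
    out[i, j] <- V / W
  }
  out
}

# O(n^2) brute-force bilateral (joint space-range Gaussian) filter.
oracle_bilateral <- function(x, sigma_s, sigma_r) {
  m <- nrow(x); n <- ncol(x)
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    W <- 0; V <- 0
    for (a in seq_len(m)) for (b in seq_len(n)) {
      w <- exp(-((i - a)^2 + (j - b)^2) / (2 * sigma_s^2)) *
        exp(-(x[i, j] - x[a, b])^2 / (2 * sigma_r^2))
      W <- W + w
      V <- V + w * x[a, b]
    }
    out[i, j] <- V / W
  }
  out
}

# Per-window MSF by explicit window extraction and scalar formulas.
oracle_msf_map <- function(image, r) {
  P <- pad_reflect(image, r)
  m <- nrow(image); n <- ncol(image)
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    win <- P[i:(i + 2L * r), j:(j + 2L * r)]
    M <- nrow(win); N <- ncol(win)
    rf2 <- 0; cf2 <- 0; df2 <- 0
    for (a in seq_len(M)) for (b in 2:N)
      rf2 <- rf2 + (win[a, b] - win[a, b - 1])^2
    for (a in 2:M) for (b in seq_len(N))
      cf2 <- cf2 + (win[a, b] - win[a - 1, b])^2
    for (a in 2:M) for (b in 2:N)
      df2 <- df2 + (win[a, b] - win[a - 1, b - 1])^2 +
        (win[a - 1, b] - win[a, b - 1])^2
    out[i, j] <- sqrt((rf2 + cf2 + df2) / (M * N))
  }
  out
}

# Scalar-loop joint histogram and mutual information (bits).
oracle_mi <- function(t, f, bins = 256L) {
  bt <- pmin(pmax(as.integer(round(t * (bins - 1))) + 1L, 1L), bins)
  bf <- pmin(pmax(as.integer(round(f * (bins - 1))) + 1L, 1L), bins)
  H <- matrix(0, bins, bins)
  for (k in seq_along(bt)) H[bt[k], bf[k]] <- H[bt[k], bf[k]] + 1
  H <- H / sum(H)
  pt <- rowSums(H); pf <- colSums(H)
  mi <- 0
  for (u in seq_len(bins)) for (v in seq_len(bins))
    if (H[u, v] > 0) mi <- mi + H[u, v] * log2(H[u, v] / (pt[u] * pf[v]))
  mi
}

oracle_entropy <- function(x, bins = 256L) {
  b <- pmin(pmax(as.integer(round(x * (bins - 1))) + 1L, 1L), bins)
  p <- as.numeric(table(b)) / length(b)
  -sum(p * log2(p))
}

rand_img <- function(m, n = m, seed = 1L) {
  set.seed(seed)
  matrix(runif(m * n), m, n)
}

# 8-bit-quantized random image (exactly representable histogram bins).
rand_img8 <- function(m, n = m, seed = 1L) {
  set.seed(seed)
  matrix(sample(0:255, m * n, replace = TRUE) / 255, m, n)
}

# Run the installed command-line front end in a child process.
run_cli <- function(args) {
  script <- system.file("cli", "amfuse.R", package = "amfuse")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  lib <- dirname(find.package("amfuse"))
  out <- suppressWarnings(
    system2(rscript, c(shQuote(script), args), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", lib)))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
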