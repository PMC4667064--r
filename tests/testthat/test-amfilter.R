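test_that("manifold count follows the scale formula and its lower bound", {
  expect_identical(compute_num_manifolds(2, 0.5), 4L)
  # H_S = 3, L_R = 0.9, ceil(2.7) = 3 -> K = 5 at the default scales
  expect_identical(compute_num_manifolds(14, 0.10), 5L)
  for (ss in c(1, 2, 5, 14, 30, 100))
    for (sr in c(0.01, 0.1, 0.5, 1))
      expect_gte(compute_num_manifolds(ss, sr), 4L)
  expect_error(compute_num_manifolds(0, 0.1), "positive")
  expect_error(compute_num_manifolds(-3, 0.1), "positive")
  expect_error(compute_num_manifolds(4, 0), "\\(0, 1\\]")
  expect_error(compute_num_manifolds(4, 1.5), "\\(0, 1\\]")
})

test_that("first manifold is the unit-gain low-pass of the image", {
  const <- matrix(0.42, 8, 8)
  expect_equal(build_first_manifold(const, 3), const, tolerance = 1e-12)

  img <- rand_img(32, seed = 21)
  eta1 <- build_first_manifold(img, 4)
  expect_equal(mean(eta1), mean(img), tolerance = 1e-6)
  expect_true(min(eta1) >= min(img) - 1e-9 && max(eta1) <= max(img) + 1e-9)
  expect_equal(eta1, oracle_gauss_conv(img, 4), tolerance = 1e-6)
})

test_that("projection weights follow the half-range Gaussian kernel", {
  img <- rand_img(8, seed = 2)
  proj <- project_onto_manifold(img, img, 0.1)
  expect_true(all(proj$weights == 1))  # zero range distance -> kernel peak
  expect_equal(proj$weighted_values, img)

  # scalar evaluation: f = 0.5, eta = 0.3, sigma_r = 0.2 -> w = exp(-1)
  f1 <- matrix(0.5, 2, 2); e1 <- matrix(0.3, 2, 2)
  p1 <- project_onto_manifold(f1, e1, 0.2)
  expect_equal(p1$weights[1, 1], exp(-(0.2)^2 / (0.2)^2), tolerance = 1e-12)
  expect_equal(p1$weighted_values, p1$weights * f1)

  # large range distance with small sigma_r drives weights to ~0 (but > 0)
  p2 <- project_onto_manifold(matrix(1, 4, 4), matrix(0, 4, 4), 0.05)
  expect_true(all(p2$weights > 0) && max(p2$weights) < 1e-100)

  expect_error(project_onto_manifold(img, matrix(0.5, 4, 4), 0.1), "shape")
})

test_that("manifold blur is unit-gain and matches the joint-space oracle", {
  const <- list(weighted_values = matrix(0.3, 8, 8),
                weights = matrix(0.6, 8, 8))
  bl <- blur_on_manifold(const, matrix(0.3, 8, 8), 2, 0.2)
  expect_equal(bl$weighted_values, const$weighted_values, tolerance = 1e-12)
  expect_equal(bl$weights, const$weights, tolerance = 1e-12)

  img <- rand_img(16, seed = 5)
  eta <- build_first_manifold(img, 3)
  proj <- project_onto_manifold(img, eta, 0.3)
  bl <- blur_on_manifold(proj, eta, 3, 0.3)
  expect_true(all(bl$weights > 0))
  expect_equal(sum(bl$weights), sum(proj$weights), tolerance = 1e-6)

  # dense Gaussian-weighted sum over all pixel pairs in (position, eta) space
  expect_lt(mean(abs(bl$weighted_values -
                       oracle_joint_blur(proj$weighted_values, eta, 3, 0.3))),
            5e-3)
  expect_lt(mean(abs(bl$weights -
                       oracle_joint_blur(proj$weights, eta, 3, 0.3))),
            5e-3)
})

test_that("gathering is a normalized ratio with scalar-loop agreement", {
  # single manifold, constant value c: ratio collapses to c
  w <- rand_img(8, seed = 7) * 0.9 + 0.1
  c0 <- 0.55
  one <- list(list(weighted_values = w * c0, weights = w))
  expect_equal(gather_manifolds(one, list(w)), matrix(c0, 8, 8),
               tolerance = 1e-12)

  # duplicated manifolds change nothing (convex-combination idempotence)
  img <- rand_img(8, seed = 8)
  eta <- build_first_manifold(img, 2)
  proj <- project_onto_manifold(img, eta, 0.2)
  bl <- blur_on_manifold(proj, eta, 2, 0.2)
  g1 <- gather_manifolds(list(bl), list(proj$weights))
  g2 <- gather_manifolds(list(bl, bl), list(proj$weights, proj$weights))
  expect_equal(g1, g2, tolerance = 1e-12)

  # K = 2 random fixture vs per-pixel scalar loops
  set.seed(9)
  b1 <- list(weighted_values = matrix(runif(64), 8, 8),
             weights = matrix(runif(64, 0.2, 1), 8, 8))
  b2 <- list(weighted_values = matrix(runif(64), 8, 8),
             weights = matrix(runif(64, 0.2, 1), 8, 8))
  w1 <- matrix(runif(64, 0.1, 1), 8, 8)
  w2 <- matrix(runif(64, 0.1, 1), 8, 8)
  expected <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    expected[i, j] <- (w1[i, j] * b1$weighted_values[i, j] +
                         w2[i, j] * b2$weighted_values[i, j]) /
      (w1[i, j] * b1$weights[i, j] + w2[i, j] * b2$weights[i, j])
  got <- gather_manifolds(list(b1, b2), list(w1, w2))
  expect_equal(got, pmin(pmax(expected, 0), 1), tolerance = 1e-12)

  # all-zero total weight must not silently produce NaN
  z <- list(weighted_values = matrix(0, 4, 4), weights = matrix(0, 4, 4))
  expect_error(gather_manifolds(list(z), list(matrix(0, 4, 4))), "degenerate")
})

test_that("pixel segmentation partitions the grid by residual sign", {
  img <- rand_img(8, seed = 10)
  seg <- segment_pixels(img, img)
  expect_true(all(seg$above))  # f - eta = 0 everywhere -> 'below' empty
  expect_false(any(seg$below))
  # empty side must fall back to the parent manifold
  expect_equal(amfuse:::child_manifold(img, img, seg$below, 2), img)

  expect_true(all(segment_pixels(matrix(0.6, 4, 4), matrix(0.5, 4, 4))$above))

  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0)
  eta <- matrix(0.5, 8, 8)
  f <- eta + ifelse(chk, 0.1, -0.1)
  seg3 <- segment_pixels(f, eta)
  expect_identical(seg3$above, chk)
  expect_identical(seg3$below, !chk)
  expect_true(all(xor(seg3$above, seg3$below)))
})

test_that("filter is exact on constants, bounded, and deterministic", {
  const <- matrix(0.73, 16, 16)
  expect_lt(max(abs(amf_filter(const, 4, 0.1) - 0.73)), 1e-9)

  for (s in 1:5) {
    img <- rand_img(16, seed = 100 + s)
    g <- amf_filter(img, 3, 0.15)
    expect_true(min(g) >= min(img) - 1e-6 && max(g) <= max(img) + 1e-6)
  }

  img <- rand_img(24, seed = 42)
  expect_identical(amf_filter(img, 4, 0.2), amf_filter(img, 4, 0.2))
})

test_that("filter approaches the pure spatial Gaussian as sigma_r grows", {
  img <- rand_img(32, seed = 11)
  expect_lt(mean(abs(amf_filter(img, 4, 10) - oracle_gauss_conv(img, 4))),
            1e-2)
})

test_that("filter agrees with the brute-force joint bilateral on small images", {
  set.seed(3)
  img <- gauss_blur(matrix(runif(256), 16, 16), 1)
  img <- (img - min(img)) / (max(img) - min(img))
  for (sr in c(0.1, 0.3))
    expect_lt(mean(abs(amf_filter(img, 3, sr) - oracle_bilateral(img, 3, sr))),
              5e-2)
})

test_that("filter preserves a step edge far from the discontinuity", {
  step <- cbind(matrix(0, 128, 64), matrix(1, 128, 64))
  fs <- amf_filter(step, 14, 0.10)
  far <- cbind(matrix(TRUE, 128, 22), matrix(FALSE, 128, 84),
               matrix(TRUE, 128, 22))  # >= 3 sigma_s from the edge
  expect_lt(max(abs(fs - step)[far]), 0.05)
})
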