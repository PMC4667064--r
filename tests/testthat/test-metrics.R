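test_that("joint histogram is conserved and marginal-consistent", {
  t <- rand_img8(32, seed = 71)
  f <- rand_img8(32, seed = 72)
  jh <- joint_histogram(t, f, 256L)
  expect_identical(sum(jh$counts), length(t))
  expect_equal(sum(jh$normalized), 1, tolerance = 1e-9)
  ht <- tabulate(amfuse:::quantize_bins(t, 256L), 256L) / length(t)
  hf <- tabulate(amfuse:::quantize_bins(f, 256L), 256L) / length(f)
  expect_equal(rowSums(jh$normalized), ht, tolerance = 1e-12)
  expect_equal(colSums(jh$normalized), hf, tolerance = 1e-12)
})

test_that("mutual information reduces to entropy for identical images", {
  for (s in 1:10) {
    t <- rand_img8(24, seed = 700 + s)
    expect_equal(mutual_information(t, t), shannon_entropy(t),
                 tolerance = 1e-9)
    expect_equal(shannon_entropy(t), oracle_entropy(t), tolerance = 1e-9)
  }
})

test_that("mutual information matches the scalar-loop oracle and is symmetric", {
  t <- rand_img8(24, seed = 81)
  f <- rand_img8(24, seed = 82)
  expect_equal(mutual_information(t, f), oracle_mi(t, f), tolerance = 1e-9)
  expect_equal(mutual_information(t, f), mutual_information(f, t),
               tolerance = 1e-12)
  expect_lte(mutual_information(t, f),
             min(shannon_entropy(t), shannon_entropy(f)) + 1e-9)
})

test_that("a perfectly dependent two-level pair carries exactly one bit", {
  chk <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  cfg <- metric_config(bins = 2L)
  expect_equal(mutual_information(chk, chk, cfg), 1, tolerance = 1e-12)
})

test_that("independent noise MI is pure finite-sample bias, far below H", {
  # plug-in MI of two independent 8-bit noise fields is dominated by the
  # estimator bias ~ (L-1)^2 / (2 N ln 2) ~ 0.7 bit at L = 256, N = 256^2;
  # measured ~ 0.82 bit, frozen here as a magnitude check against H = 8 bits
  n1 <- rand_img8(256, seed = 91)
  n2 <- rand_img8(256, seed = 92)
  mi <- mutual_information(n1, n2)
  expect_gt(mi, 0.4)
  expect_lt(mi, 1)
})

test_that("total fusion MI is the sum of the pairwise terms", {
  x <- rand_img8(24, seed = 93); y <- rand_img8(24, seed = 94)
  f <- rand_img8(24, seed = 95)
  expect_identical(fusion_mutual_information(x, y, f),
                   mutual_information(x, f) + mutual_information(y, f))
  expect_identical(fusion_mutual_information(x, y, f),
                   fusion_mutual_information(y, x, f))
  expect_equal(fusion_mutual_information(x, x, x), 2 * shannon_entropy(x),
               tolerance = 1e-9)
})

test_that("edge index hits its sigmoid ceiling at perfect preservation", {
  cfg <- metric_config()
  ceiling_q <- (cfg$gamma_g / (1 + exp(cfg$kappa_g * (1 - cfg$sigma_g)))) *
    (cfg$gamma_a / (1 + exp(cfg$kappa_a * (1 - cfg$sigma_a))))
  p <- generate_phantom_pair(size = 128, seed = 14, noise_sigma = 0)
  q_self <- edge_similarity(p$img_x, p$img_x, p$img_x)
  expect_equal(q_self, ceiling_q, tolerance = 1e-6)
  expect_equal(ceiling_q, 0.9747936, tolerance = 1e-6)
})

test_that("edge index collapses for a structure-destroying fusion", {
  p <- generate_phantom_pair(size = 128, seed = 15, noise_sigma = 0)
  flat <- matrix(0.5, 128, 128)
  expect_lte(edge_similarity(p$img_x, p$img_y, flat), 0.05)
})

test_that("edge index stays in [0,1] and is symmetric in the sources", {
  for (s in 1:4) {
    x <- rand_img(32, seed = 800 + s)
    y <- rand_img(32, seed = 900 + s)
    f <- merge_images(x, y, matrix(as.integer(rand_img(32, seed = s) > 0.5),
                                   32, 32))
    q <- edge_similarity(x, y, f)
    expect_gte(q, 0)
    expect_lte(q, 1)
    expect_identical(q, edge_similarity(y, x, f))
  }
  # both sources perfectly flat: defined as 1, with a warning
  flat <- matrix(0.4, 8, 8)
  expect_warning(q0 <- edge_similarity(flat, flat, flat), "flat")
  expect_identical(q0, 1)
})

test_that("increasing noise in the fused image degrades the edge index", {
  means <- sapply(c(0, 0.03, 0.08), function(ns) {
    mean(sapply(1:10, function(s) {
      p <- generate_phantom_pair(size = 64, seed = s, noise_sigma = 0)
      f <- fuse(p$img_x, p$img_y, sigma_s = 4)$fused
      set.seed(1000 + s)
      fn <- pmin(pmax(f + matrix(rnorm(64 * 64, 0, ns), 64, 64), 0), 1)
      edge_similarity(p$img_x, p$img_y, fn)
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("metric configuration validates its constants", {
  expect_error(metric_config(bins = 1), ">= 2")
  expect_error(metric_config(gamma_g = 1.2), "\\(0, 1\\]")
  expect_error(metric_config(sigma_a = 1), "\\(0, 1\\)")
})
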