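cfg_small <- fusion_config(avg_size = 15L,
                           guided_base = list(radius = 11L, eps = 0.3),
                           guided_detail = list(radius = 3L, eps = 1e-6))

test_that("two-scale decomposition conserves the input exactly", {
  cst <- matrix(0.3, 40, 40)
  d <- two_scale_decompose(cst, cfg_small)
  expect_equal(d$base, cst, tolerance = 1e-12)
  expect_equal(d$detail, matrix(0, 40, 40), tolerance = 1e-12)

  for (seed in 1:5) {
    x <- rand_image(40, 40, seed)
    d <- two_scale_decompose(x, cfg_small)
    expect_lt(max(abs(d$base + d$detail - x)), 1e-12)
  }

  x <- matrix(0, 9, 9); x[5, 5] <- 1
  d <- two_scale_decompose(x, fusion_config(avg_size = 3L))
  expect_equal(d$detail[5, 5], 1 - 1 / 9, tolerance = 1e-12)
})

test_that("baseline saliency composes Laplacian magnitude and Gaussian", {
  expect_equal(saliency_gff(matrix(0.5, 30, 30), cfg_small),
               matrix(0, 30, 30))

  # step edge: saliency peaks along the edge and decays away from it
  step <- cbind(matrix(0.2, 32, 16), matrix(0.8, 32, 16))
  s <- saliency_gff(step, cfg_small)
  expect_equal(unname(which.max(s[16, ])), 16, tolerance = 1)
  expect_gt(s[16, 16], s[16, 4])
  expect_gt(s[16, 16], s[16, 28])
  expect_equal(s, gaussian_smooth(laplacian_magnitude(step),
                                  cfg_small$gaussian_sigma,
                                  cfg_small$gaussian_radius))
  expect_true(all(s >= 0))

  # positive homogeneity
  x <- rand_image(24, 24, 3)
  expect_equal(saliency_gff(3 * x, cfg_small),
               3 * saliency_gff(x, cfg_small), tolerance = 1e-9)
})

test_that("LMMSE saliency reduces to the Laplacian magnitude when noise-free", {
  x <- rand_image(32, 32, 4)
  expect_identical(saliency_lmmse(x, cfg_small, sigma_n = 0),
                   laplacian_magnitude(x))
  expect_equal(saliency_lmmse(matrix(0.4, 32, 32), cfg_small,
                              sigma_n = 0.1),
               matrix(0, 32, 32))
})

test_that("LMMSE saliency is more robust to Rician noise than the baseline", {
  closer <- 0L
  for (seed in 1:10) {
    ph <- generate_phantom_pair(size = 128, seed = seed, sigma = 0.1)
    d_lmmse <- mean(abs(
      saliency_lmmse(ph$mr_noisy, cfg_small, sigma_n = 0.1) -
        saliency_lmmse(ph$mr_clean, cfg_small, sigma_n = 0)))
    d_gff <- mean(abs(saliency_gff(ph$mr_noisy, cfg_small) -
                        saliency_gff(ph$mr_clean, cfg_small)))
    closer <- closer + (d_lmmse < d_gff)
  }
  expect_gte(closer, 8L)
})

test_that("saliency pair normalization rescales jointly", {
  s2 <- rand_image(10, 10, 5); s1 <- 2 * s2
  ns <- normalize_saliency_pair(s1, s2)
  expect_equal(max(pmax(ns$s1, ns$s2)), 1)
  expect_equal(ns$s1, s1 / max(s1), tolerance = 1e-12)
  expect_true(all((ns$s1 >= ns$s2) == (s1 >= s2)))

  z <- matrix(0, 5, 5)
  nz <- normalize_saliency_pair(z, z)
  expect_equal(nz$s1, z); expect_equal(nz$s2, z)

  # scale invariance of the normalized pair
  a <- rand_image(8, 8, 6); b <- rand_image(8, 8, 7)
  n1 <- normalize_saliency_pair(a, b)
  n2 <- normalize_saliency_pair(5 * a, 5 * b)
  expect_equal(n1$s1, n2$s1, tolerance = 1e-12)
  expect_equal(n1$s2, n2$s2, tolerance = 1e-12)
})

test_that("binary weight maps follow the winner-take-all rule with A-ties", {
  m <- binary_weight_maps(matrix(0.5, 1, 1), matrix(0.3, 1, 1))
  expect_equal(m$p1[1, 1], 1); expect_equal(m$p2[1, 1], 0)

  s <- rand_image(6, 6, 8)
  tie <- binary_weight_maps(s, s)
  expect_equal(tie$p1, matrix(1, 6, 6))
  expect_equal(tie$p2, matrix(0, 6, 6))

  # exhaustive 2x2 images over {0, 0.5, 1}: per-pixel comparison oracle
  vals <- c(0, 0.5, 1)
  grid <- expand.grid(a1 = vals, a2 = vals, b1 = vals, b2 = vals)
  for (k in seq_len(nrow(grid))) {
    s1 <- matrix(c(grid$a1[k], grid$a2[k]), 2, 2)
    s2 <- matrix(c(grid$b1[k], grid$b2[k]), 2, 2)
    m <- binary_weight_maps(s1, s2)
    expect_equal(m$p1, (s1 >= s2) * 1)
    expect_equal(m$p1 + m$p2, matrix(1, 2, 2))
  }
})

test_that("multi-level weight maps reproduce the printed level function", {
  wl <- weight_level_table()
  lvl <- function(s1, s2) {
    m <- multilevel_weight_maps(matrix(s1, 1, 1), matrix(s2, 1, 1), wl)
    c(m$p1[1, 1], m$p2[1, 1])
  }
  expect_equal(lvl(0.77, 0.50), c(0.8, 0))  # margin 0.27
  expect_equal(lvl(0.60, 0.50), c(0, 0))    # margin 0.10, otherwise
  expect_equal(lvl(0.50, 0.72), c(0, 0.7))  # B-margin 0.22
  expect_equal(lvl(0.80, 0.50), c(1, 0))    # margin at the top threshold
  expect_equal(lvl(0.65, 0.50), c(0.6, 0))  # margin exactly 0.15
})

test_that("weight tables validate their invariants", {
  expect_error(weight_level_table(c(0.2, 0.3), c(1, 0.8)), "decreasing")
  expect_error(weight_level_table(c(0.3, 0.2), c(0.6, 0.8)),
               "non-increasing")
  expect_error(weight_level_table(0.3, 1.4), "0,1")
})

test_that("weight-set normalization clamps and renormalizes pairwise", {
  w <- list(base_A = matrix(0.2, 2, 2), base_B = matrix(0.6, 2, 2),
            detail_A = matrix(0, 2, 2), detail_B = matrix(0, 2, 2))
  nw <- normalize_weight_set(w)
  expect_equal(nw$base_A, matrix(0.25, 2, 2))
  expect_equal(nw$base_B, matrix(0.75, 2, 2))
  expect_equal(nw$detail_A, matrix(0.5, 2, 2))  # both-zero fallback
  expect_equal(nw$detail_B, matrix(0.5, 2, 2))

  set.seed(30)
  w2 <- list(base_A = matrix(runif(64, -0.2, 1.2), 8),
             base_B = matrix(runif(64, -0.2, 1.2), 8),
             detail_A = matrix(runif(64), 8),
             detail_B = matrix(runif(64), 8))
  nw2 <- normalize_weight_set(w2)
  expect_lt(max(abs(nw2$base_A + nw2$base_B - 1)), 1e-9)
  expect_lt(max(abs(nw2$detail_A + nw2$detail_B - 1)), 1e-9)
  expect_true(all(nw2$base_A >= 0 & nw2$base_A <= 1))
})

test_that("guided refinement keeps degenerate maps and smooths binary ones", {
  a <- smooth_rand_image(32, 9); b <- smooth_rand_image(32, 10)
  ones <- matrix(1, 32, 32); zeros <- matrix(0, 32, 32)
  w <- refine_weights(ones, zeros, a, b, cfg_small)
  expect_equal(w$base_A, ones, tolerance = 1e-9)
  expect_equal(w$base_B, zeros, tolerance = 1e-9)

  half <- matrix(0.5, 32, 32)
  ws <- refine_weights(half, half, a, a, cfg_small)
  expect_equal(ws$base_A, half, tolerance = 1e-9)
  expect_equal(ws$detail_B, half, tolerance = 1e-9)

  smoother <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    p1 <- matrix(rbinom(32 * 32, 1, 0.5), 32)
    w <- refine_weights(p1, 1 - p1, a, b, cfg_small)
    smoother <- smoother + (total_variation(w$base_A) <=
                              total_variation(p1))
  }
  expect_equal(smoother, 5L)
})

test_that("reconstruction is the weighted layer sum", {
  # hand-computed 2x2 example with all layers and weights enumerated
  w <- list(base_A = matrix(c(1, 0.25, 0.5, 0), 2, 2),
            base_B = matrix(c(0, 0.75, 0.5, 1), 2, 2),
            detail_A = matrix(c(0.5, 1, 0, 0.25), 2, 2),
            detail_B = matrix(c(0.5, 0, 1, 0.75), 2, 2))
  da <- list(base = matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2),
             detail = matrix(c(0.1, -0.1, 0.05, 0), 2, 2))
  db <- list(base = matrix(c(0.8, 0.6, 0.4, 0.2), 2, 2),
             detail = matrix(c(-0.05, 0.2, 0.1, -0.2), 2, 2))
  expected <- w$base_A * da$base + w$base_B * db$base +
    w$detail_A * da$detail + w$detail_B * db$detail
  expect_equal(reconstruct(w, da, db), pmin(pmax(expected, 0), 1))

  # weights all on A reproduce A
  x <- rand_image(12, 12, 11)
  dx <- two_scale_decompose(x, cfg_small)
  dy <- two_scale_decompose(rand_image(12, 12, 12), cfg_small)
  wa <- list(base_A = matrix(1, 12, 12), base_B = matrix(0, 12, 12),
             detail_A = matrix(1, 12, 12), detail_B = matrix(0, 12, 12))
  expect_equal(reconstruct(wa, dx, dy), pmin(pmax(x, 0), 1),
               tolerance = 1e-12)
})

test_that("fusing an image with itself returns the image", {
  ph <- generate_phantom_pair(size = 96, seed = 13, sigma = 0.1)
  for (scheme in c("gff", "improved")) {
    cfg <- fusion_config(scheme, avg_size = 15L,
                         guided_base = list(radius = 11L, eps = 0.3),
                         guided_detail = list(radius = 3L, eps = 1e-6))
    fz <- fuse_images(ph$mr_noisy, ph$mr_noisy, cfg)
    expect_lt(max(abs(fz$fused - ph$mr_noisy)), 1e-9)
  }
})

test_that("fusion recovers complementary half-images", {
  ph <- generate_phantom_pair(size = 128, seed = 2, sigma = 0)
  ideal <- ph$ideal_composite
  a <- ideal; a[, 65:128] <- 0.3
  b <- ideal; b[, 1:64] <- 0.3
  for (scheme in c("gff", "improved")) {
    cfg <- fusion_config(scheme, lmmse_sigma = 0)
    fz <- fuse_images(a, b, cfg)$fused
    err_f <- mean(abs(fz - ideal))
    expect_lt(err_f, mean(abs(a - ideal)))
    expect_lt(err_f, mean(abs(b - ideal)))
  }
})

test_that("fusion is symmetric under input swap on tie-free images", {
  a <- smooth_rand_image(96, 14); b <- smooth_rand_image(96, 15)
  for (scheme in c("gff", "improved")) {
    cfg <- fusion_config(scheme, lmmse_sigma = 0)
    f1 <- fuse_images(a, b, cfg)$fused
    f2 <- fuse_images(b, a, cfg)$fused
    expect_lt(max(abs(f1 - f2)), 1e-9)
  }
})

test_that("fused output stays in [0,1] and weight pairs sum to one", {
  ph <- generate_phantom_pair(size = 96, seed = 17, sigma = 0.1)
  fz <- fuse_images(ph$mr_noisy, ph$ct,
                    fusion_config("improved", avg_size = 15L))
  expect_true(all(fz$fused >= 0 & fz$fused <= 1))
  expect_lt(max(abs(fz$weights$base_A + fz$weights$base_B - 1)), 1e-9)
  expect_lt(max(abs(fz$weights$detail_A + fz$weights$detail_B - 1)),
            1e-9)
})
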