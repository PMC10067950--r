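test_that("LSE pooling matches the direct formula and its bounds", {
  # constant grid pools to the constant for any sharpness
  for (r in c(0.5, 1, 5, 50)) expect_equal(lse_pool(matrix(2, 3, 3), r), 2)
  # hand-evaluated 2x2 example
  expect_equal(lse_pool(matrix(c(0, 0, 0, 1), 2, 2), 1), log((3 + exp(1)) / 4),
               tolerance = 1e-12)
  # oracle suite: direct (unshifted) formula, mean/max bounds, r -> Inf
  set.seed(101)
  for (i in 1:1000) {
    g <- matrix(rnorm(12 * 8, sd = 2), 12, 8)
    r <- runif(1, 0.2, 10)
    direct <- log(mean(exp(r * g))) / r
    v <- lse_pool(g, r)
    expect_equal(v, direct, tolerance = 1e-9)
    expect_gte(v, mean(g) - 1e-12)
    expect_lte(v, max(g) + 1e-12)
  }
  set.seed(102)
  for (i in 1:20) {
    g <- matrix(rnorm(12 * 8), 12, 8)
    expect_equal(lse_pool(g, 500), max(g), tolerance = 1 / 50)
  }
  expect_error(lse_pool(matrix(c(1, NA, 3, 4), 2, 2), 1), "non-finite")
  expect_error(lse_pool(matrix(1, 2, 2), -1), "positive")
})

test_that("squeeze-and-excitation gates match a hand-computed toy case", {
  # 1x1 spatial, 2 channels, hand-set weights
  x <- array(c(2, -1), c(1, 1, 2))
  w1 <- matrix(c(0.5, -0.25), nrow = 1)        # bottleneck to 1 unit
  b1 <- 0.1
  w2 <- matrix(c(1, -2), ncol = 1)             # expand to 2 channels
  b2 <- c(0, 0.5)
  # z = (2, -1); a = relu(0.5*2 + 0.25*1 + 0.1) = 1.35
  # s = sigmoid(c(1.35, -2.7 + 0.5))
  s_expected <- 1 / (1 + exp(-c(1.35, -2.2)))
  out <- se_recalibrate(x, w1, b1, w2, b2)
  expect_equal(out$gate, s_expected)
  expect_equal(as.vector(out$output), c(2, -1) * s_expected)
  # gate < 1 bounds output magnitude by input magnitude
  set.seed(5)
  xr <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  outr <- se_recalibrate(xr, w1, b1, w2, b2)
  expect_true(all(abs(outr$output) <= abs(xr)))
  # all-zero input stays zero
  z0 <- se_recalibrate(array(0, c(2, 2, 2)), w1, b1, w2, b2)
  expect_true(all(z0$output == 0))
})

test_that("the default stream maps 384x256 to a 12x8x3 feature map", {
  st <- build_stream(stream_config(), seed = 1)
  set.seed(2)
  fm <- forward_stream(st, matrix(runif(384 * 256), 384, 256))
  expect_identical(dim(fm), c(12L, 8L, 3L))
})

test_that("each stream has six SE-residual blocks and 32x reduction", {
  cfg <- stream_config()
  expect_identical(cfg$n_blocks, 6L)
  expect_equal(prod(cfg$block_strides), 32)
  blocks <- mastosym:::stream_blocks(cfg)
  expect_length(blocks, 6L)
  st <- build_stream(cfg, seed = 1)
  # every block carries its own SE weights
  for (i in 1:6) {
    expect_true(paste0("b", i, ".se.w1") %in% names(st$params))
  }
})

test_that("misconfigured stride schedules are a construction error", {
  expect_error(stream_config(block_strides = c(1L, 2L, 2L, 2L, 2L, 7L),
                             block_widths = rep(4L, 6)),
               "stride")
  expect_error(stream_config(block_strides = c(1L, 2L), block_widths = c(4L, 4L)),
               "n_blocks")
})

test_that("the bilateral model shares one stream parameter set", {
  cfg <- tiny_stream_config()
  st <- build_stream(cfg, seed = 1)
  mb <- build_bilateral(cfg, seed = 1)
  ms <- build_single_side(cfg, seed = 1)
  # bilateral = one stream + the 3x3 (+3) symmetry grade map
  expect_identical(n_params(mb), n_params(st) + 9L + 3L)
  # single-side = exactly one stream, identical layer structure
  expect_identical(n_params(ms), n_params(st))
  expect_identical(lapply(ms$params, dim), lapply(st$params, dim))
  expect_identical(names(ms$params), names(st$params))
})

test_that("mastoiditis head behaves like softmax over pooled channel logits", {
  set.seed(9)
  fm <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  # identical channels -> uniform probabilities
  fm_eq <- array(rep(fm[, , 1], 3), c(4, 4, 3))
  expect_equal(mastoiditis_head(fm_eq, 5), rep(1 / 3, 3))
  # adding a constant to all channels changes nothing
  expect_equal(mastoiditis_head(fm, 5), mastoiditis_head(fm + 3.7, 5))
  # raising the severe channel raises p(severe), monotonically
  for (i in 1:10) {
    fm2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    fm3 <- fm2; fm3[, , 3] <- fm3[, , 3] + 0.5
    expect_gt(mastoiditis_head(fm3, 5)[3], mastoiditis_head(fm2, 5)[3])
  }
  expect_equal(sum(mastoiditis_head(fm, 5)), 1)
})

test_that("the symmetry evaluation layer is a symmetric absolute difference", {
  set.seed(10)
  a <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  b <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  d <- symmetry_eval(a, b)
  expect_true(all(d >= 0))
  expect_equal(unclass(d), abs(a - b))
  expect_equal(unclass(symmetry_eval(b, a)), unclass(d))
  expect_true(all(symmetry_eval(a, a) == 0))
  expect_error(symmetry_eval(a, array(0, c(2, 2, 3))), "differ")
})

test_that("symmetry head reduces to its bias on a zero difference map", {
  zero <- array(0, c(4, 4, 3))
  sym_w <- matrix(rnorm(9), 3, 3)
  sym_b <- c(0.2, -0.1, 0.5)
  p <- symmetry_head(zero, r = 5, head = "linear", sym_w = sym_w, sym_b = sym_b)
  expect_equal(p, as.vector(exp(sym_b) / sum(exp(sym_b))))
  expect_equal(sum(p), 1)
  # direct head pools the raw channels without parameters
  set.seed(11)
  d <- abs(array(rnorm(4 * 4 * 3), c(4, 4, 3)))
  pd <- symmetry_head(d, r = 5, head = "direct")
  logits <- sapply(1:3, function(g) lse_pool(d[, , g], 5))
  expect_equal(pd, as.vector(exp(logits - max(logits)) /
                               sum(exp(logits - max(logits)))))
})

test_that("swapping the two sides swaps category outputs exactly and fixes symmetry", {
  m <- build_bilateral(tiny_stream_config(), seed = 4)
  set.seed(12)
  pair <- list(right_image = matrix(runif(32 * 32), 32, 32),
               left_image = matrix(runif(32 * 32), 32, 32))
  a <- forward_bilateral(m, pair)
  b <- forward_bilateral(m, list(right_image = pair$left_image,
                                 left_image = pair$right_image))
  expect_identical(a$right_probs, b$left_probs)
  expect_identical(a$left_probs, b$right_probs)
  expect_identical(a$symmetry_probs, b$symmetry_probs)
  # identical halves give identical per-side outputs
  c2 <- forward_bilateral(m, list(right_image = pair$right_image,
                                  left_image = pair$right_image))
  expect_identical(c2$right_probs, c2$left_probs)
  expect_equal(sum(a$right_probs), 1, tolerance = 1e-6)
  expect_equal(sum(a$symmetry_probs), 1, tolerance = 1e-6)
})

test_that("single-side model equals one bilateral stream on the same seed", {
  cfg <- tiny_stream_config()
  ms <- build_single_side(cfg, seed = 21)
  st <- build_stream(cfg, seed = 21)
  expect_identical(ms$params, st$params)
  set.seed(22)
  img <- matrix(runif(32 * 32), 32, 32)
  p <- forward_single(ms, img)
  expect_equal(p, mastoiditis_head(forward_stream(st, img), cfg$lse_r))
  expect_equal(sum(p), 1)
})

test_that("inputs of the wrong shape are rejected", {
  m <- build_single_side(tiny_stream_config(), seed = 1)
  expect_error(forward_single(m, matrix(0, 16, 16)), "shape")
})
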