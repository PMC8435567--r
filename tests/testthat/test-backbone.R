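# Backbone construction, block composition and tap-point geometry.

test_that("block variants carry the right attention module", {
  blk_r <- build_block("resnet", 32L, 8L, cfg = ska_config(), G = 4L, d = 4L)
  expect_null(blk_r$att)
  blk_g <- build_block("sge", 32L, 8L, cfg = ska_config(), G = 4L, d = 4L)
  expect_named(blk_g$att, c("gamma", "beta", "G"))
  blk_k <- build_block("sk", 32L, 8L, cfg = ska_config(), G = 4L, d = 4L)
  expect_null(blk_k$att$sge1)
  blk_a <- build_block("ska", 32L, 8L, cfg = ska_config(), G = 4L, d = 4L)
  expect_false(is.null(blk_a$att$sge1))
  expect_error(build_block("nope", 32L, 8L), "variant")
})

test_that("a block preserves shape and composes bottleneck + attention + shortcut", {
  set.seed(30)
  blk <- build_block("ska", 32L, 8L, stride = 1L, cfg = ska_config(),
                     G = 4L, d = 4L)
  x <- rand_fm(1, 32, 6, 6)
  out <- skanet:::block_fwd(blk, x)
  expect_identical(dim(out$y), dim(x))

  # compositional oracle: bottleneck output fed through the standalone module
  h <- skanet:::conv_fwd(x, blk$conv1$w)
  h <- pmax(skanet:::bn2d_fwd(h, blk$bn1)$y, 0)
  h <- skanet:::conv_fwd(h, blk$conv2$w, stride = 1L, pad = 1L)
  h <- pmax(skanet:::bn2d_fwd(h, blk$bn2)$y, 0)
  h <- skanet:::conv_fwd(h, blk$conv3$w)
  h <- skanet:::bn2d_fwd(h, blk$bn3)$y
  h <- ska_module(h, blk$att)
  expect_equal(out$y, pmax(h + x, 0), tolerance = 1e-12)
})

test_that("stage spatial sizes follow /4 /8 /16 /32 and logits are normalized", {
  set.seed(31)
  spec <- tiny_spec("ska")
  m <- build_model(spec, seed = 1)
  b <- forward_features(m, rand_fm(2, 3, 64, 64))
  expect_identical(dim(b$F3), c(2L, 128L, 4L, 4L))
  expect_identical(dim(b$F4), c(2L, 256L, 2L, 2L))
  expect_equal(length(b$pooled[1, ]), 256L)
  p <- skanet:::softmax_rows(b$logits)
  expect_equal(rowSums(p), c(1, 1))

  # 16 blocks at the 50-layer depth
  spec50 <- net_spec("resnet", num_classes = 10L, width_divisor = 8L)
  m50 <- build_model(spec50, init = "zeros")
  expect_identical(sum(lengths(m50$params$stages)), 16L)
})

test_that("full-width tap points land at 14x14x1024 and 7x7x2048 at input 224", {
  m <- build_model(net_spec("resnet", num_classes = 1000L), init = "zeros",
                   seed = 1)
  # zero kernels give zero maps; shapes are what is under test
  b <- forward_features(m, array(0, c(1, 3, 224, 224)))
  expect_identical(dim(b$F3), c(1L, 1024L, 14L, 14L))
  expect_identical(dim(b$F4), c(1L, 2048L, 7L, 7L))
  b2 <- forward_features(m, array(0, c(1, 3, 112, 112)))
  expect_identical(dim(b2$F3), c(1L, 1024L, 7L, 7L))
  expect_identical(dim(b2$F4), c(1L, 2048L, 4L, 4L))
})

test_that("all four tiny variants run at every ablation input scale", {
  set.seed(32)
  # spatial size divides by 32 exactly when the input does, with ceiling
  # at the odd intermediate sizes otherwise
  for (v in c("resnet", "sge", "sk", "ska")) {
    spec <- net_spec(v, stage_blocks = c(1L, 1L, 1L, 1L), num_classes = 4L,
                     input_size = 64L, width_divisor = 8L)
    m <- build_model(spec, seed = 2)
    for (s in c(112L, 224L)) {
      b <- forward_features(m, array(0.1, c(1, 3, s, s)))
      expect_identical(dim(b$F4)[3], as.integer(ceiling(s / 32)))
    }
  }
  m <- build_model(tiny_spec("ska"), seed = 2)
  for (s in c(336L, 448L))
    expect_identical(dim(forward_features(m, array(0, c(1, 3, s, s)))$F4)[3],
                     as.integer(ceiling(s / 32)))
})

test_that("undersized inputs fail with an explicit message", {
  m <- build_model(tiny_spec("resnet"), seed = 1)
  expect_error(forward_features(m, rand_fm(1, 3, 16, 16)), "too small")
  expect_error(forward_features(m, rand_fm(1, 4, 64, 64)), "RGB")
})

test_that("forward passes are deterministic in eval mode", {
  set.seed(33)
  m <- build_model(tiny_spec("ska"), seed = 4)
  x <- rand_fm(1, 3, 64, 64)
  expect_identical(forward_features(m, x)$logits, forward_features(m, x)$logits)
})

test_that("checkpoints round-trip weights and spec", {
  set.seed(34)
  m <- build_model(tiny_spec("sk"), seed = 5)
  x <- rand_fm(1, 3, 64, 64)
  p <- file.path(tempdir(), "ck.rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  expect_identical(m2$spec$variant, "sk")
  expect_identical(forward_features(m2, x)$logits, forward_features(m, x)$logits)
  p2 <- file.path(tempdir(), "not-a-checkpoint.rds")
  saveRDS(list(a = 1), p2)
  expect_error(load_checkpoint(p2), "not a model checkpoint")
})
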