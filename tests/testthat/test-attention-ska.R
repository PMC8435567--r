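# Selective-kernel attention arithmetic: divide, fuse, enhancement,
# selection, aggregation, and the composed module.

test_that("branch transform preserves shape and applies ReLU(BN(depthwise conv))", {
  set.seed(1)
  C <- 8L
  prm <- list(w = skanet:::he_conv(3L, 3L, 1L, C), bn = skanet:::bn_init(C))
  x <- rand_fm(1, C, 6, 6)
  y <- branch_transform(x, prm)
  expect_identical(dim(y), dim(x))
  expect_true(all(y >= 0))

  # identity depthwise kernel with BN frozen to the identity passes
  # nonnegative inputs through unchanged and clamps negative ones to zero
  idw <- array(0, c(3, 3, 1, C)); idw[2, 2, 1, ] <- 1
  idp <- list(w = idw, bn = skanet:::bn_init(C))
  xp <- abs(x)
  # identity up to the batch-norm eps in 1/sqrt(1 + eps)
  expect_equal(branch_transform(xp, idp), xp, tolerance = 1e-4)
  expect_equal(branch_transform(array(-1, dim(x)), idp), array(0, dim(x)))

  # channel mismatch between input and kernel is a shape error
  expect_error(branch_transform(rand_fm(1, 4, 6, 6), prm), "channel")
})

test_that("fuse descriptor standardizes, is symmetric, and matches hand values", {
  set.seed(2)
  C <- 8L; G <- 4L
  prm <- ska_params(C, G = G, d = G)
  y1 <- rand_fm(2, C, 5, 5); y2 <- rand_fm(2, C, 5, 5)

  # constant maps with all channels equal standardize to the zero vector
  const <- array(3.7, c(2, C, 5, 5))
  f <- fuse_descriptor(const, const, prm)
  expect_equal(max(abs(f$g_std)), 0)

  # symmetry of the summation gate
  fa <- fuse_descriptor(y1, y2, prm)
  fb <- fuse_descriptor(y2, y1, prm)
  expect_equal(fa$g1, fb$g1)

  # two-channel toy: pooled g = (1, 3) standardizes to (-1, 1) under the
  # population std
  p2 <- ska_params(2L, G = 2L, d = 2L)
  h1 <- array(1, c(1, 2, 2, 2)); h1[1, 2, , ] <- 3
  fz <- fuse_descriptor(h1, array(0, dim(h1)), p2)
  expect_equal(as.vector(fz$g), c(1, 3))
  expect_equal(as.vector(fz$g_std), c(-1, 1), tolerance = 1e-4)

  expect_error(fuse_descriptor(y1, rand_fm(2, C, 4, 4), prm), "shape")
})

test_that("group-wise enhancement matches its defining equations", {
  # spatially uniform maps standardize to zero similarity: gate 0.5
  y <- array(2, c(1, 4, 3, 3))
  expect_equal(sge_enhance(y, rep(1, 2), rep(0, 2), G = 2), 0.5 * y)

  # gamma = beta = 0 always gates by sigmoid(0) = 0.5
  set.seed(3)
  y2 <- rand_fm(2, 4, 3, 3)
  expect_equal(sge_enhance(y2, rep(0, 2), rep(0, 2), G = 2), 0.5 * y2)

  # hand evaluation at G = C = 1, spatial values (1, 3)
  y3 <- array(c(1, 3), c(1, 1, 1, 2))
  out <- sge_enhance(y3, 1, 0, G = 1)
  expect_equal(as.vector(out), c(1 / (1 + exp(1)), 3 / (1 + exp(-1))),
               tolerance = 1e-4)

  # brute-force oracle on a random map
  g <- c(0.7, 1.3); b <- c(0.1, -0.2)
  expect_equal(sge_enhance(y2, g, b, G = 2), oracle_sge(y2, g, b, G = 2),
               tolerance = 1e-10)

  expect_error(sge_enhance(y2, g, b, G = 3), "divide")
})

test_that("branch selection weights are a softmax over two logits", {
  # equal logits give (0.5, 0.5); logits (1, 0) give the closed form
  prm <- list(w = matrix(0, 3, 2), b = c(0, 0))
  v <- select_branch_weights(matrix(rnorm(6), 2, 3), prm)
  expect_equal(v, matrix(0.5, 2, 2))
  prm2 <- list(w = matrix(c(1, 0), 1, 2), b = c(0, 0))
  v2 <- select_branch_weights(matrix(1, 1, 1), prm2)
  expect_equal(as.vector(v2), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-7)

  # normalization holds over many random descriptors
  set.seed(4)
  prm3 <- list(w = matrix(rnorm(10), 5, 2), b = rnorm(2))
  g1 <- matrix(rnorm(5000), 1000, 5)
  v3 <- select_branch_weights(g1, prm3)
  expect_lt(max(abs(rowSums(v3) - 1)), 1e-6)
  expect_true(all(v3 > 0 & v3 < 1))
})

test_that("aggregation is the selection-weighted sum of the branches", {
  set.seed(5)
  y1 <- rand_fm(2, 4, 3, 3); y2 <- rand_fm(2, 4, 3, 3)
  # degenerate selection picks one branch
  expect_equal(aggregate_branches(y1, y2, cbind(c(1, 1), c(0, 0))), y1)
  # convex combination of equal branches is the branch itself
  v <- cbind(c(0.3, 0.8), c(0.7, 0.2))
  expect_equal(aggregate_branches(y1, y1, v), y1)
  # scalar hand arithmetic
  a <- array(2, c(1, 1, 1, 1)); b <- array(4, c(1, 1, 1, 1))
  expect_equal(as.vector(aggregate_branches(a, b, cbind(0.25, 0.75))), 3.5)
  expect_error(aggregate_branches(y1, rand_fm(2, 4, 2, 2), v), "shape")
})

test_that("the composed module matches a brute-force evaluation and keeps shape", {
  set.seed(6)
  x <- rand_fm(2, 4, 4, 4)
  for (with_sge in c(TRUE, FALSE)) {
    prm <- ska_params(4L, G = 2L, d = 2L, with_sge = with_sge)
    y <- ska_module(x, prm)
    expect_identical(dim(y), dim(x))
    expect_equal(y, oracle_ska(x, prm), tolerance = 1e-5)
  }

  # shape preservation across randomized shapes, G dividing C
  set.seed(7)
  for (i in 1:5) {
    C <- sample(c(4L, 8L, 16L), 1)
    x2 <- rand_fm(sample(1:3, 1), C, sample(2:6, 1), sample(2:6, 1))
    prm <- ska_params(C, G = 2L, d = 4L)
    expect_identical(dim(ska_module(x2, prm)), dim(x2))
  }

  # with identical branch parameters and equal kernels the output is
  # independent of the selection weights
  cfg5 <- ska_config(kernel_a = 5L, kernel_b = 5L)
  prm <- ska_params(4L, cfg5, G = 2L, d = 2L)
  prm$b2 <- prm$b1
  y1 <- branch_transform(x, prm$b1)
  ref <- sge_enhance(y1, prm$sge1$gamma, prm$sge1$beta, prm$G)
  prm$sge2 <- prm$sge1
  expect_equal(ska_module(x, prm), ref, tolerance = 1e-10)
})

test_that("attention outputs are deterministic given identical inputs", {
  set.seed(8)
  prm <- ska_params(8L, G = 4L, d = 4L)
  x <- rand_fm(2, 8, 5, 5)
  expect_identical(ska_module(x, prm), ska_module(x, prm))
})
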