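# Multi-scale regularizer: KL matching, strategy sets, classification loss
# and the combined objective.

test_that("KL matching reproduces hand-derived values and is asymmetric", {
  pa <- matrix(c(0.75, 0.25), 1)
  pb <- matrix(c(0.5, 0.5), 1)
  expect_equal(kl_match(pa, pb), 0.1308120, tolerance = 1e-6)
  expect_equal(kl_match(pb, pa), 0.1438410, tolerance = 1e-6)
  expect_equal(kl_match(pa, pa), 0)
  expect_error(kl_match(matrix(c(0.9, 0.3), 1), pb), "sum to 1")
})

test_that("KL is nonnegative over random pairs and zero only on equal pairs", {
  set.seed(40)
  for (i in 1:1000) {
    pa <- matrix(rexp(5), 1); pa <- pa / sum(pa)
    pb <- matrix(rexp(5), 1); pb <- pb / sum(pb)
    expect_gte(kl_match(pa, pb), 0)
  }
  # batch form agrees with the per-row brute-force sum
  set.seed(41)
  A <- matrix(rexp(40), 8); A <- A / rowSums(A)
  B <- matrix(rexp(40), 8); B <- B / rowSums(B)
  expect_equal(kl_match(A, B), oracle_kl(A, B), tolerance = 1e-12)
})

test_that("matching loss follows the strategy directions and is additive", {
  set.seed(42)
  mk <- function() { m <- matrix(rexp(12), 3); m / rowSums(m) }
  p3 <- mk(); p4 <- mk(); p <- mk()
  expect_equal(msl_loss(p3, p3, p3), 0)
  expect_equal(msl_loss(p3, p4, p, msl_config("P3+P4")), kl_match(p4, p3))
  expect_equal(msl_loss(p3, p4, p, msl_config("P+P4")), kl_match(p4, p))
  expect_equal(msl_loss(p3, p4, p, msl_config("P3+P")), kl_match(p, p3))
  full <- msl_loss(p3, p4, p)
  expect_equal(full, kl_match(p4, p3) + kl_match(p4, p) + kl_match(p, p3))
  expect_equal(msl_loss(p3, p4, p, msl_config(character(0))), 0)
  # six printed strategy sets: constructible and pairwise distinct
  sets <- msl_strategy_sets()
  expect_length(sets, 6)
  expect_length(unique(lapply(sets, sort)), 6)
  vals <- vapply(sets, function(s) msl_loss(p3, p4, p, msl_config(s)), 0)
  expect_length(unique(round(vals, 12)), 6)
})

test_that("classification loss averages the three heads against one-hot labels", {
  C <- 19L
  onehot <- matrix(0, 1, C); onehot[1, 5] <- 1
  expect_equal(classification_loss(onehot, onehot, onehot, 5L), 0)
  u <- matrix(1 / C, 1, C)
  expect_equal(classification_loss(u, u, u, 3L), log(19), tolerance = 1e-6)
  p3 <- matrix(c(0.9, 0.1), 1); p4 <- matrix(c(0.6, 0.4), 1)
  expect_equal(classification_loss(p3, p4, p4, 1L), -log(0.7), tolerance = 1e-7)
  # brute-force agreement on a random batch
  set.seed(43)
  mk <- function() { m <- matrix(rexp(20), 4); m / rowSums(m) }
  a <- mk(); b <- mk(); c <- mk(); y <- c(1L, 3L, 5L, 2L)
  expect_equal(classification_loss(a, b, c, y), oracle_ce_mean(a, b, c, y),
               tolerance = 1e-12)
  expect_error(classification_loss(a, b, c, c(1L, 2L, 9L, 1L)), "labels")
  # the literal summed form goes negative at confident agreement
  expect_lt(classification_loss(onehot, onehot, onehot, 5L,
                                literal_sum = TRUE), 0)
})

test_that("total loss combines components exactly", {
  expect_equal(total_loss(1.5, 0.25, msl_config(alpha = 1))$total, 1.75)
  expect_equal(total_loss(1.5, 0.25, msl_config(alpha = 0))$total, 1.5)
  expect_equal(total_loss(2.2, 0, msl_config())$total, 2.2)
  cls <- pi / 7; msl <- exp(-2); alpha <- 1
  tl <- total_loss(cls, msl, msl_config(alpha = alpha))
  expect_identical(tl$total, cls + alpha * msl)   # bit-exact
  expect_error(total_loss(NaN, 0, msl_config()), "finite")
})

test_that("head predictions are distributions and match a composed pipeline", {
  set.seed(44)
  m <- build_model(tiny_spec("ska", msl = TRUE), seed = 3)
  b <- forward_features(m, rand_fm(2, 3, 64, 64))
  hp <- head_predictions(b, m$msl)
  for (p in hp) expect_equal(rowSums(p), c(1, 1), tolerance = 1e-9)

  # compositional oracle: cbam -> mean pool -> affine -> softmax
  f3h <- oracle_cbam(b$F3, m$msl$cbam3)
  pooled <- t(apply(f3h, 1, function(a) apply(array(a, dim(f3h)[2:4]), 1, mean)))
  z <- pooled %*% m$msl$fc3$w
  z <- sweep(z, 2, m$msl$fc3$b, `+`)
  e <- exp(z - apply(z, 1, max)); want <- e / rowSums(e)
  expect_equal(hp$P3, want, tolerance = 1e-8)

  # all-zero fc weights give uniform rows
  m$msl$fc3$w[] <- 0; m$msl$fc3$b[] <- 0
  hp2 <- head_predictions(b, m$msl)
  expect_equal(hp2$P3, matrix(0.25, 2, 4))

  # class-count mismatch among heads is an error
  m$msl$fc3$w <- m$msl$fc3$w[, 1:3]
  m$msl$fc3$b <- m$msl$fc3$b[1:3]
  expect_error(head_predictions(b, m$msl), "class count")
})

test_that("msl_config validates its fields", {
  expect_error(msl_config("P5+P"), "subset")
  expect_error(msl_config(alpha = -1), "alpha")
  expect_error(msl_config(epsilon = 0.5), "epsilon")
})
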