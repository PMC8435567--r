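# Training engine: schedule, optimization smoke, evaluation, activation
# maps, ablation drivers.

test_that("the step schedule decays by 10 at half and three-quarters", {
  cfg <- train_config(epochs = 50L)
  expect_equal(lr_at(0, cfg), 0.01)
  expect_equal(lr_at(24, cfg), 0.01)
  expect_equal(lr_at(25, cfg), 0.001)
  expect_equal(lr_at(37, cfg), 1e-4)
  expect_equal(lr_at(40, cfg), 1e-4)
  expect_error(lr_at(50, cfg), "epoch")
  # non-increasing with exactly three plateaus
  lrs <- lr_at(0:49, cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_identical(length(unique(lrs)), 3L)
})

test_that("training descends on a small fine-grained set and is seeded", {
  idx <- tiny_dataset()
  spec <- tiny_spec("ska", msl = TRUE)
  cfg <- train_config(epochs = 3L, batch_size = 8L, input_scale = 64L,
                      seed = 2L)
  log1 <- file.path(tempdir(), "m1.csv")
  r1 <- train_model(spec, idx, cfg, eval_every = 3L, log_csv = log1)
  expect_identical(nrow(r1$history), 3L)
  expect_lt(tail(r1$history$total, 1), r1$history$total[1])
  expect_true(all(c("cls", "msl", "total", "lr") %in% names(r1$history)))
  # identical seed and config reproduce the metric log byte for byte
  log2 <- file.path(tempdir(), "m2.csv")
  r2 <- train_model(spec, idx, cfg, eval_every = 3L, log_csv = log2)
  expect_identical(readLines(log1), readLines(log2))
  expect_identical(r1$history$total, r2$history$total)
})

test_that("the regularizer weight only enters through the msl term", {
  set.seed(60)
  m <- build_model(tiny_spec("ska", msl = TRUE), seed = 6)
  x <- rand_fm(4, 3, 64, 64, sd = 0.5)
  y <- c(1L, 2L, 3L, 4L)
  r1 <- skanet:::train_batch(m, x, y, msl_config(alpha = 1))
  r0 <- skanet:::train_batch(m, x, y, msl_config(alpha = 0))
  expect_equal(r0$cls, r1$cls)
  expect_equal(r0$msl, r1$msl)
  expect_equal(r1$total - r0$total, r1$msl)
})

test_that("evaluation equals a manual tally of argmax predictions", {
  idx <- tiny_dataset()
  m <- build_model(tiny_spec("ska"), seed = 8)
  pp <- preprocess_config(crop = 64L)
  acc <- evaluate_model(m, idx, split = "test", cfg = pp)
  rows <- idx[idx$split == "test", ]
  ncorr <- 0L
  for (i in seq_len(nrow(rows))) {
    x <- skanet:::load_batch(rows[i, , drop = FALSE], attr(idx, "dir"),
                             "eval", pp)
    ncorr <- ncorr + (skanet:::model_predict(m, x)$pred == rows$label[i])
  }
  expect_equal(acc, 100 * ncorr / nrow(rows))
  expect_error(evaluate_model(m, idx[idx$split == "nope", ], cfg = pp), "empty")
})

test_that("activation maps are normalized, scored, and channel-faithful", {
  set.seed(61)
  m <- build_model(tiny_spec("ska"), seed = 12)
  img <- render_instrument("Needle holder", "closed", 40, "day", size = 96,
                           seed = 13)
  pp <- preprocess_config(crop = 64L)
  am <- activation_map(m, img, cfg = pp)
  expect_true(all(am$map >= 0 & am$map <= 1))
  if (!am$degenerate) expect_equal(max(am$map), 1)
  # the reported score is the model's softmax at the target class
  x <- preprocess_image(img, "eval", pp)
  dim(x) <- c(1L, dim(x))
  P <- skanet:::softmax_rows(forward_features(m, x)$logits)
  expect_equal(am$score, P[1, am$class])
  # a head that reads a single channel yields a map proportional to it
  m2 <- m
  m2$params$head$w[] <- 0
  m2$params$head$w[5, 2] <- 1
  am2 <- activation_map(m2, img, target = 2L, cfg = pp)
  f4 <- forward_features(m2, x)$F4[1, 5, , ]
  ref <- pmax(f4, 0); ref <- ref / max(ref)
  up <- skanet:::bilinear_resize_cpp(ref, 64L, 64L)
  expect_equal(am2$map, up / max(up), tolerance = 1e-8)
  # overlay stays a valid image
  ov <- cam_overlay(img, am)
  expect_true(all(ov >= 0 & ov <= 1))
})

test_that("ablation grids enumerate the printed configurations", {
  b <- ablation_grid("batch")
  expect_identical(vapply(b, `[[`, 0L, "batch_size"), c(`16` = 16L, `32` = 32L,
                                                        `64` = 64L, `128` = 128L))
  s <- ablation_grid("scale")
  expect_identical(vapply(s, `[[`, 0L, "input_scale"),
                   c(`112` = 112L, `224` = 224L, `336` = 336L, `448` = 448L))
  expect_length(ablation_grid("strategy"), 6L)
})
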