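# Synthetic instrument dataset: rendering, generation, splitting,
# preprocessing, and the fine-grained difficulty structure.

test_that("rendering is deterministic and validates its pose", {
  a <- render_instrument("Alice forceps", "open", 45, "day", size = 96, seed = 3)
  b <- render_instrument("Alice forceps", "open", 45, "day", size = 96, seed = 3)
  expect_identical(a, b)
  expect_error(render_instrument("Alice forceps", "open", 120, "day", size = 64),
               "angle")
  expect_error(render_instrument("no such tool", size = 64), "unknown class")
  # stateless classes coerce the state
  img <- render_instrument("Attraction tube", "open", 40, "day", size = 64)
  expect_identical(attr(img, "pose")$state, "none")
})

test_that("the background emulates a near-black light-absorbing cloth", {
  for (lt in c("day", "night")) {
    img <- render_instrument("S deep pull hook", "closed", 50, lt,
                             size = 128, seed = 9)
    # tool pixels are bright; estimate the background as the darkest 60%
    lum <- apply(img, c(1, 2), mean)
    bgmean <- mean(sort(as.vector(lum))[1:round(0.6 * length(lum))])
    expect_lt(bgmean, 0.10)
  }
})

test_that("fine-grained partners differ only around the fore-end", {
  for (pair in list(c("Alice forceps", "Appendix forceps"),
                    c("Curved tip surgical scissors",
                      "Straight tip surgical scissors"))) {
    a <- render_instrument(pair[1], "closed", 45, "day", size = 128, seed = 77)
    b <- render_instrument(pair[2], "closed", 45, "day", size = 128, seed = 77)
    outside <- !(skanet:::tip_region_mask(a) | skanet:::tip_region_mask(b))
    same <- a[, , 1][outside] == b[, , 1][outside]
    expect_gte(mean(same), 0.99)
    # and they do differ inside the tip region
    expect_gt(max(abs(a - b)), 0.1)
  }
})

test_that("generated trees match the manifest counts and are seeded", {
  man <- sid_manifest(per_class = 3L, image_size = 48L, seed = 21L,
                      classes = sid_class_specs()[1:5])
  d1 <- file.path(tempdir(), "gen-a"); d2 <- file.path(tempdir(), "gen-b")
  i1 <- generate_dataset(man, d1, overwrite = TRUE)
  i2 <- generate_dataset(man, d2, overwrite = TRUE)
  expect_identical(nrow(i1), 15L)
  expect_identical(unname(lengths(split(i1$path, i1$class))), rep(3L, 5))
  expect_identical(length(list.files(d1, pattern = "[.]png$", recursive = TRUE)),
                   15L)
  # identical seed, identical index bytes
  expect_identical(readLines(file.path(d1, "index.csv")),
                   readLines(file.path(d2, "index.csv")))
  expect_error(generate_dataset(man, d1), "overwrite")
  # images decode as RGB and paths resolve
  img <- png::readPNG(file.path(d1, i1$path[1]))
  expect_identical(dim(img), c(48L, 48L, 3L))
  # round-trip through the on-disk index
  i3 <- read_dataset_index(d1)
  expect_identical(i3$path, i1$path)
  expect_identical(attr(i3, "manifest")$per_class, 3L)
})

test_that("file counts follow per-class counts for arbitrary manifests", {
  set.seed(50)
  for (i in 1:3) {
    k <- sample(2:5, 1); pc <- sample(2:4, 1)
    man <- sid_manifest(per_class = pc, image_size = 32L, seed = i,
                        classes = sid_class_specs()[sample(19, k)])
    idx <- generate_dataset(man, tempfile("gen"))
    expect_identical(nrow(idx), as.integer(k * pc))
  }
})

test_that("stratified splitting honors the 3:2 protocol ratio", {
  idx <- data.frame(path = sprintf("f%03d", 1:600),
                    class = rep(c("a", "b", "c"), each = 200),
                    label = rep(1:3, each = 200))
  sp <- split_train_test(idx, c(3, 2), seed = 4)
  tab <- table(sp$class, sp$split)
  expect_true(all(tab[, "train"] == 120L))
  expect_true(all(tab[, "test"] == 80L))
  # disjoint and exhaustive by construction; same seed reproduces
  sp2 <- split_train_test(idx, c(3, 2), seed = 4)
  expect_identical(sp$split, sp2$split)
  expect_false(identical(sp$split, split_train_test(idx, c(3, 2), seed = 5)$split))
  # ratio within rounding for every class size 2..200
  for (n in c(2L, 3L, 7L, 50L, 199L)) {
    one <- data.frame(path = as.character(1:n), class = "z", label = 1L)
    s <- split_train_test(one, c(3, 2), seed = 1)
    expect_identical(sum(s$split == "train"), as.integer(ceiling(n * 3 / 5)))
  }
  expect_error(split_train_test(idx[1, , drop = FALSE], c(3, 2), 1), "fewer")
})

test_that("preprocessing produces normalized crops of the requested scale", {
  set.seed(51)
  img <- render_instrument("Oval forceps", "open", 40, "day", size = 96, seed = 5)
  out <- preprocess_image(img, "eval")
  expect_identical(dim(out), c(3L, 224L, 224L))
  # deterministic in eval mode
  expect_identical(out, preprocess_image(img, "eval"))
  # constant image with matching stats normalizes to zero
  flat <- array(0.4, c(50, 50, 3))
  z <- preprocess_image(flat, "eval",
                        preprocess_config(crop = 32L, mean = rep(0.4, 3),
                                          sd = rep(1, 3)))
  expect_equal(max(abs(z)), 0)
  # scale ablation sizes all work
  for (s in c(112L, 224L, 336L, 448L))
    expect_identical(dim(preprocess_image(img, "eval",
                                          preprocess_config(crop = s)))[2], s)
  expect_error(preprocess_image(array(0, c(10, 10)), "eval"), "RGB")
  # train mode is seeded-random but shape-stable
  set.seed(52)
  t1 <- preprocess_image(img, "train", preprocess_config(crop = 64L))
  expect_identical(dim(t1), c(3L, 64L, 64L))
})

test_that("channel statistics are recorded and recomputable", {
  idx <- tiny_dataset()
  man <- attr(idx, "manifest")
  expect_length(man$channel_mean, 3)
  cs <- channel_stats(idx, split = "train", max_images = 10)
  expect_true(all(cs$mean > 0 & cs$mean < 0.6))
  expect_true(all(cs$sd > 0))
})

test_that("the coarse pair separates better than the matched fine pair", {
  probe <- function(n1, n2, n = 50, size = 96) {
    imgs <- function(nm) do.call(rbind, lapply(1:n, function(i) {
      v <- as.vector(render_instrument(nm, state = "closed",
        angle = 30 + (i * 7) %% 31, lighting = "day", size = size,
        rotation = 0, seed = 1000 + i))
      (v - mean(v)) / sd(v)
    }))
    A <- imgs(n1); B <- imgs(n2)
    trn <- 1:30; tst <- 31:50
    ca <- colMeans(A[trn, ]); cb <- colMeans(B[trn, ])
    pa <- mean(colSums((t(A[tst, ]) - ca)^2) < colSums((t(A[tst, ]) - cb)^2))
    pb <- mean(colSums((t(B[tst, ]) - cb)^2) < colSums((t(B[tst, ]) - ca)^2))
    (pa + pb) / 2
  }
  coarse <- probe("Alice forceps", "Tissue tweezers")
  fine <- probe("Alice forceps", "Appendix forceps")
  expect_gt(coarse, fine)
  expect_gt(coarse, 0.5)
})
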