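# Image preprocessing: resize, random-resized-crop (train) or center crop
# (eval), optional horizontal/vertical flips, per-channel mean/std
# normalization. Output is a (3, crop, crop) array ready for batching.

#' Preprocessing configuration
#'
#' @param crop network input side (the scale ablation uses 112/224/336/448).
#' @param scale pre-crop resize side; default `round(crop * 8 / 7)`
#'   (256 for a 224 crop).
#' @param mean,sd per-channel normalization statistics. Defaults are the
#'   widely used natural-image values; for generated datasets pass the
#'   manifest's `channel_mean` / `channel_sd`.
#' @param flip apply random horizontal and vertical flips in training mode.
#' @param min_area lower bound of the random-resized-crop area fraction.
#' @param tta apply random crop and flips at evaluation time too (the
#'   photographic protocol's test-time augmentation); default is a
#'   deterministic center crop.
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(crop = 224L, scale = as.integer(round(crop * 8 / 7)),
                              mean = c(0.485, 0.456, 0.406),
                              sd = c(0.229, 0.224, 0.225),
                              flip = TRUE, tta = FALSE, min_area = 0.5) {
  structure(list(crop = as.integer(crop), scale = as.integer(scale),
                 mean = mean, sd = sd, flip = flip, tta = tta,
                 min_area = min_area),
            class = "preprocess_config")
}

#' Preprocess one image
#'
#' @param img (H, W, 3) RGB array in [0, 1].
#' @param mode `"train"` (random resized crop + flips) or `"eval"`
#'   (deterministic resize + center crop unless `cfg$tta`).
#' @param cfg a [preprocess_config()].
#' @return (3, crop, crop) normalized array.
#' @export
preprocess_image <- function(img, mode = c("eval", "train"),
                             cfg = preprocess_config()) {
  mode <- match.arg(mode)
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stop("expected an (H, W, 3) RGB image")
  img <- bilinear_resize_cpp(img, cfg$scale, cfg$scale)
  S <- cfg$scale; cp <- cfg$crop
  augment <- mode == "train" || isTRUE(cfg$tta)
  if (augment) {
    # random resized crop: area in [min_area, 1], aspect in [3/4, 4/3]
    for (try in 1:10) {
      a <- runif(1, cfg$min_area, 1) * S * S
      ar <- exp(runif(1, log(3 / 4), log(4 / 3)))
      ch <- round(sqrt(a / ar)); cw <- round(sqrt(a * ar))
      if (ch <= S && cw <= S && ch >= 8 && cw >= 8) break
      ch <- cw <- S
    }
    y0 <- sample.int(S - ch + 1L, 1L); x0 <- sample.int(S - cw + 1L, 1L)
    patch <- img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), , drop = FALSE]
    out <- bilinear_resize_cpp(patch, cp, cp)
    if (isTRUE(cfg$flip)) {
      if (runif(1) < 0.5) out <- out[, cp:1, , drop = FALSE]
      if (runif(1) < 0.5) out <- out[cp:1, , , drop = FALSE]
    }
  } else {
    off <- (S - cp) %/% 2L
    out <- img[(off + 1L):(off + cp), (off + 1L):(off + cp), , drop = FALSE]
  }
  for (ch in 1:3) out[, , ch] <- (out[, , ch] - cfg$mean[ch]) / cfg$sd[ch]
  aperm(out, c(3L, 1L, 2L))
}

# Load and preprocess a batch of index rows into an (N, 3, S, S) array.
load_batch <- function(rows, dir, mode, cfg) {
  N <- nrow(rows)
  x <- array(0, c(N, 3L, cfg$crop, cfg$crop))
  for (i in seq_len(N)) {
    img <- png::readPNG(file.path(dir, rows$path[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    x[i, , , ] <- preprocess_image(img, mode, cfg)
  }
  x
}
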