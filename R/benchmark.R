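# The desk-scale fine-grained learning benchmark: fixed conditions shared by
# the package's tests and its acceptance script.

#' Manifest of the four-class fine-grained benchmark
#'
#' The two hardest partner pairs — Alice vs appendix forceps and curved- vs
#' straight-tip scissors — at 200 images per class.
#'
#' @param per_class images per class.
#' @param image_size render resolution.
#' @param seed manifest seed.
#' @return a [sid_manifest()] over the four classes.
#' @export
fine_grained_manifest <- function(per_class = 200L, image_size = 128L,
                                  seed = 11L) {
  sid_manifest(per_class = per_class, image_size = image_size, seed = seed,
               classes = sid_class_specs()[c(
                 "Alice forceps", "Appendix forceps",
                 "Curved tip surgical scissors",
                 "Straight tip surgical scissors")])
}

#' Train one desk-scale model on the fine-grained benchmark
#'
#' Fixed conditions: one block per stage, width divisor 8, 64-px input,
#' SGD lr 0.05 / batch 16 / 10 epochs, crop-area >= 0.8, no flips,
#' per-dataset channel statistics. Only the variant and the seed vary.
#'
#' @param variant backbone variant, usually `"ska"` or `"resnet"`.
#' @param index split dataset index from [fine_grained_manifest()] data.
#' @param seed training seed.
#' @param epochs training epochs.
#' @param dir dataset directory.
#' @return final test top-1 accuracy (percent).
#' @export
learning_benchmark <- function(variant, index, seed = 1L, epochs = 10L,
                               dir = attr(index, "dir")) {
  man <- attr(index, "manifest")
  pp <- preprocess_config(crop = 64L, mean = man$channel_mean,
                          sd = man$channel_sd, min_area = 0.8, flip = FALSE)
  spec <- net_spec(variant, stage_blocks = c(1L, 1L, 1L, 1L),
                   num_classes = 4L, input_size = 64L, width_divisor = 8L)
  cfg <- train_config(epochs = epochs, batch_size = 16L, base_lr = 0.05,
                      input_scale = 64L, seed = seed)
  r <- train_model(spec, index, cfg, dir = dir, pp = pp, eval_every = epochs)
  tail(r$history$test_top1[!is.na(r$history$test_top1)], 1)
}
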