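# Shared fixtures: tiny desk-scale networks and small generated datasets.

rand_fm <- function(n, c, h, w, sd = 1) array(rnorm(n * c * h * w, sd = sd),
                                              c(n, c, h, w))

tiny_spec <- function(variant = "ska", num_classes = 4L, msl = FALSE) {
  net_spec(variant, stage_blocks = c(1L, 1L, 1L, 1L), num_classes = num_classes,
           input_size = 64L, width_divisor = 8L, msl = msl)
}

# four-class fine-grained subset: two partner pairs differing only at the tips
fine_grained_classes <- function() {
  sid_class_specs()[c("Alice forceps", "Appendix forceps",
                      "Curved tip surgical scissors",
                      "Straight tip surgical scissors")]
}

# small on-disk dataset reused across engine tests (built once per run)
tiny_dataset <- local({
  cache <- NULL
  function(per_class = 6L, image_size = 96L) {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "skanet-tiny-ds")
    man <- sid_manifest(per_class = per_class, image_size = image_size,
                        seed = 404L, classes = fine_grained_classes())
    idx <- generate_dataset(man, dir, overwrite = TRUE)
    idx <- split_train_test(idx, c(3, 2), seed = 5L)
    attr(idx, "dir") <- dir
    cache <<- idx
    idx
  }
})
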