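# Dataset manifest, generation, reading and stratified splitting. The
# default manifest mirrors the collection protocol being emulated: 19 named
# classes, 200 images per class, open/closed states where applicable, side
# views between 30 and 60 degrees, day / night-with-lamp lighting, on a
# near-black cloth. Any conforming class-per-directory tree with the same
# index format can be read back, so a real photographic dataset drops in
# unchanged.

#' Dataset manifest
#'
#' @param per_class images per class (protocol default 200).
#' @param image_size square image side in pixels. The default 512 keeps
#'   desk-scale I/O light; the native capture resolution (3456) is available
#'   by flag.
#' @param seed master RNG seed; every image derives its own stream from it.
#' @param classes class specifications, see [sid_class_specs()].
#' @param angle_range side-view angle range in degrees.
#' @param rotation_range planar rotation range in degrees (the workbench
#'   protocol lays tools out roughly aligned; widen to `c(0, 360)` for
#'   free rotation).
#' @param lighting available lighting modes.
#' @return object of class `sid_manifest`.
#' @export
sid_manifest <- function(per_class = 200L, image_size = 512L, seed = 20240501L,
                         classes = sid_class_specs(),
                         angle_range = c(30, 60),
                         rotation_range = c(-35, 35),
                         lighting = c("day", "night")) {
  if (per_class < 1L) stop("per_class must be >= 1")
  canonical <- names(sid_class_specs())
  if (length(classes) == 0L || !all(names(classes) %in% canonical))
    stop("classes must be a non-empty subset of the 19 protocol classes")
  if (angle_range[1] < 0 || angle_range[2] > 90 || diff(angle_range) < 0)
    stop("angle range must lie within [0, 90] degrees")
  structure(list(per_class = as.integer(per_class),
                 image_size = as.integer(image_size),
                 seed = as.integer(seed), classes = classes,
                 angle_range = angle_range, rotation_range = rotation_range,
                 lighting = lighting),
            class = "sid_manifest")
}

class_slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Generate a synthetic instrument dataset
#'
#' Renders `per_class` images for each of the 19 classes into a
#' class-per-directory PNG tree, writes a JSON copy of the manifest
#' (including per-channel intensity statistics of the generated images) and
#' a CSV index of (path, class, label, state, angle, lighting).
#'
#' @param manifest a [sid_manifest()].
#' @param out_dir output directory (created if missing).
#' @param overwrite allow regeneration over an existing index.
#' @return the dataset index as a data frame (invisible manifest attached as
#'   attribute `manifest`).
#' @export
generate_dataset <- function(manifest, out_dir, overwrite = FALSE) {
  stopifnot(inherits(manifest, "sid_manifest"))
  idx_path <- file.path(out_dir, "index.csv")
  if (file.exists(idx_path) && !overwrite)
    stop("an index already exists in ", out_dir, "; use overwrite = TRUE")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  specs <- manifest$classes
  rows <- vector("list", length(specs) * manifest$per_class)
  csum <- c(0, 0, 0); csum2 <- c(0, 0, 0); npix <- 0
  k <- 0L
  for (ci in seq_along(specs)) {
    sp <- specs[[ci]]
    cdir <- file.path(out_dir, class_slug(sp$name))
    dir.create(cdir, showWarnings = FALSE)
    for (j in seq_len(manifest$per_class)) {
      k <- k + 1L
      img_seed <- (manifest$seed %% 1000003L) * 2011L + ci * 7919L + j
      set.seed(img_seed)
      state <- if (identical(sp$states, "none")) "none"
               else sample(c("open", "closed"), 1L)
      angle <- runif(1, manifest$angle_range[1], manifest$angle_range[2])
      light <- sample(manifest$lighting, 1L)
      img <- render_instrument(sp, state, angle, light,
                               size = manifest$image_size,
                               rotation_range = manifest$rotation_range)
      rel <- file.path(class_slug(sp$name), sprintf("img_%04d.png", j))
      png::writePNG(img, file.path(out_dir, rel))
      if (j %% 20L == 1L) {           # subsample for channel statistics
        csum <- csum + apply(img, 3, sum)
        csum2 <- csum2 + apply(img, 3, function(m) sum(m * m))
        npix <- npix + prod(dim(img)[1:2])
      }
      rows[[k]] <- data.frame(path = rel, class = sp$name, label = ci,
                              state = state, angle = round(angle, 3),
                              rotation = round(attr(img, "pose")$rotation, 3),
                              lighting = light, stringsAsFactors = FALSE)
    }
  }
  index <- do.call(rbind, rows)
  mu <- csum / npix
  sd_ <- sqrt(pmax(csum2 / npix - mu^2, 1e-8))
  man_out <- list(per_class = manifest$per_class,
                  image_size = manifest$image_size, seed = manifest$seed,
                  classes = vapply(specs, `[[`, "", "name"),
                  angle_range = manifest$angle_range,
                  rotation_range = manifest$rotation_range,
                  lighting = manifest$lighting,
                  channel_mean = round(mu, 6), channel_sd = round(sd_, 6))
  jsonlite::write_json(man_out, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(index, idx_path, row.names = FALSE)
  attr(index, "manifest") <- man_out
  attr(index, "dir") <- out_dir
  invisible(index)
}

#' Read a dataset index from disk
#'
#' @param dir directory holding `index.csv` (and optionally
#'   `manifest.json`) as written by [generate_dataset()].
#' @return the index data frame with `manifest` / `dir` attributes.
#' @export
read_dataset_index <- function(dir) {
  idx_path <- file.path(dir, "index.csv")
  if (!file.exists(idx_path)) stop("no index.csv under ", dir)
  index <- read.csv(idx_path, stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.json")
  if (file.exists(mpath))
    attr(index, "manifest") <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  attr(index, "dir") <- dir
  index
}

#' Stratified train/test split
#'
#' Splits the index per class at the given ratio (3:2 by default), rounding
#' toward the training side, with a seeded reproducible assignment.
#'
#' @param index dataset index data frame.
#' @param ratio length-2 train:test ratio.
#' @param seed RNG seed for the assignment.
#' @return the index with a `split` column (`"train"` / `"test"`).
#' @export
split_train_test <- function(index, ratio = c(3, 2), seed = 1L) {
  if (length(ratio) != 2L || any(ratio <= 0)) stop("ratio must be two positives")
  set.seed(seed)
  index$split <- NA_character_
  for (cl in unique(index$class)) {
    rows <- which(index$class == cl)
    n <- length(rows)
    if (n < 2L) stop(sprintf("class '%s' has fewer than 2 images", cl))
    ntr <- ceiling(n * ratio[1] / sum(ratio))
    tr <- sample(rows, ntr)
    index$split[tr] <- "train"
    index$split[setdiff(rows, tr)] <- "test"
  }
  index
}

#' Per-channel intensity statistics of a dataset split
#'
#' @param index dataset index with a `dir` attribute (or pass `dir`).
#' @param split which split to use; `NULL` for all rows.
#' @param dir dataset directory.
#' @param max_images cap on images read (evenly subsampled).
#' @return list with `mean` and `sd`, each length 3.
#' @export
channel_stats <- function(index, split = "train", dir = attr(index, "dir"),
                          max_images = 100L) {
  rows <- if (is.null(split)) index else index[index$split == split, ]
  if (nrow(rows) > max_images)
    rows <- rows[round(seq(1, nrow(rows), length.out = max_images)), ]
  s <- c(0, 0, 0); s2 <- c(0, 0, 0); npx <- 0
  for (p in rows$path) {
    img <- png::readPNG(file.path(dir, p))
    s <- s + apply(img, 3, sum)
    s2 <- s2 + apply(img, 3, function(m) sum(m * m))
    npx <- npx + prod(dim(img)[1:2])
  }
  mu <- s / npx
  list(mean = mu, sd = sqrt(pmax(s2 / npx - mu^2, 1e-8)))
}
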