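# Silhouette renderer: capsule distance field -> antialiased mask ->
# metallic shading with a specular streak, composited over a near-black
# textured cloth background, under two lighting modes. All randomness flows
# through R's RNG so a fixed seed reproduces images byte for byte.

#' Render one synthetic instrument image
#'
#' Draws the parametric silhouette of an instrument class in a random pose:
#' planar rotation, slight scale/translation jitter, and side-view
#' foreshortening for the given angle. The background emulates a black
#' light-absorbing cloth (mean intensity well below 10% of full scale);
#' `lighting = "night"` adds a lamp spot with a stronger specular streak.
#'
#' @param spec a class name from [sid_class_specs()] or one of its entries.
#' @param state `"open"` / `"closed"` for articulated classes, `"none"`
#'   otherwise.
#' @param angle side-view angle in degrees, within [0, 90].
#' @param lighting `"day"` or `"night"`.
#' @param size square image side in pixels.
#' @param rotation planar rotation in degrees; drawn uniformly from
#'   `rotation_range` if `NULL`.
#' @param rotation_range rotation range sampled for the workbench pose.
#' @param seed optional RNG seed; if `NULL` the current RNG stream is used.
#' @return (size, size, 3) RGB array in [0, 1], with attributes `tip_bbox`
#'   (pixel rectangle of the fore-end region) and `pose`.
#' @export
render_instrument <- function(spec, state = "closed", angle = 45,
                              lighting = c("day", "night"), size = 512L,
                              rotation = NULL, rotation_range = c(-35, 35),
                              seed = NULL) {
  lighting <- match.arg(lighting)
  if (is.character(spec)) {
    specs <- sid_class_specs()
    if (!spec %in% names(specs)) stop(sprintf("unknown class '%s'", spec))
    spec <- specs[[spec]]
  }
  if (identical(spec$states, "none")) state <- "none"
  if (!state %in% spec$states)
    stop(sprintf("state '%s' not applicable to class '%s'", state, spec$name))
  if (!is.finite(angle) || angle < 0 || angle > 90)
    stop("side-view angle must lie in [0, 90] degrees")
  if (!is.null(seed)) set.seed(seed)
  size <- as.integer(size)

  # pose draws (identical draw sequence for every class, so fine-grained
  # partners rendered with the same seed share pose and noise exactly)
  theta <- if (is.null(rotation)) runif(1, rotation_range[1], rotation_range[2])
           else rotation
  sc <- runif(1, 0.92, 1.10)
  tx <- runif(1, -0.04, 0.04); ty <- runif(1, -0.04, 0.04)
  lamp <- runif(2, 0.35, 0.65)
  fr <- runif(2, 1.5, 5.5); ph <- runif(2, 0, 2 * pi)
  # low-frequency grain, upsampled: cloth weave and brushed-metal mottle are
  # smooth at pixel scale, and smooth bytes keep the PNGs small and fast
  ng <- max(16L, size %/% 10L)
  noise <- bilinear_resize_cpp(matrix(runif(ng * ng, -1, 1), ng, ng),
                               size, size)

  fshort <- cos(angle * pi / 180)
  th <- theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  segs <- instrument_skeleton(spec, state)
  tf <- function(x, y) {
    p <- cbind((x - 0.5) * sc, (y - 0.5) * sc * fshort) %*% t(R)
    cbind((p[, 1] + 0.5 + tx) * size, (p[, 2] + 0.5 + ty) * size)
  }
  a <- tf(segs[, 1], segs[, 2]); b <- tf(segs[, 3], segs[, 4])
  wsc <- size * sc * (1 + fshort) / 2
  px <- cbind(a, b, segs[, 5] * wsc, segs[, 6] * wsc)
  field <- capsule_field_cpp(px, size, size)
  alpha <- pmin(pmax(0.5 - field / 1.5, 0), 1)

  # pixel grid in tool coordinates for shading
  xs <- (seq_len(size) - 0.5) / size - (0.5 + tx)
  ys <- (seq_len(size) - 0.5) / size - (0.5 + ty)
  Xg <- matrix(xs, size, size, byrow = TRUE)
  Yg <- matrix(ys, size, size)
  tl <- Xg * R[1, 1] + Yg * R[1, 2]          # along-axis coordinate
  cr <- Xg * R[2, 1] + Yg * R[2, 2]          # cross-axis coordinate
  spec_w <- if (lighting == "night") 0.022 else 0.035
  spec_a <- if (lighting == "night") 0.40 else 0.22
  tool <- 0.50 + 0.10 * tl / sc + spec_a * exp(-(cr / spec_w)^2) + 0.045 * noise
  bg0 <- if (lighting == "night") 0.028 else 0.045
  # cloth weave and lamp falloff are low-frequency: evaluate on a quarter-
  # resolution grid and upsample
  sg <- max(16L, size %/% 4L)
  xc <- (seq_len(sg) - 0.5) / sg - (0.5 + tx)
  yc <- (seq_len(sg) - 0.5) / sg - (0.5 + ty)
  Xc <- matrix(xc, sg, sg, byrow = TRUE)
  Yc <- matrix(yc, sg, sg)
  texc <- sin(2 * pi * (fr[1] * Xc + fr[2] * Yc) + ph[1]) *
    cos(2 * pi * (fr[2] * Xc - fr[1] * Yc) + ph[2])
  tex <- bilinear_resize_cpp(texc, size, size)
  bg <- bg0 * (1 + 0.28 * tex) + 0.010 * noise
  if (lighting == "night") {
    r2 <- (Xc + 0.5 + tx - lamp[1])^2 + (Yc + 0.5 + ty - lamp[2])^2
    lampf <- bilinear_resize_cpp(0.72 + 0.55 * exp(-r2 / 0.24), size, size)
    tool <- tool * lampf
    bg <- bg * lampf
  }
  tool <- pmin(pmax(tool, 0), 1)
  bg <- pmin(pmax(bg, 0), 1)
  img <- array(0, c(size, size, 3L))
  tint_t <- c(0.96, 0.985, 1.00)
  tint_b <- c(1.00, 0.97, 0.94)
  for (ch in 1:3)
    img[, , ch] <- pmin(alpha * tool * tint_t[ch] + (1 - alpha) * bg * tint_b[ch], 1)
  # 128 intensity levels: the images are 8-bit photographs in spirit, and the
  # coarser step keeps the PNG stream compact
  img <- round(img * 127) / 127

  bb <- attr(segs, "tip_bbox")
  corners <- tf(bb[c(1, 2, 1, 2)], bb[c(3, 3, 4, 4)])
  margin <- 0.02 * size
  attr(img, "tip_bbox") <- c(xmin = max(1, floor(min(corners[, 1]) - margin)),
                             xmax = min(size, ceiling(max(corners[, 1]) + margin)),
                             ymin = max(1, floor(min(corners[, 2]) - margin)),
                             ymax = min(size, ceiling(max(corners[, 2]) + margin)))
  attr(img, "pose") <- list(state = state, angle = angle, lighting = lighting,
                            rotation = theta)
  img
}

# mask of pixels inside the tip bounding box of a rendered image
tip_region_mask <- function(img) {
  bb <- attr(img, "tip_bbox")
  m <- matrix(FALSE, dim(img)[1], dim(img)[2])
  # bbox is in (x = column, y = row) pixel coordinates
  m[bb["ymin"]:bb["ymax"], bb["xmin"]:bb["xmax"]] <- TRUE
  m
}
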