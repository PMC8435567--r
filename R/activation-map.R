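# Gradient-weighted class activation maps on the last convolutional outputs.

#' Class-discriminative activation map
#'
#' Gradient-weighted combination of the last convolutional feature maps for
#' a target class: channel weights are the spatial means of the target
#' logit's gradient at the stage-4 output, the weighted sum is rectified,
#' bilinearly upsampled to the input size and normalized to max 1.
#'
#' @param model a model from [build_model()] or [train_model()].
#' @param img either a raw (H, W, 3) image in [0, 1] or a preprocessed
#'   (3, S, S) array.
#' @param target 1-based class index; defaults to the predicted class.
#' @param cfg a [preprocess_config()] used when `img` is raw.
#' @return object of class `activation_map`: list with `map` (S x S in
#'   [0, 1]), `score` (softmax probability of the target class), `class`,
#'   and `degenerate` (TRUE when the rectified map was all zero).
#' @export
activation_map <- function(model, img, target = NULL,
                           cfg = preprocess_config()) {
  d <- dim(img)
  x <- if (length(d) == 3L && d[1] == 3L) img
       else preprocess_image(img, "eval", cfg)
  S <- dim(x)[2]
  dim(x) <- c(1L, 3L, dim(x)[2], dim(x)[3])
  fwd <- backbone_fwd(model, x, training = FALSE)
  P <- softmax_rows(fwd$logits)
  if (is.null(target)) target <- which.max(P[1, ])
  # d logit_target / d F4 = w[c, target] / (H*W): spatially constant, so the
  # gradient-weighted channel combination reduces to a closed form
  d4 <- dim(fwd$F4); C <- d4[2]; HW <- d4[3] * d4[4]
  alpha <- model$params$head$w[, target] / HW
  fm <- t(matrix(fwd$F4[1, , , ], C, HW))          # HW x C
  cam <- pmax(fm %*% alpha, 0)
  degenerate <- max(cam) <= 0
  camm <- matrix(cam, d4[3], d4[4])
  up <- bilinear_resize_cpp(camm, S, S)
  if (!degenerate) up <- up / max(up)
  up[up < 0] <- 0
  structure(list(map = up, score = P[1, target], class = target,
                 degenerate = degenerate),
            class = "activation_map")
}

#' Overlay an activation map on its image
#'
#' @param img (H, W, 3) RGB array in [0, 1].
#' @param am an [activation_map()] result (or a matrix in [0, 1]).
#' @param alpha blend weight of the heat map.
#' @return (H, W, 3) RGB array.
#' @export
cam_overlay <- function(img, am, alpha = 0.45) {
  map <- if (inherits(am, "activation_map")) am$map else am
  if (!all(dim(map) == dim(img)[1:2]))
    map <- bilinear_resize_cpp(map, dim(img)[1], dim(img)[2])
  heat <- array(0, dim(img))
  heat[, , 1] <- pmin(1, 1.6 * map)
  heat[, , 2] <- pmax(0, 1.6 * (map - 0.4))
  heat[, , 3] <- pmax(0, 0.6 - map)
  pmin(1, (1 - alpha) * img + alpha * heat)
}
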