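# Residual backbone family: ResNet-50 and its attention variants (SGE, SK,
# SKA), built from bottleneck blocks whose residual-path output optionally
# passes through an attention module before the shortcut addition.

#' Network specification
#'
#' Describes one of the four backbone variants: a 7x7/stride-2 stem with 3x3
#' max pooling, four bottleneck stages, global average pooling and a linear
#' classification head. `width_divisor` scales every channel width (and the
#' attention cardinality) down proportionally for desk-scale models.
#'
#' @param variant `"resnet"` (plain bottlenecks), `"sge"` (group-wise
#'   enhancement at block end), `"sk"` (selective kernel without SGE) or
#'   `"ska"` (selective kernel with per-branch SGE).
#' @param stage_blocks number of blocks per stage; `c(3, 4, 6, 3)` gives the
#'   50-layer architecture.
#' @param num_classes classifier width.
#' @param input_size nominal square input size (must survive five stride-2
#'   reductions).
#' @param width_divisor integer >= 1; divides all channel widths.
#' @param msl attach the multi-scale auxiliary heads (CBAM + fc on the
#'   stage-3 and stage-4 outputs) used by the KL prediction-matching
#'   regularizer.
#' @param strategies KL matching strategy set, see [msl_config()].
#' @param alpha weight of the matching regularizer in the total loss.
#' @param cfg an [ska_config()].
#' @return an object of class `net_spec`.
#' @export
net_spec <- function(variant = c("ska", "resnet", "sge", "sk"),
                     stage_blocks = c(3L, 4L, 6L, 3L), num_classes = 1000L,
                     input_size = 224L, width_divisor = 1L, msl = FALSE,
                     strategies = c("P3+P4", "P+P4", "P3+P"), alpha = 1,
                     cfg = ska_config()) {
  variant <- match.arg(variant)
  if (length(stage_blocks) != 4L || any(stage_blocks < 1L))
    stop("stage_blocks must be four positive block counts")
  wd <- as.integer(width_divisor)
  if (wd < 1L) stop("width_divisor must be >= 1")
  stem_ch <- 64L %/% wd
  mids <- c(64L, 128L, 256L, 512L) %/% wd
  if (stem_ch < 1L || any(mids < 1L)) stop("width_divisor too large")
  G <- max(1L, cfg$groups_G %/% wd)
  d <- max(1L, cfg$d_min %/% wd)
  if (variant != "resnet" && any((mids * 4L) %% G != 0L))
    stop("expanded channel widths must be divisible by the attention cardinality")
  structure(list(variant = variant, stage_blocks = as.integer(stage_blocks),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size), width_divisor = wd,
                 stem_ch = stem_ch, mids = mids, expansion = 4L,
                 G = G, d = d, msl = isTRUE(msl),
                 strategies = strategies, alpha = alpha, cfg = cfg),
            class = "net_spec")
}

#' Build one bottleneck block
#'
#' A 1x1 / 3x3 / 1x1 bottleneck with batch norm and ReLU, an identity or
#' 1x1-projection shortcut, and — for the attention variants — the
#' corresponding attention module applied to the residual-path output
#' immediately before the shortcut addition.
#'
#' @param variant one of `"resnet"`, `"sge"`, `"sk"`, `"ska"`.
#' @param in_ch,mid_ch input and bottleneck channel counts (output is
#'   `4 * mid_ch`).
#' @param stride stride of the 3x3 convolution (2 on stage transitions).
#' @param cfg an [ska_config()].
#' @param G,d effective cardinality / descriptor width.
#' @param init `"he"` or `"zeros"`.
#' @return block parameter list consumed by `block_fwd()`.
#' @export
build_block <- function(variant, in_ch, mid_ch, stride = 1L,
                        cfg = ska_config(), G = cfg$groups_G, d = cfg$d_min,
                        init = "he") {
  if (!variant %in% c("resnet", "sge", "sk", "ska"))
    stop(sprintf("unknown variant '%s'", variant))
  out_ch <- 4L * mid_ch
  z <- init == "zeros"
  mk_conv <- function(k, ci, co) {
    list(w = if (z) array(0, c(k, k, ci, co)) else he_conv(k, k, ci, co))
  }
  blk <- list(conv1 = mk_conv(1L, in_ch, mid_ch), bn1 = bn_init(mid_ch),
              conv2 = mk_conv(3L, mid_ch, mid_ch), bn2 = bn_init(mid_ch),
              conv3 = mk_conv(1L, mid_ch, out_ch), bn3 = bn_init(out_ch),
              stride = as.integer(stride), variant = variant)
  if (stride != 1L || in_ch != out_ch)
    blk$down <- c(mk_conv(1L, in_ch, out_ch), list(bn = bn_init(out_ch)))
  blk$att <- switch(variant,
    resnet = NULL,
    sge = list(gamma = rep(1, G), beta = rep(cfg$sge_beta_init, G), G = G),
    sk = ska_params(out_ch, cfg, G = G, d = d, with_sge = FALSE, init = init),
    ska = ska_params(out_ch, cfg, G = G, d = d, with_sge = TRUE, init = init))
  blk
}

block_fwd <- function(blk, x, training = FALSE) {
  c1 <- conv_fwd(x, blk$conv1$w)
  b1 <- bn2d_fwd(c1, blk$bn1, training); r1 <- relu_fwd(b1$y)
  c2 <- conv_fwd(r1$y, blk$conv2$w, stride = blk$stride, pad = 1L)
  b2 <- bn2d_fwd(c2, blk$bn2, training); r2 <- relu_fwd(b2$y)
  c3 <- conv_fwd(r2$y, blk$conv3$w)
  b3 <- bn2d_fwd(c3, blk$bn3, training)
  h <- b3$y
  att_cache <- NULL
  if (!is.null(blk$att)) {
    if (blk$variant == "sge") {
      s <- sge_fwd(h, blk$att$gamma, blk$att$beta, blk$att$G)
      h <- s$y; att_cache <- s$cache
    } else {
      s <- ska_fwd(h, blk$att, training)
      h <- s$y; att_cache <- s$cache
      if (training) blk$att <- s$params
    }
  }
  if (!is.null(blk$down)) {
    dc <- conv_fwd(x, blk$down$w, stride = blk$stride)
    db <- bn2d_fwd(dc, blk$down$bn, training)
    sc <- db$y
    down_cache <- list(x = x, bn = db$cache)
    if (training) blk$down$bn <- db$p
  } else {
    sc <- x
    down_cache <- NULL
  }
  r3 <- relu_fwd(h + sc)
  if (training) {
    blk$bn1 <- b1$p; blk$bn2 <- b2$p; blk$bn3 <- b3$p
  }
  list(y = r3$y, blk = blk,
       cache = list(x = x, r1 = r1$y, r2 = r2$y,
                    m1 = r1$cache, m2 = r2$cache, m3 = r3$cache,
                    bn1 = b1$cache, bn2 = b2$cache, bn3 = b3$cache,
                    att = att_cache, down = down_cache))
}

block_bwd <- function(blk, cache, gy) {
  g <- relu_bwd(cache$m3, gy)
  grads <- list()
  # shortcut path
  if (!is.null(blk$down)) {
    db <- bn2d_bwd(cache$down$bn, g)
    dc <- conv_bwd(db$gx, cache$down$x, blk$down$w, stride = blk$stride)
    gx_sc <- dc$gx
    grads$down <- list(w = dc$gw, bn = list(gamma = db$dgamma, beta = db$dbeta))
  } else {
    gx_sc <- g
  }
  # residual path
  gh <- g
  if (!is.null(blk$att)) {
    if (blk$variant == "sge") {
      s <- sge_bwd(cache$att, gh, blk$att$gamma)
      gh <- s$gx
      grads$att <- s$grads
    } else {
      s <- ska_bwd(blk$att, cache$att, gh)
      gh <- s$gx
      grads$att <- s$grads
    }
  }
  b3 <- bn2d_bwd(cache$bn3, gh)
  c3 <- conv_bwd(b3$gx, cache$r2, blk$conv3$w)
  g2 <- relu_bwd(cache$m2, c3$gx)
  b2 <- bn2d_bwd(cache$bn2, g2)
  c2 <- conv_bwd(b2$gx, cache$r1, blk$conv2$w, stride = blk$stride, pad = 1L)
  g1 <- relu_bwd(cache$m1, c2$gx)
  b1 <- bn2d_bwd(cache$bn1, g1)
  c1 <- conv_bwd(b1$gx, cache$x, blk$conv1$w)
  grads$conv1 <- list(w = c1$gw); grads$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  grads$conv2 <- list(w = c2$gw); grads$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  grads$conv3 <- list(w = c3$gw); grads$bn3 <- list(gamma = b3$dgamma, beta = b3$dbeta)
  list(gx = c1$gx + gx_sc, grads = grads)
}

#' Build a model from a specification
#'
#' @param spec a [net_spec()].
#' @param init `"he"` (random, seedable) or `"zeros"` (cheap allocation for
#'   profiling).
#' @param seed optional RNG seed for reproducible initialization.
#' @return an object of class `skanet_model`: list(spec, params).
#' @export
build_model <- function(spec, init = "he", seed = NULL) {
  stopifnot(inherits(spec, "net_spec"))
  if (!is.null(seed)) set.seed(seed)
  z <- init == "zeros"
  params <- list(
    stem = list(conv = list(w = if (z) array(0, c(7L, 7L, 3L, spec$stem_ch))
                                 else he_conv(7L, 7L, 3L, spec$stem_ch)),
                bn = bn_init(spec$stem_ch))
  )
  in_ch <- spec$stem_ch
  stages <- vector("list", 4L)
  for (si in 1:4) {
    blocks <- vector("list", spec$stage_blocks[si])
    for (bi in seq_len(spec$stage_blocks[si])) {
      stride <- if (si > 1L && bi == 1L) 2L else 1L
      blocks[[bi]] <- build_block(spec$variant, in_ch, spec$mids[si], stride,
                                  spec$cfg, spec$G, spec$d, init)
      in_ch <- 4L * spec$mids[si]
    }
    stages[[si]] <- blocks
  }
  params$stages <- stages
  params$head <- list(w = if (z) matrix(0, in_ch, spec$num_classes)
                           else matrix(rnorm(in_ch * spec$num_classes, sd = 0.01),
                                       in_ch, spec$num_classes),
                      b = rep(0, spec$num_classes))
  model <- list(spec = spec, params = params)
  if (spec$msl) {
    C3 <- 4L * spec$mids[3]; C4 <- 4L * spec$mids[4]
    model$msl <- list(
      cbam3 = cbam_params(C3, init = init),
      fc3 = list(w = if (z) matrix(0, C3, spec$num_classes)
                      else matrix(rnorm(C3 * spec$num_classes, sd = 0.01),
                                  C3, spec$num_classes),
                 b = rep(0, spec$num_classes)),
      cbam4 = cbam_params(C4, init = init),
      fc4 = list(w = if (z) matrix(0, C4, spec$num_classes)
                      else matrix(rnorm(C4 * spec$num_classes, sd = 0.01),
                                  C4, spec$num_classes),
                 b = rep(0, spec$num_classes)))
  }
  structure(model, class = "skanet_model")
}

backbone_fwd <- function(model, x, training = FALSE) {
  p <- model$params
  d <- fm_dim(x)
  if (d[2] != 3L) stop("expected a 3-channel (RGB) input batch")
  if (d[3] < 32L || d[4] < 32L)
    stop(sprintf("input %dx%d too small: five stride-2 reductions need at least 32x32",
                 d[3], d[4]))
  cache <- list()
  c0 <- conv_fwd(x, p$stem$conv$w, stride = 2L, pad = 3L)
  b0 <- bn2d_fwd(c0, p$stem$bn, training); r0 <- relu_fwd(b0$y)
  mp <- maxpool_fwd(r0$y, 3L, 2L, 1L)
  if (training) p$stem$bn <- b0$p
  cache$stem <- list(x = x, bn = b0$cache, mask = r0$cache, mp = mp$cache)
  h <- mp$y
  cache$stages <- vector("list", 4L)
  F3 <- NULL
  for (si in 1:4) {
    nb <- length(p$stages[[si]])
    cache$stages[[si]] <- vector("list", nb)
    for (bi in seq_len(nb)) {
      bf <- block_fwd(p$stages[[si]][[bi]], h, training)
      h <- bf$y
      if (training) p$stages[[si]][[bi]] <- bf$blk
      cache$stages[[si]][[bi]] <- bf$cache
    }
    if (si == 3L) F3 <- h
  }
  F4 <- h
  pooled <- gap_fwd(F4)
  logits <- linear_fwd(pooled, p$head$w, p$head$b)
  model$params <- p
  list(F3 = F3, F4 = F4, pooled = pooled, logits = logits,
       cache = cache, model = model)
}

# dlogits: gradient at the main head logits; dF3/dF4: extra gradients
# injected at the tap points by the auxiliary heads.
backbone_bwd <- function(model, fwd, dlogits, dF3 = NULL, dF4 = NULL) {
  p <- model$params
  grads <- list()
  hd <- linear_bwd(dlogits, fwd$pooled, p$head$w)
  grads$head <- list(w = hd$gw, b = hd$gb)
  g <- gap_bwd(hd$gx, dim(fwd$F4))
  if (!is.null(dF4)) g <- g + dF4
  grads$stages <- vector("list", 4L)
  for (si in 4:1) {
    nb <- length(p$stages[[si]])
    grads$stages[[si]] <- vector("list", nb)
    for (bi in nb:1) {
      bb <- block_bwd(p$stages[[si]][[bi]], fwd$cache$stages[[si]][[bi]], g)
      g <- bb$gx
      grads$stages[[si]][[bi]] <- bb$grads
    }
    if (si == 4L && !is.null(dF3)) g <- g + dF3
  }
  st <- fwd$cache$stem
  g <- maxpool_bwd(st$mp, g)
  g <- relu_bwd(st$mask, g)
  b0 <- bn2d_bwd(st$bn, g)
  c0 <- conv_bwd(b0$gx, st$x, p$stem$conv$w, stride = 2L, pad = 3L)
  grads$stem <- list(conv = list(w = c0$gw),
                     bn = list(gamma = b0$dgamma, beta = b0$dbeta))
  list(grads = grads, gx = c0$gx)
}

#' Forward pass exposing the multi-scale tap points
#'
#' Runs the backbone once and returns the stage-3 and stage-4 feature maps
#' (the taps strengthened by the auxiliary CBAM heads), the pooled feature
#' vector and the main-head logits.
#'
#' @param model a [build_model()] result.
#' @param x input batch, dim (N, 3, H, W).
#' @param training batch-norm mode (running statistics are not updated
#'   through this entry point; use [train_model()] for that).
#' @return list with `F3`, `F4`, `pooled`, `logits`.
#' @export
forward_features <- function(model, x, training = FALSE) {
  r <- backbone_fwd(model, x, training = FALSE)
  r[c("F3", "F4", "pooled", "logits")]
}

#' @export
print.skanet_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<skanet_model> %s-50-style backbone\n", toupper(s$variant)))
  cat(sprintf("  stage blocks: %s | classes: %d | width 1/%d | G = %d, d = %d\n",
              paste(s$stage_blocks, collapse = "-"), s$num_classes,
              s$width_divisor, s$G, s$d))
  cat(sprintf("  multi-scale heads: %s\n", if (s$msl) "on" else "off"))
  st <- count_parameters(x)
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(st$params, big.mark = ","), st$params / 1e6))
  invisible(x)
}
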