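# Training / evaluation engine: SGD with momentum and weight decay, the
# step learning-rate schedule (decay by 10 at half and three-quarters of
# the run), per-epoch history, and top-1 evaluation.

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size mini-batch size (the ablation grid uses 16/32/64/128).
#' @param base_lr initial learning rate.
#' @param lr_decay_factor multiplicative decay applied at the milestones
#'   `floor(epochs / 2)` and `floor(3 * epochs / 4)` (0-based epochs).
#' @param momentum,weight_decay SGD momentum and L2 weight decay.
#' @param input_scale network input side (112/224/336/448 in the scale
#'   ablation).
#' @param seed seed controlling initialization, shuffling and augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L, base_lr = 0.01,
                         lr_decay_factor = 0.1, momentum = 0.9,
                         weight_decay = 1e-4, input_scale = 224L, seed = 1L) {
  if (epochs < 1L || batch_size < 1L || base_lr <= 0)
    stop("epochs and batch_size must be >= 1 and base_lr > 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), base_lr = base_lr,
                 lr_decay_factor = lr_decay_factor, momentum = momentum,
                 weight_decay = weight_decay,
                 input_scale = as.integer(input_scale),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at an epoch
#'
#' `base_lr * lr_decay_factor^k`, where `k` counts passed milestones at
#' `floor(E / 2)` and `floor(3 * E / 4)` (0-based epochs).
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param cfg a [train_config()].
#' @return the learning rate.
#' @export
lr_at <- function(epoch, cfg) {
  if (any(epoch < 0L | epoch >= cfg$epochs))
    stop(sprintf("epoch must lie in [0, %d)", cfg$epochs))
  miles <- c(cfg$epochs %/% 2L, (3L * cfg$epochs) %/% 4L)
  k <- vapply(epoch, function(e) sum(e >= miles), 0)
  cfg$base_lr * cfg$lr_decay_factor^k
}

# recursive SGD-with-momentum update over a parameter tree; velocity tree
# mirrors the trainable leaves
sgd_step <- function(params, grads, vel, lr, momentum, wd) {
  nms <- names(params)
  if (length(vel) == 0L) vel <- vector("list", length(params))
  for (i in seq_along(params)) {
    n <- if (is.null(nms)) "" else nms[i]
    g <- if (nzchar(n)) grads[[n]] else grads[[i]]
    if (is.null(g)) next
    if (n %in% trainable_leaf_names && is.numeric(params[[i]])) {
      v <- vel[[i]]
      if (is.null(v)) v <- 0
      v <- momentum * v + g + wd * params[[i]]
      params[[i]] <- params[[i]] - lr * v
      vel[[i]] <- v
    } else if (is.list(params[[i]])) {
      r <- sgd_step(params[[i]], g,
                    if (is.null(vel[[i]])) list() else vel[[i]],
                    lr, momentum, wd)
      params[[i]] <- r$params
      vel[[i]] <- r$vel
    }
  }
  list(params = params, vel = vel)
}

# forward + loss + full backward for one batch; returns losses, grads and
# the model with updated batch-norm buffers
train_batch <- function(model, x, labels, mcfg, literal_sum = FALSE) {
  fwd <- backbone_fwd(model, x, training = TRUE)
  model <- fwd$model
  N <- dim(x)[1]
  C <- model$spec$num_classes
  onehot <- matrix(0, N, C); onehot[cbind(seq_len(N), labels)] <- 1
  if (!is.null(model$msl)) {
    hd <- heads_fwd(model$msl, fwd$F3, fwd$F4, fwd$logits)
    P3 <- hd$P3; P4 <- hd$P4; P <- hd$P
    cls <- classification_loss(P3, P4, P, labels, mcfg$epsilon, literal_sum)
    ms <- msl_loss(P3, P4, P, mcfg)
    cg <- classification_loss_grads(P3, P4, P, labels, mcfg$epsilon, literal_sum)
    mg <- msl_loss_grads(P3, P4, P, mcfg)
    d3 <- cg$d3 + mcfg$alpha * mg$d3
    d4 <- cg$d4 + mcfg$alpha * mg$d4
    dp <- cg$dp + mcfg$alpha * mg$dp
    dlogits <- softmax_bwd(P, dp)
    hb <- heads_bwd(model$msl, hd$cache, P3, P4, d3, d4)
    bb <- backbone_bwd(model, fwd, dlogits, dF3 = hb$dF3, dF4 = hb$dF4)
    prob <- (P3 + P4 + P) / 3
    list(model = model, cls = cls, msl = ms,
         total = cls + mcfg$alpha * ms, prob = prob,
         grads = bb$grads, msl_grads = hb$grads)
  } else {
    P <- softmax_rows(fwd$logits)
    cls <- -mean(log(pmax(P[cbind(seq_len(N), labels)], 1e-12)))
    dlogits <- (P - onehot) / N
    bb <- backbone_bwd(model, fwd, dlogits)
    list(model = model, cls = cls, msl = 0, total = cls, prob = P,
         grads = bb$grads, msl_grads = NULL)
  }
}

model_predict <- function(model, x) {
  fwd <- backbone_fwd(model, x, training = FALSE)
  if (!is.null(model$msl)) {
    hd <- heads_fwd(model$msl, fwd$F3, fwd$F4, fwd$logits)
    prob <- (hd$P3 + hd$P4 + hd$P) / 3
  } else {
    prob <- softmax_rows(fwd$logits)
  }
  list(prob = prob, pred = max.col(prob, ties.method = "first"))
}

#' Train a model on a dataset index
#'
#' Builds the network described by `spec`, then optimizes the combined
#' objective with SGD (momentum 0.9, weight decay 1e-4) under the step
#' schedule of [lr_at()]. Fully seeded: initialization, shuffling and
#' augmentation all derive from `cfg$seed`.
#'
#' @param spec a [net_spec()] (its `num_classes` must match the index).
#' @param index dataset index with a `split` column from
#'   [split_train_test()].
#' @param cfg a [train_config()].
#' @param dir dataset directory (defaults to the index attribute).
#' @param checkpoint_path if set, the best-test-accuracy model is saved
#'   here via [save_checkpoint()].
#' @param log_csv if set, per-step loss components (epoch, step, cls, msl,
#'   total, lr) are appended to this CSV.
#' @param eval_every evaluate test top-1 every this many epochs.
#' @param verbose print per-epoch progress.
#' @return list with `model` and `history` (one row per epoch: epoch, lr,
#'   cls, msl, total, train_top1, test_top1).
#' @export
train_model <- function(spec, index, cfg, dir = attr(index, "dir"),
                        pp = NULL, checkpoint_path = NULL, log_csv = NULL,
                        eval_every = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "net_spec"), inherits(cfg, "train_config"))
  if (!"split" %in% names(index)) stop("index has no split column; run split_train_test()")
  tr <- index[index$split == "train", , drop = FALSE]
  if (nrow(tr) == 0L) stop("empty training split")
  if (max(index$label) > spec$num_classes)
    stop("spec num_classes is smaller than the label range of the index")
  set.seed(cfg$seed)
  model <- build_model(spec, seed = cfg$seed)
  man <- attr(index, "manifest")
  if (is.null(pp)) {
    pp <- if (!is.null(man$channel_mean))
      preprocess_config(crop = cfg$input_scale, mean = man$channel_mean,
                        sd = man$channel_sd)
    else preprocess_config(crop = cfg$input_scale)
  }
  mcfg <- msl_config(spec$strategies, spec$alpha)
  vel <- list(); vel_msl <- list()
  hist <- vector("list", cfg$epochs)
  if (!is.null(log_csv))
    cat("epoch,step,cls,msl,total,lr\n", file = log_csv)
  best <- -Inf
  for (ep in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at(ep, cfg)
    ord <- sample.int(nrow(tr))
    nb <- ceiling(nrow(tr) / cfg$batch_size)
    esum <- c(cls = 0, msl = 0, total = 0); ncorr <- 0L
    for (b in seq_len(nb)) {
      rows <- tr[ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, nrow(tr))], ]
      x <- load_batch(rows, dir, "train", pp)
      r <- train_batch(model, x, rows$label, mcfg)
      if (!is.finite(r$total))
        stop(sprintf("training diverged (non-finite loss) at epoch %d step %d", ep, b))
      model <- r$model
      up <- sgd_step(model$params, r$grads, vel, lr, cfg$momentum,
                     cfg$weight_decay)
      model$params <- up$params; vel <- up$vel
      if (!is.null(r$msl_grads)) {
        up2 <- sgd_step(model$msl, r$msl_grads, vel_msl, lr, cfg$momentum,
                        cfg$weight_decay)
        model$msl <- up2$params; vel_msl <- up2$vel
      }
      esum <- esum + c(r$cls, r$msl, r$total) * nrow(rows)
      ncorr <- ncorr + sum(max.col(r$prob, ties.method = "first") == rows$label)
      if (!is.null(log_csv))
        cat(sprintf("%d,%d,%.6f,%.6f,%.6f,%g\n", ep, b, r$cls, r$msl,
                    r$total, lr), file = log_csv, append = TRUE)
    }
    esum <- esum / nrow(tr)
    test_top1 <- NA_real_
    if (ep %% eval_every == 0L || ep == cfg$epochs - 1L) {
      test_top1 <- evaluate_model(model, index, cfg = pp, dir = dir,
                                  batch_size = cfg$batch_size)
      if (!is.na(test_top1) && test_top1 > best) {
        best <- test_top1
        if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
      }
    }
    hist[[ep + 1L]] <- data.frame(epoch = ep, lr = lr, cls = esum[1],
                                  msl = esum[2], total = esum[3],
                                  train_top1 = 100 * ncorr / nrow(tr),
                                  test_top1 = test_top1)
    if (verbose)
      message(sprintf("epoch %2d lr %.4g loss %.4f train %.1f%% test %s", ep,
                      lr, esum[3], 100 * ncorr / nrow(tr),
                      ifelse(is.na(test_top1), "-", sprintf("%.1f%%", test_top1))))
  }
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  list(model = model, history = history)
}

#' Top-1 accuracy on a dataset split
#'
#' Predictions use the mean of the three head distributions when the model
#' carries multi-scale heads, the main softmax otherwise.
#'
#' @param model a trained model.
#' @param index dataset index.
#' @param split which split to evaluate (`NULL` for all rows).
#' @param cfg a [preprocess_config()].
#' @param dir dataset directory.
#' @param batch_size evaluation batch size.
#' @return top-1 accuracy as a percentage.
#' @export
evaluate_model <- function(model, index, split = "test",
                           cfg = preprocess_config(), dir = attr(index, "dir"),
                           batch_size = 32L) {
  rows <- if (is.null(split)) index else index[index$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("empty evaluation split")
  nb <- ceiling(nrow(rows) / batch_size)
  ncorr <- 0L
  for (b in seq_len(nb)) {
    rr <- rows[((b - 1L) * batch_size + 1L):min(b * batch_size, nrow(rows)), ]
    x <- load_batch(rr, dir, "eval", cfg)
    pr <- model_predict(model, x)
    ncorr <- ncorr + sum(pr$pred == rr$label)
  }
  100 * ncorr / nrow(rows)
}

#' Ablation grids
#'
#' Runnable configuration grids: batch sizes 16/32/64/128, input scales
#' 112/224/336/448, and the six matching-strategy sets.
#'
#' @param kind which grid.
#' @param base a [train_config()] used as the template.
#' @return named list of configurations (or strategy sets for
#'   `kind = "strategy"`).
#' @export
ablation_grid <- function(kind = c("batch", "scale", "strategy"),
                          base = train_config()) {
  kind <- match.arg(kind)
  if (kind == "strategy") return(msl_strategy_sets())
  vals <- if (kind == "batch") c(16L, 32L, 64L, 128L) else c(112L, 224L, 336L, 448L)
  out <- lapply(vals, function(v) {
    cfg <- base
    if (kind == "batch") cfg$batch_size <- v else cfg$input_scale <- v
    cfg
  })
  names(out) <- vals
  out
}
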