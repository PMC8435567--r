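# Closed-form parameter and multiply-add accounting. The multiply-add
# convention is frozen: convolution and fc layers contribute their MACs,
# batch norm 2 ops per output element, ReLU and pooling 1 op per input
# element; bare tensor additions (residual shortcuts, branch sums) are not
# counted. Under this convention the plain 50-layer baseline at 224 input
# reproduces 25,557,032 parameters and 4,121,925,096 multiply-adds.

trainable_leaf_names <- c("w", "b", "gamma", "beta")

walk_params <- function(tree, path, rows) {
  nms <- names(tree)
  for (i in seq_along(tree)) {
    v <- tree[[i]]
    n <- if (is.null(nms) || !nzchar(nms[i])) as.character(i) else nms[i]
    if (n %in% trainable_leaf_names && is.numeric(v)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(c(path, n), collapse = "."),
        params = length(v), stringsAsFactors = FALSE)
    } else if (is.list(v)) {
      rows <- walk_params(v, c(path, n), rows)
    }
  }
  rows
}

#' Count trainable parameters
#'
#' Exact integer count of every trainable scalar in the model (convolution
#' and fc weights and biases, batch-norm and group-enhancement gammas and
#' betas). Running batch-norm statistics are buffers, not parameters.
#'
#' @param model a [build_model()] result.
#' @return an object of class `model_stats`: list with `params` (integer),
#'   `params_M` (millions, 2 decimals) and a `per_layer` ledger.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "skanet_model"))
  rows <- walk_params(model$params, character(0), list())
  if (!is.null(model$msl)) rows <- walk_params(model$msl, "msl", rows)
  per_layer <- do.call(rbind, rows)
  total <- sum(per_layer$params)
  structure(list(params = total, params_M = round(total / 1e6, 2),
                 per_layer = per_layer),
            class = "model_stats")
}

out_hw <- function(h, k, s, p) (h + 2L * p - k) %/% s + 1L

#' Count multiply-add operations
#'
#' Analytic multiply-add count for one forward pass at a stated square input
#' size, itemized per layer, under the frozen convention described above.
#' Attention-module arithmetic (descriptor pooling, standardizations,
#' sigmoid gates, gating products) is counted at one operation per element.
#'
#' @param model a [build_model()] result.
#' @param input_size square input side in pixels; defaults to the spec's.
#' @return an object of class `model_stats`: list with `madds` (count),
#'   `gmacs` (1e9 units, 3 decimals) and a `per_layer` ledger.
#' @export
count_multiply_adds <- function(model, input_size = model$spec$input_size) {
  stopifnot(inherits(model, "skanet_model"))
  S <- as.integer(input_size)
  if (S < 32L) stop("input size must allow five stride-2 reductions")
  rows <- list()
  add <- function(name, kind, macs) {
    rows[[length(rows) + 1L]] <<- data.frame(name = name, kind = kind,
                                             madds = macs,
                                             stringsAsFactors = FALSE)
  }
  conv_macs <- function(wdim, hout, wout, groups = 1, bias = FALSE) {
    m <- prod(wdim) * hout * wout            # wdim already holds Cin/groups
    if (bias) m <- m + wdim[4] * hout * wout
    m
  }
  p <- model$params
  # stem
  h <- out_hw(S, 7L, 2L, 3L)
  C0 <- dim(p$stem$conv$w)[4]
  add("stem.conv", "conv", conv_macs(dim(p$stem$conv$w), h, h))
  add("stem.bn", "bn", 2 * C0 * h * h)
  add("stem.relu", "relu", C0 * h * h)
  add("stem.maxpool", "pool", C0 * h * h)
  h <- out_hw(h, 3L, 2L, 1L)
  att_macs <- function(blk, C, K, G) {
    m <- 0
    if (is.null(blk$att)) return(m)
    if (blk$variant == "sge") {
      # descriptor pool, similarity (mul + reduce), standardize, affine +
      # sigmoid, gating product
      return(C * K + 2 * C * K + 2 * G * K + 2 * G * K + C * K)
    }
    a <- blk$att
    for (br in c("b1", "b2")) {
      wd <- dim(a[[br]]$w)
      m <- m + conv_macs(wd, sqrt(K), sqrt(K), groups = C) + 2 * C * K + C * K
    }
    m <- m + C * K                            # fuse global average pool
    m <- m + 2 * C                            # channel standardization
    m <- m + C                                # group averaging
    m <- m + length(a$fuse$w) + 2 * a$d + a$d # fc + bn1d + relu
    m <- m + length(a$sel$w) + 2 + 4          # selection head + softmax
    if (!is.null(a$sge1)) m <- m + 2 * (C * K + 2 * C * K + 2 * G * K + 2 * G * K + C * K)
    m <- m + 2 * C * K                        # aggregation products
    m
  }
  for (si in 1:4) {
    for (bi in seq_along(p$stages[[si]])) {
      blk <- p$stages[[si]][[bi]]
      nm <- sprintf("stage%d.block%d", si, bi)
      hin <- h
      hout <- if (blk$stride == 2L) out_hw(h, 3L, 2L, 1L) else h
      mid <- dim(blk$conv1$w)[4]; outc <- dim(blk$conv3$w)[4]
      add(paste0(nm, ".conv1"), "conv", conv_macs(dim(blk$conv1$w), hin, hin))
      add(paste0(nm, ".bn1"), "bn", 2 * mid * hin * hin)
      add(paste0(nm, ".relu1"), "relu", mid * hin * hin)
      add(paste0(nm, ".conv2"), "conv", conv_macs(dim(blk$conv2$w), hout, hout))
      add(paste0(nm, ".bn2"), "bn", 2 * mid * hout * hout)
      add(paste0(nm, ".relu2"), "relu", mid * hout * hout)
      add(paste0(nm, ".conv3"), "conv", conv_macs(dim(blk$conv3$w), hout, hout))
      add(paste0(nm, ".bn3"), "bn", 2 * outc * hout * hout)
      if (!is.null(blk$down)) {
        add(paste0(nm, ".down"), "conv", conv_macs(dim(blk$down$w), hout, hout))
        add(paste0(nm, ".down.bn"), "bn", 2 * outc * hout * hout)
      }
      am <- att_macs(blk, outc, hout * hout, model$spec$G)
      if (am > 0) add(paste0(nm, ".att"), "attention", am)
      add(paste0(nm, ".relu3"), "relu", outc * hout * hout)
      h <- hout
    }
  }
  Cf <- nrow(p$head$w)
  add("gap", "pool", Cf * h * h)
  add("head.fc", "fc", length(p$head$w) + length(p$head$b))
  if (!is.null(model$msl)) {
    # auxiliary CBAM + fc heads at the stage-3 / stage-4 spatial sizes
    hw3 <- (out_hw(out_hw(out_hw(out_hw(S, 7L, 2L, 3L), 3L, 2L, 1L), 3L, 2L, 1L), 3L, 2L, 1L))^2
    hw4 <- out_hw(as.integer(sqrt(hw3)), 3L, 2L, 1L)^2
    cb <- function(nm, prm, C, K) {
      m <- 2 * C * K                                      # avg + max pooling
      m <- m + 2 * (length(prm$mlp1$w) + length(prm$mlp1$b) +
                    length(prm$mlp2$w) + length(prm$mlp2$b))
      m <- m + ncol(prm$mlp2$w) + C * K                   # sigmoid + gating
      m <- m + 2 * C * K                                  # channel avg/max
      m <- m + conv_macs(dim(prm$conv$w), sqrt(K), sqrt(K), bias = TRUE)
      m <- m + K + C * K                                  # sigmoid + gating
      add(nm, "attention", m)
    }
    C3 <- nrow(model$msl$fc3$w); C4 <- nrow(model$msl$fc4$w)
    cb("msl.cbam3", model$msl$cbam3, C3, hw3)
    add("msl.fc3", "fc", length(model$msl$fc3$w) + length(model$msl$fc3$b))
    cb("msl.cbam4", model$msl$cbam4, C4, hw4)
    add("msl.fc4", "fc", length(model$msl$fc4$w) + length(model$msl$fc4$b))
  }
  per_layer <- do.call(rbind, rows)
  total <- sum(per_layer$madds)
  structure(list(madds = total, gmacs = round(total / 1e9, 3),
                 per_layer = per_layer, input_size = S),
            class = "model_stats")
}

#' @export
print.model_stats <- function(x, ...) {
  if (!is.null(x$params))
    cat(sprintf("trainable parameters: %s (%.2f M)\n",
                format(x$params, big.mark = ","), x$params / 1e6))
  if (!is.null(x$madds))
    cat(sprintf("multiply-adds @ %d: %s (%.3f G)\n", x$input_size,
                format(x$madds, big.mark = ","), x$madds / 1e9))
  cat(sprintf("layers itemized: %d\n", nrow(x$per_layer)))
  invisible(x)
}

#' Text summary of a model's layer ledger
#'
#' @param model a [build_model()] result.
#' @param input_size square input side for the multiply-add column.
#' @return data frame with one row per layer: name, kind, params, madds.
#' @export
model_summary <- function(model, input_size = model$spec$input_size) {
  pp <- count_parameters(model)$per_layer
  mm <- count_multiply_adds(model, input_size)$per_layer
  merge(mm, pp, by = "name", all = TRUE, sort = FALSE)
}
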