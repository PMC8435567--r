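# Core tensor primitives: forward passes paired with analytic backward passes.
# Feature maps are numeric arrays with dim (N, C, H, W); "cache" lists carry
# exactly what the matching backward needs. Everything is double precision.

#' Dimensions of a feature map
#' @param x feature map array
#' @return integer vector (N, C, H, W)
#' @noRd
fm_dim <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("expected a rank-4 (N, C, H, W) feature map")
  d
}

check_same_shape <- function(a, b, what = "feature maps") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

## ---- convolution -----------------------------------------------------------

conv_fwd <- function(x, w, bias = NULL, stride = 1L, pad = 0L, groups = 1L) {
  d <- fm_dim(x); wd <- dim(w)
  if (d[2] != wd[3] * groups)
    stop(sprintf("channel mismatch: input has %d channels, kernel expects %d x %d groups",
                 d[2], wd[3], groups))
  conv2d_fwd_cpp(x, w, if (is.null(bias)) numeric(0) else bias,
                 as.integer(stride), as.integer(pad), as.integer(groups))
}

conv_bwd <- function(gy, x, w, stride = 1L, pad = 0L, groups = 1L,
                     has_bias = FALSE) {
  gx <- conv2d_bwd_input_cpp(gy, w, dim(x), as.integer(stride),
                             as.integer(pad), as.integer(groups))
  gw <- conv2d_bwd_weight_cpp(x, gy, dim(w), as.integer(stride),
                              as.integer(pad), as.integer(groups))
  gb <- NULL
  if (has_bias) {
    d <- dim(gy)
    gb <- rowSums(matrix(colSums(matrix(gy, d[1], d[2] * d[3] * d[4])), d[2], d[3] * d[4]))
  }
  list(gx = gx, gw = gw, gb = gb)
}

## ---- batch normalization ---------------------------------------------------

# Population (biased) variance throughout; eps stabilizes zero-variance
# channels. `p` is list(gamma, beta, rmean, rvar); running stats are updated
# with momentum only in training mode.
bn2d_fwd <- function(x, p, training = FALSE, eps = 1e-5, momentum = 0.1) {
  d <- fm_dim(x)
  N <- d[1]; C <- d[2]; HW <- d[3] * d[4]
  xm <- matrix(x, N * C, HW)
  if (training) {
    percs <- rowSums(xm)                       # per (n, c)
    mu <- colSums(matrix(percs, N, C)) / (N * HW)
    percs2 <- rowSums(xm * xm)
    ex2 <- colSums(matrix(percs2, N, C)) / (N * HW)
    v <- pmax(ex2 - mu^2, 0)
    p$rmean <- (1 - momentum) * p$rmean + momentum * mu
    p$rvar <- (1 - momentum) * p$rvar + momentum * v
  } else {
    mu <- p$rmean; v <- p$rvar
  }
  invstd <- 1 / sqrt(v + eps)
  mu_r <- rep(mu, each = N); invstd_r <- rep(invstd, each = N)
  xhat <- (xm - mu_r) * invstd_r
  y <- xhat * rep(p$gamma, each = N) + rep(p$beta, each = N)
  dim(y) <- d
  list(y = y,
       cache = list(xhat = xhat, invstd = invstd, d = d, gamma = p$gamma,
                    training = training),
       p = p)
}

bn2d_bwd <- function(cache, gy) {
  d <- cache$d; N <- d[1]; C <- d[2]; HW <- d[3] * d[4]
  gym <- matrix(gy, N * C, HW)
  xhat <- cache$xhat
  per_nc <- function(m) colSums(matrix(rowSums(m), N, C))
  dgamma <- per_nc(gym * xhat)
  dbeta <- per_nc(gym)
  g_r <- rep(cache$gamma, each = N)
  invstd_r <- rep(cache$invstd, each = N)
  if (cache$training) {
    M <- N * HW
    dxhat <- gym * g_r
    t1 <- rep(dgamma / M, each = N)   # mean(dxhat * xhat) per channel
    t2 <- rep(dbeta / M, each = N)    # mean(dxhat) per channel, pre-gamma
    gx <- invstd_r * (dxhat - g_r * (xhat * t1 + t2))
  } else {
    gx <- gym * g_r * invstd_r
  }
  dim(gx) <- d
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}

# 1-d batch norm over (N, D) matrices (used on the fuse descriptor).
bn1d_fwd <- function(x, p, training = FALSE, eps = 1e-5, momentum = 0.1) {
  N <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    v <- pmax(colMeans(x * x) - mu^2, 0)
    p$rmean <- (1 - momentum) * p$rmean + momentum * mu
    p$rvar <- (1 - momentum) * p$rvar + momentum * v
  } else {
    mu <- p$rmean; v <- p$rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(y = y,
       cache = list(xhat = xhat, invstd = invstd, gamma = p$gamma, N = N,
                    training = training),
       p = p)
}

bn1d_bwd <- function(cache, gy) {
  xhat <- cache$xhat; N <- cache$N
  dgamma <- colSums(gy * xhat)
  dbeta <- colSums(gy)
  if (cache$training) {
    dxhat <- sweep(gy, 2, cache$gamma, `*`)
    gx <- sweep(dxhat - sweep(xhat, 2, dgamma * cache$gamma / N, `*`) -
                  matrix(rep(dbeta * cache$gamma / N, each = N), N),
                2, cache$invstd, `*`)
  } else {
    gx <- sweep(sweep(gy, 2, cache$gamma, `*`), 2, cache$invstd, `*`)
  }
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C), rmean = rep(0, C), rvar = rep(1, C))
}

## ---- pointwise and pooling -------------------------------------------------

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, cache = mask)
}

relu_bwd <- function(mask, gy) {
  gy[!mask] <- 0
  gy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

maxpool_fwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  r <- maxpool2d_fwd_cpp(x, as.integer(k), as.integer(stride), as.integer(pad))
  list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)))
}

maxpool_bwd <- function(cache, gy) maxpool2d_bwd_cpp(gy, cache$idx, cache$xdim)

# Global average pooling (N, C, H, W) -> (N, C)
gap_fwd <- function(x) {
  d <- fm_dim(x)
  matrix(rowMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[1], d[2])
}

gap_bwd <- function(gy, xdim) {
  HW <- xdim[3] * xdim[4]
  gx <- rep(as.vector(gy) / HW, HW)
  dim(gx) <- xdim
  gx
}

## ---- linear / softmax ------------------------------------------------------

linear_fwd <- function(x, w, b = NULL) {
  y <- x %*% w
  if (!is.null(b)) y <- sweep(y, 2, b, `+`)
  y
}

linear_bwd <- function(gy, x, w, has_bias = TRUE) {
  list(gx = gy %*% t(w), gw = crossprod(x, gy),
       gb = if (has_bias) colSums(gy) else NULL)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# gradient through row-wise softmax: gz = p * (gp - rowSums(gp * p))
softmax_bwd <- function(p, gp) {
  p * (gp - rowSums(gp * p))
}

## ---- broadcast helpers -----------------------------------------------------

# multiply each channel c of x (N,C,H,W) by gate (N,C)
mul_channel <- function(x, gate) {
  d <- fm_dim(x)
  y <- matrix(x, d[1] * d[2], d[3] * d[4]) * as.vector(gate)
  dim(y) <- d
  y
}

# multiply each spatial position of x (N,C,H,W) by gate (N, H*W)
mul_spatial <- function(x, gate) {
  d <- fm_dim(x)
  f <- aperm(array(gate, c(d[1], d[3] * d[4], d[2])), c(1, 3, 2))
  y <- as.vector(x) * as.vector(f)
  dim(y) <- d
  y
}

# sum of x (N,C,H,W) over channels -> (N, H*W)
sum_channel <- function(x) {
  d <- fm_dim(x)
  colSums(aperm(array(x, c(d[1], d[2], d[3] * d[4])), c(2, 1, 3)))
}

## ---- initializers ----------------------------------------------------------

# He-style fan-in scaling for conv kernels, dim (kh, kw, cg, cout)
he_conv <- function(kh, kw, cg, cout) {
  fan_in <- kh * kw * cg
  array(rnorm(kh * kw * cg * cout, sd = sqrt(2 / fan_in)), c(kh, kw, cg, cout))
}

he_linear <- function(cin, cout) {
  matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
}
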