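# The selective-kernel attention (SKA) block: Divide (two depthwise kernels),
# Fuse (pooled, standardized, compressed descriptor), spatial group-wise
# enhancement of each branch, and softmax-weighted Aggregation. Forward ops
# are exported as pure functions of (input, params); the *_fwd/*_bwd pairs
# carry caches for training.

#' Configuration of a selective-kernel attention module
#'
#' @param kernel_a,kernel_b odd kernel sizes of the two divide branches.
#' @param reduction_r channel reduction ratio of the fuse stage.
#' @param d_min floor on the compressed descriptor width.
#' @param groups_G cardinality: number of channel groups in the group-wise
#'   enhancement (must divide every channel count it is applied to).
#' @param sge_beta_init initial value of the group-enhancement shift. The
#'   default 1 starts every gate near pass-through (sigmoid(1 + z)), so the
#'   enhancement learns a deviation from identity rather than opening from
#'   the half-attenuated sigmoid(z); the enhancement module's own
#'   initialization is unstated in its reference.
#' @param eps stabilizer for the per-sample standardizations.
#' @return an object of class `ska_config`.
#' @export
ska_config <- function(kernel_a = 3L, kernel_b = 5L, reduction_r = 16L,
                       d_min = 32L, groups_G = 32L, sge_beta_init = 1,
                       eps = 1e-5) {
  if (kernel_a %% 2 == 0 || kernel_b %% 2 == 0)
    stop("divide kernels must be odd so spatial size is preserved")
  if (reduction_r < 1 || d_min < 1 || groups_G < 1)
    stop("reduction_r, d_min and groups_G must all be >= 1")
  structure(list(kernel_a = as.integer(kernel_a), kernel_b = as.integer(kernel_b),
                 reduction_r = as.integer(reduction_r), d_min = as.integer(d_min),
                 groups_G = as.integer(groups_G), sge_beta_init = sge_beta_init,
                 eps = eps),
            class = "ska_config")
}

# Standardize rows of a matrix with population std; returns z plus backward
# closure inputs. Used for the fuse descriptor (over channels) and the
# group-wise similarity maps (over spatial positions).
row_standardize <- function(m, eps = 1e-5) {
  mu <- rowMeans(m)
  v <- rowMeans(m * m) - mu^2
  invstd <- 1 / sqrt(pmax(v, 0) + eps)
  z <- (m - mu) * invstd
  list(z = z, invstd = invstd)
}

row_standardize_bwd <- function(z, invstd, dz) {
  (dz - rowMeans(dz) - z * rowMeans(dz * z)) * invstd
}

## ---- parameter constructors ------------------------------------------------

ska_branch_params <- function(C, kernel, init = "he") {
  w <- if (init == "he") he_conv(kernel, kernel, 1L, C)
       else array(0, c(kernel, kernel, 1L, C))
  list(w = w, bn = bn_init(C))
}

#' Parameters of a selective-kernel attention module
#'
#' Builds freshly initialized parameters for [ska_module()] at channel width
#' `C`. The fuse stage compresses the standardized pooled descriptor to one
#' value per channel group (length `G`) before a `G -> d` fc layer with batch
#' norm and ReLU; the selection head maps the compressed descriptor to two
#' branch logits shared across channels.
#'
#' @param C channel count the module is applied to.
#' @param cfg an [ska_config()].
#' @param G,d effective cardinality and descriptor width; default taken from
#'   `cfg` (scaled implementations may pass reduced values for narrow nets).
#' @param with_sge include the per-branch group-wise enhancement parameters
#'   (`FALSE` gives the plain selective-kernel module).
#' @param init `"he"` for random fan-in-scaled kernels, `"zeros"` for
#'   all-zero kernels (profiling).
#' @return a nested parameter list.
#' @export
ska_params <- function(C, cfg = ska_config(), G = cfg$groups_G,
                       d = cfg$d_min, with_sge = TRUE, init = "he") {
  if (C %% G != 0)
    stop(sprintf("cardinality G = %d must divide the channel count C = %d", G, C))
  p <- list(
    b1 = ska_branch_params(C, cfg$kernel_a, init),
    b2 = ska_branch_params(C, cfg$kernel_b, init),
    fuse = list(w = if (init == "he") he_linear(G, d) else matrix(0, G, d),
                bn = bn_init(d)),
    sel = list(w = matrix(rnorm(d * 2L, sd = 0.01), d, 2L), b = rep(0, 2L)),
    G = G, d = d
  )
  if (init == "zeros") p$sel$w[] <- 0
  if (with_sge) {
    p$sge1 <- list(gamma = rep(1, G), beta = rep(cfg$sge_beta_init, G))
    p$sge2 <- list(gamma = rep(1, G), beta = rep(cfg$sge_beta_init, G))
  }
  p
}

## ---- divide ----------------------------------------------------------------

#' Divide-stage branch transform
#'
#' One branch of the divide stage: a depthwise convolution with an odd kernel
#' (padding `(k - 1) / 2`, so spatial size is preserved), batch normalization
#' and ReLU.
#'
#' @param x feature map, dim (N, C, H, W).
#' @param params list with `w` (kernel, dim (k, k, 1, C)) and `bn`.
#' @param training use batch statistics and update running statistics.
#' @return feature map of the same shape as `x`, all entries >= 0.
#' @export
branch_transform <- function(x, params, training = FALSE) {
  branch_fwd(x, params, training)$y
}

branch_fwd <- function(x, params, training = FALSE) {
  k <- dim(params$w)[1]
  C <- fm_dim(x)[2]
  if (dim(params$w)[4] != C)
    stop(sprintf("channel mismatch: input has %d channels, branch kernel has %d",
                 C, dim(params$w)[4]))
  y0 <- conv_fwd(x, params$w, stride = 1L, pad = (k - 1L) %/% 2L, groups = C)
  bn <- bn2d_fwd(y0, params$bn, training)
  r <- relu_fwd(bn$y)
  list(y = r$y, cache = list(x = x, y0 = y0, bn = bn$cache, mask = r$cache, k = k),
       bn_p = bn$p)
}

branch_bwd <- function(params, cache, gy) {
  C <- dim(cache$x)[2]
  g <- relu_bwd(cache$mask, gy)
  b <- bn2d_bwd(cache$bn, g)
  cv <- conv_bwd(b$gx, cache$x, params$w, stride = 1L,
                 pad = (cache$k - 1L) %/% 2L, groups = C)
  list(gx = cv$gx,
       grads = list(w = cv$gw, bn = list(gamma = b$dgamma, beta = b$dbeta)))
}

## ---- fuse ------------------------------------------------------------------

#' Fuse-stage descriptor
#'
#' Element-wise sum of the two branch maps, global average pooling to a
#' per-sample channel vector `g`, per-sample standardization over channels
#' (population std, eps-stabilized), group-averaging to a `G`-vector, and a
#' fc + batch-norm + ReLU compression to the selection descriptor `g1`.
#'
#' @param y1,y2 branch feature maps of identical shape.
#' @param params fuse parameters (see [ska_params()]), plus `G`, `d`.
#' @param training batch-norm mode.
#' @param eps standardization stabilizer.
#' @return list with `g` (N x C pooled vector), `g_std` (standardized `g`)
#'   and `g1` (N x d compressed descriptor).
#' @export
fuse_descriptor <- function(y1, y2, params, training = FALSE, eps = 1e-5) {
  f <- fuse_fwd(y1, y2, params, training, eps)
  list(g = f$g, g_std = f$g_std, g1 = f$y)
}

fuse_fwd <- function(y1, y2, params, training = FALSE, eps = 1e-5) {
  check_same_shape(y1, y2, "branch maps")
  d4 <- fm_dim(y1)
  N <- d4[1]; C <- d4[2]
  G <- params$G; Cg <- C %/% G
  g <- gap_fwd(y1 + y2)                              # (N, C)
  st <- row_standardize(g, eps)
  gg <- colMeans(aperm(array(st$z, c(N, Cg, G)), c(2, 1, 3)))  # (N, G)
  lin <- gg %*% params$fuse$w                        # (N, d)
  bn <- bn1d_fwd(lin, params$fuse$bn, training)
  r <- relu_fwd(bn$y)
  list(y = r$y, g = g, g_std = st$z,
       cache = list(st = st, gg = gg, bn = bn$cache, mask = r$cache,
                    d4 = d4, G = G, Cg = Cg),
       bn_p = bn$p)
}

# returns gradient wrt y1 (== gradient wrt y2) plus fuse param grads
fuse_bwd <- function(params, cache, gy) {
  d4 <- cache$d4; N <- d4[1]; C <- d4[2]
  g <- relu_bwd(cache$mask, gy)
  b <- bn1d_bwd(cache$bn, g)
  dgg <- b$gx %*% t(params$fuse$w)                   # (N, G)
  dw <- crossprod(cache$gg, b$gx)
  dz <- matrix(aperm(array(dgg / cache$Cg, c(N, 1, cache$G))[, rep(1, cache$Cg), , drop = FALSE],
                     c(1, 2, 3)), N, C)
  dgvec <- row_standardize_bwd(cache$st$z, cache$st$invstd, dz)
  dy <- gap_bwd(dgvec, d4)                           # same for y1 and y2
  list(gy1 = dy,
       grads = list(w = dw, bn = list(gamma = b$dgamma, beta = b$dbeta)))
}

## ---- spatial group-wise enhancement ---------------------------------------

#' Spatial group-wise enhancement
#'
#' Splits channels into `G` groups; for each group, the spatial average
#' descriptor is dotted with the features at every position, the similarity
#' map is standardized over positions, scaled and shifted by the per-group
#' learnables, squashed by a sigmoid and applied as a spatial gate.
#'
#' @param y feature map (N, C, H, W) with C divisible by `G`.
#' @param gamma,beta per-group scale and shift, length `G`.
#' @param G number of channel groups.
#' @param eps standardization stabilizer.
#' @return gated feature map, same shape as `y`.
#' @export
sge_enhance <- function(y, gamma, beta, G, eps = 1e-5) {
  sge_fwd(y, gamma, beta, G, eps)$y
}

sge_fwd <- function(y, gamma, beta, G, eps = 1e-5) {
  d4 <- fm_dim(y)
  N <- d4[1]; C <- d4[2]; K <- d4[3] * d4[4]
  if (C %% G != 0)
    stop(sprintf("cardinality G = %d must divide the channel count C = %d", G, C))
  Cg <- C %/% G
  desc <- rowMeans(matrix(y, N * Cg * G, K))          # (n, j, g) spatial mean
  prod_ <- as.vector(y) * rep(desc, times = K)
  sim <- colSums(aperm(array(prod_, c(N, Cg, G * K)), c(2, 1, 3))) # (N, G*K)
  simm <- matrix(array(sim, c(N, G, K)), N * G, K)    # rows (n, g)
  st <- row_standardize(simm, eps)
  u <- st$z * rep(gamma, each = N) + rep(beta, each = N)
  a <- sigmoid(u)                                     # (N*G, K)
  a3 <- array(a, c(N, G, K))
  yp <- aperm(array(y, c(N, Cg, G, K)), c(1, 3, 4, 2))
  outp <- yp * as.vector(a3)
  out <- aperm(outp, c(1, 4, 2, 3))
  dim(out) <- d4
  list(y = out,
       cache = list(x = y, desc = desc, st = st, a = a, d4 = d4, G = G,
                    Cg = Cg, K = K))
}

sge_bwd <- function(cache, gy, gamma) {
  d4 <- cache$d4; N <- d4[1]; C <- d4[2]; K <- cache$K
  G <- cache$G; Cg <- cache$Cg
  x4 <- array(cache$x, c(N, Cg, G, K))
  g4 <- array(gy, c(N, Cg, G, K))
  a3 <- array(cache$a, c(N, G, K))
  # direct gate term
  ap <- aperm(array(as.vector(a3), c(N, G, K, 1))[, , , rep(1, Cg), drop = FALSE],
              c(1, 4, 2, 3))                          # (N, Cg, G, K)
  dx_direct <- g4 * ap
  # dL/da(n,g,k) = sum_j gy * x
  da <- colSums(aperm(array(g4 * x4, c(N, Cg, G * K)), c(2, 1, 3))) # (N, G*K)
  da <- matrix(array(da, c(N, G, K)), N * G, K)
  a <- cache$a
  du <- da * a * (1 - a)
  dgamma <- colSums(matrix(rowSums(du * cache$st$z), N, G))
  dbeta <- colSums(matrix(rowSums(du), N, G))
  dz <- du * rep(gamma, each = N)
  ds <- row_standardize_bwd(cache$st$z, cache$st$invstd, dz)  # (N*G, K)
  ds3 <- array(matrix(ds, N, G * K), c(N, G, K))
  dsp <- aperm(array(as.vector(ds3), c(N, G, K, 1))[, , , rep(1, Cg), drop = FALSE],
               c(1, 4, 2, 3))                         # (N, Cg, G, K)
  # s = sum_j d_j x_jk: direct x term + descriptor term
  dx_sim <- dsp * array(rep(cache$desc, times = K), c(N, Cg, G, K))
  ddesc <- rowSums(matrix(dsp * x4, N * Cg * G, K))
  dx_desc <- array(rep(ddesc / K, times = K), c(N, Cg, G, K))
  dx <- dx_direct + dx_sim + dx_desc
  dim(dx) <- d4
  list(gx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- aggregation -----------------------------------------------------------

#' Branch selection weights
#'
#' Maps the compressed fuse descriptor to two branch logits through a linear
#' head and normalizes them with a softmax across the branch dimension.
#'
#' @param g1 compressed descriptor, N x d matrix.
#' @param params list with `w` (d x 2) and `b` (length 2).
#' @return N x 2 matrix of selection weights; rows sum to 1.
#' @export
select_branch_weights <- function(g1, params) {
  softmax_rows(linear_fwd(as.matrix(g1), params$w, params$b))
}

#' Weighted aggregation of the two enhanced branches
#'
#' @param y1p,y2p enhanced branch maps of identical shape.
#' @param v N x 2 matrix of branch selection weights.
#' @return `v[, 1] * y1p + v[, 2] * y2p`, same shape as the inputs.
#' @export
aggregate_branches <- function(y1p, y2p, v) {
  check_same_shape(y1p, y2p, "branch maps")
  d <- fm_dim(y1p)
  if (nrow(as.matrix(v)) != d[1])
    stop("selection weights must have one row per sample")
  y <- as.vector(y1p) * v[, 1] + as.vector(y2p) * v[, 2]
  dim(y) <- d
  y
}

## ---- full module -----------------------------------------------------------

#' Apply a selective-kernel attention module
#'
#' Composition of the divide transforms (3x3 and 5x5 depthwise branches),
#' the fuse descriptor, per-branch spatial group-wise enhancement (when the
#' parameters carry it), the softmax selection head, and the weighted
#' aggregation. Output shape equals input shape.
#'
#' @param x feature map (N, C, H, W), C divisible by the module cardinality.
#' @param params parameters from [ska_params()].
#' @param training batch-norm mode.
#' @return feature map of the same shape as `x`.
#' @export
ska_module <- function(x, params, training = FALSE) {
  ska_fwd(x, params, training)$y
}

ska_fwd <- function(x, params, training = FALSE) {
  b1 <- branch_fwd(x, params$b1, training)
  b2 <- branch_fwd(x, params$b2, training)
  fu <- fuse_fwd(b1$y, b2$y, params, training)
  with_sge <- !is.null(params$sge1)
  if (with_sge) {
    s1 <- sge_fwd(b1$y, params$sge1$gamma, params$sge1$beta, params$G)
    s2 <- sge_fwd(b2$y, params$sge2$gamma, params$sge2$beta, params$G)
    y1p <- s1$y; y2p <- s2$y
  } else {
    s1 <- s2 <- NULL
    y1p <- b1$y; y2p <- b2$y
  }
  logits <- linear_fwd(fu$y, params$sel$w, params$sel$b)
  v <- softmax_rows(logits)
  y <- aggregate_branches(y1p, y2p, v)
  if (training) {
    params$b1$bn <- b1$bn_p
    params$b2$bn <- b2$bn_p
    params$fuse$bn <- fu$bn_p
  }
  list(y = y, v = v,
       cache = list(b1 = b1$cache, b2 = b2$cache, fu = fu$cache,
                    s1 = s1$cache, s2 = s2$cache, g1 = fu$y, v = v,
                    y1p = y1p, y2p = y2p, with_sge = with_sge),
       params = params)
}

ska_bwd <- function(params, cache, gy) {
  d4 <- dim(gy); N <- d4[1]
  gym <- matrix(gy, N, prod(d4[-1]))
  dv <- cbind(rowSums(gym * matrix(cache$y1p, N, prod(d4[-1]))),
              rowSums(gym * matrix(cache$y2p, N, prod(d4[-1]))))
  dy1p <- array(as.vector(gy) * cache$v[, 1], d4)
  dy2p <- array(as.vector(gy) * cache$v[, 2], d4)
  dlogits <- softmax_bwd(cache$v, dv)
  sel <- linear_bwd(dlogits, cache$g1, params$sel$w)
  fu <- fuse_bwd(params, cache$fu, sel$gx)
  grads <- list(sel = list(w = sel$gw, b = sel$gb), fuse = fu$grads)
  if (cache$with_sge) {
    s1 <- sge_bwd(cache$s1, dy1p, params$sge1$gamma)
    s2 <- sge_bwd(cache$s2, dy2p, params$sge2$gamma)
    dy1 <- s1$gx + fu$gy1
    dy2 <- s2$gx + fu$gy1
    grads$sge1 <- s1$grads
    grads$sge2 <- s2$grads
  } else {
    dy1 <- dy1p + fu$gy1
    dy2 <- dy2p + fu$gy1
  }
  bb1 <- branch_bwd(params$b1, cache$b1, dy1)
  bb2 <- branch_bwd(params$b2, cache$b2, dy2)
  grads$b1 <- bb1$grads
  grads$b2 <- bb2$grads
  list(gx = bb1$gx + bb2$gx, grads = grads)
}
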