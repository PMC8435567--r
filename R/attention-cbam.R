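# CBAM-style sequential channel / spatial gating used to strengthen the
# tapped feature maps before the auxiliary prediction heads.

#' Parameters of a CBAM layer
#'
#' @param C channel count of the gated feature map.
#' @param rho reduction ratio of the shared channel MLP (hidden width
#'   `max(1, C / rho)`).
#' @param init `"he"` or `"zeros"`.
#' @return nested parameter list (shared two-layer MLP and a 7x7, 2-to-1
#'   channel spatial convolution, all with biases).
#' @export
cbam_params <- function(C, rho = 16L, init = "he") {
  Ch <- max(1L, C %/% rho)
  z <- init == "zeros"
  list(
    mlp1 = list(w = if (z) matrix(0, C, Ch) else he_linear(C, Ch), b = rep(0, Ch)),
    mlp2 = list(w = if (z) matrix(0, Ch, C) else he_linear(Ch, C), b = rep(0, C)),
    conv = list(w = if (z) array(0, c(7L, 7L, 2L, 1L)) else he_conv(7L, 7L, 2L, 1L),
                b = 0),
    rho = as.integer(rho)
  )
}

#' Apply a CBAM layer
#'
#' Channel gate: `sigmoid(MLP(AvgPool F) + MLP(MaxPool F))` (shared MLP),
#' applied multiplicatively per channel; then spatial gate:
#' `sigmoid(conv7x7([AvgPool; MaxPool] over channels))` applied
#' multiplicatively per position. Output shape equals input shape and the
#' gates lie strictly inside (0, 1).
#'
#' @param f feature map (N, C, H, W).
#' @param params parameters from [cbam_params()].
#' @param return_gates also return the channel and spatial gate tensors.
#' @return the gated feature map, or (with `return_gates`) a list with
#'   `y`, `channel_gate` (N x C) and `spatial_gate` (N x H*W).
#' @export
cbam_layer <- function(f, params, return_gates = FALSE) {
  r <- cbam_fwd(f, params)
  if (return_gates)
    list(y = r$y, channel_gate = r$cache$Mc, spatial_gate = r$cache$Ms)
  else r$y
}

cbam_fwd <- function(f, params) {
  d4 <- fm_dim(f)
  N <- d4[1]; C <- d4[2]; HW <- d4[3] * d4[4]
  avg <- gap_fwd(f)
  fmat <- matrix(f, N * C, HW)
  mx_idx <- max.col(fmat, ties.method = "first")
  mx <- matrix(fmat[cbind(seq_len(N * C), mx_idx)], N, C)
  mlp_pass <- function(x) {
    h0 <- linear_fwd(x, params$mlp1$w, params$mlp1$b)
    r <- relu_fwd(h0)
    list(o = linear_fwd(r$y, params$mlp2$w, params$mlp2$b), h = r$y, mask = r$cache)
  }
  pa <- mlp_pass(avg)
  pm <- mlp_pass(mx)
  Mc <- sigmoid(pa$o + pm$o)                           # (N, C)
  f1 <- mul_channel(f, Mc)
  savg <- sum_channel(f1) / C                          # (N, HW)
  f1p <- aperm(array(f1, c(N, C, HW)), c(2, 1, 3))     # (C, N, HW)
  cmat <- matrix(f1p, C, N * HW)
  smax_idx <- max.col(t(cmat), ties.method = "first")  # argmax channel per (n,k)
  smax <- matrix(cmat[cbind(smax_idx, seq_len(N * HW))], N, HW)
  z2 <- array(0, c(N, 2L, d4[3], d4[4]))
  z2[, 1L, , ] <- array(savg, c(N, d4[3], d4[4]))
  z2[, 2L, , ] <- array(smax, c(N, d4[3], d4[4]))
  spre <- conv_fwd(z2, params$conv$w, bias = params$conv$b, stride = 1L, pad = 3L)
  Ms <- matrix(sigmoid(spre), N, HW)
  y <- mul_spatial(f1, Ms)
  list(y = y,
       cache = list(f = f, d4 = d4, avg = avg, mx = mx, mx_idx = mx_idx,
                    pa = pa, pm = pm, Mc = Mc, f1 = f1, z2 = z2, Ms = Ms,
                    smax_idx = smax_idx))
}

cbam_bwd <- function(params, cache, gy) {
  d4 <- cache$d4; N <- d4[1]; C <- d4[2]; HW <- d4[3] * d4[4]
  f <- cache$f; f1 <- cache$f1; Ms <- cache$Ms; Mc <- cache$Mc
  # spatial gate
  dF1 <- mul_spatial(gy, Ms)
  dMs <- sum_channel(gy * f1)
  dspre <- dMs * Ms * (1 - Ms)
  dim(dspre) <- c(N, 1L, d4[3], d4[4])
  cv <- conv_bwd(dspre, cache$z2, params$conv$w, stride = 1L, pad = 3L,
                 has_bias = TRUE)
  dz2 <- cv$gx
  dsavg <- matrix(dz2[, 1L, , ], N, HW)
  dsmax <- matrix(dz2[, 2L, , ], N, HW)
  # avg over channels
  f_avg <- aperm(array(dsavg / C, c(N, HW, C)), c(1, 3, 2))
  dim(f_avg) <- d4
  dF1 <- dF1 + f_avg
  # max over channels: scatter to argmax channel
  dF1m <- matrix(0, C, N * HW)
  dF1m[cbind(cache$smax_idx, seq_len(N * HW))] <- as.vector(dsmax)
  dF1s <- aperm(array(dF1m, c(C, N, HW)), c(2, 1, 3))
  dim(dF1s) <- d4
  dF1 <- dF1 + dF1s
  # channel gate
  dMc <- matrix(rowSums(matrix(dF1 * f, N * C, HW)), N, C)
  gF <- mul_channel(dF1, Mc)
  dpre <- dMc * Mc * (1 - Mc)
  mlp_bwd <- function(p, dpre) {
    l2 <- linear_bwd(dpre, p$h, params$mlp2$w)
    dh <- relu_bwd(p$mask, l2$gx)
    list(l2 = l2, dh = dh)
  }
  ba <- mlp_bwd(cache$pa, dpre)
  bm <- mlp_bwd(cache$pm, dpre)
  l1a <- linear_bwd(ba$dh, cache$avg, params$mlp1$w)
  l1m <- linear_bwd(bm$dh, cache$mx, params$mlp1$w)
  gF <- gF + gap_bwd(l1a$gx, d4)
  # channel-max scatter
  dmaxm <- matrix(0, N * C, HW)
  dmaxm[cbind(seq_len(N * C), cache$mx_idx)] <- as.vector(l1m$gx)
  dim(dmaxm) <- d4
  gF <- gF + dmaxm
  grads <- list(
    mlp1 = list(w = l1a$gw + l1m$gw, b = l1a$gb + l1m$gb),
    mlp2 = list(w = ba$l2$gw + bm$l2$gw, b = ba$l2$gb + bm$l2$gb),
    conv = list(w = cv$gw, b = cv$gb)
  )
  list(gx = gF, grads = grads)
}
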