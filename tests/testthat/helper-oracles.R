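# Independent brute-force oracles, written with plain loops and base R only.
# They re-derive the attention arithmetic from the defining equations and are
# deliberately kept separate from the package's vectorized/C++ implementation.

oracle_conv <- function(x, w, stride = 1, pad = 0, groups = 1) {
  d <- dim(x); wd <- dim(w)
  N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  KH <- wd[1]; KW <- wd[2]; Cg <- wd[3]; Cout <- wd[4]
  Ho <- (H + 2 * pad - KH) %/% stride + 1
  Wo <- (W + 2 * pad - KW) %/% stride + 1
  copg <- Cout / groups
  y <- array(0, c(N, Cout, Ho, Wo))
  for (n in 1:N) for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- 0
    cbase <- (ceiling(co / copg) - 1) * Cg
    for (ci in 1:Cg) for (kh in 1:KH) for (kw in 1:KW) {
      hi <- (ho - 1) * stride - pad + kh
      wi <- (wo - 1) * stride - pad + kw
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[n, cbase + ci, hi, wi] * w[kh, kw, ci, co]
    }
    y[n, co, ho, wo] <- acc
  }
  y
}

oracle_bn_eval <- function(x, bn, eps = 1e-5) {
  d <- dim(x)
  y <- x
  for (c in seq_len(d[2]))
    y[, c, , ] <- bn$gamma[c] * (x[, c, , ] - bn$rmean[c]) /
      sqrt(bn$rvar[c] + eps) + bn$beta[c]
  y
}

oracle_branch <- function(x, prm) {
  k <- dim(prm$w)[1]
  y <- oracle_conv(x, prm$w, pad = (k - 1) / 2, groups = dim(x)[2])
  pmax(oracle_bn_eval(y, prm$bn), 0)
}

oracle_sge <- function(y, gamma, beta, G, eps = 1e-5) {
  d <- dim(y); N <- d[1]; C <- d[2]; Cg <- C / G
  out <- y
  for (n in 1:N) for (g in 1:G) {
    ch <- ((g - 1) * Cg + 1):(g * Cg)
    grp <- array(y[n, ch, , ], c(Cg, d[3], d[4]))
    desc <- apply(grp, 1, mean)
    sim <- matrix(0, d[3], d[4])
    for (h in 1:d[3]) for (w in 1:d[4]) sim[h, w] <- sum(desc * grp[, h, w])
    mu <- mean(sim); v <- mean((sim - mu)^2)
    z <- (sim - mu) / sqrt(v + eps)
    gate <- 1 / (1 + exp(-(gamma[g] * z + beta[g])))
    for (j in seq_along(ch)) out[n, ch[j], , ] <- grp[j, , ] * gate
  }
  out
}

oracle_ska <- function(x, prm, eps = 1e-5) {
  y1 <- oracle_branch(x, prm$b1)
  y2 <- oracle_branch(x, prm$b2)
  d <- dim(x); N <- d[1]; C <- d[2]
  G <- prm$G; Cg <- C / G
  out <- array(0, d)
  # fuse: pooled, standardized, group-averaged, fc + BN + ReLU
  for (n in 1:N) {
    g <- sapply(1:C, function(c) mean(y1[n, c, , ] + y2[n, c, , ]))
    z <- (g - mean(g)) / sqrt(mean((g - mean(g))^2) + eps)
    gg <- sapply(1:G, function(k) mean(z[((k - 1) * Cg + 1):(k * Cg)]))
    lin <- as.vector(gg %*% prm$fuse$w)
    bn <- prm$fuse$bn
    g1 <- pmax(bn$gamma * (lin - bn$rmean) / sqrt(bn$rvar + eps) + bn$beta, 0)
    logit <- as.vector(g1 %*% prm$sel$w) + prm$sel$b
    v <- exp(logit - max(logit)); v <- v / sum(v)
    y1p <- if (!is.null(prm$sge1))
      oracle_sge(y1[n, , , , drop = FALSE], prm$sge1$gamma, prm$sge1$beta, G)
    else y1[n, , , , drop = FALSE]
    y2p <- if (!is.null(prm$sge2))
      oracle_sge(y2[n, , , , drop = FALSE], prm$sge2$gamma, prm$sge2$beta, G)
    else y2[n, , , , drop = FALSE]
    out[n, , , ] <- v[1] * y1p[1, , , ] + v[2] * y2p[1, , , ]
  }
  out
}

oracle_cbam <- function(f, prm) {
  d <- dim(f); N <- d[1]; C <- d[2]
  sig <- function(x) 1 / (1 + exp(-x))
  out <- f
  for (n in 1:N) {
    avg <- sapply(1:C, function(c) mean(f[n, c, , ]))
    mx <- sapply(1:C, function(c) max(f[n, c, , ]))
    mlp <- function(v) as.vector(
      pmax(as.vector(v %*% prm$mlp1$w) + prm$mlp1$b, 0) %*% prm$mlp2$w) +
      prm$mlp2$b
    mc <- sig(mlp(avg) + mlp(mx))
    f1 <- array(0, c(C, d[3], d[4]))
    for (c in 1:C) f1[c, , ] <- f[n, c, , ] * mc[c]
    savg <- apply(f1, c(2, 3), mean)
    smax <- apply(f1, c(2, 3), max)
    z <- array(0, c(1, 2, d[3], d[4]))
    z[1, 1, , ] <- savg; z[1, 2, , ] <- smax
    sp <- oracle_conv(z, prm$conv$w, pad = 3)[1, 1, , ] + prm$conv$b
    ms <- sig(sp)
    for (c in 1:C) out[n, c, , ] <- f1[c, , ] * ms
  }
  out
}

oracle_kl <- function(pa, pb, eps = 1e-8) {
  tot <- 0
  for (i in seq_len(nrow(pa))) for (j in seq_len(ncol(pa))) {
    a <- max(pa[i, j], eps); b <- max(pb[i, j], eps)
    tot <- tot + a * log(a / b)
  }
  tot / nrow(pa)
}

oracle_ce_mean <- function(p3, p4, p, labels) {
  tot <- 0
  for (i in seq_along(labels)) {
    q <- (p3[i, labels[i]] + p4[i, labels[i]] + p[i, labels[i]]) / 3
    tot <- tot - log(q)
  }
  tot / length(labels)
}
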