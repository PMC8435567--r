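# Multi-scale regularizer: CBAM-strengthened auxiliary heads on the stage-3
# and stage-4 taps, KL-divergence matching between the three prediction
# distributions, and the combined training objective.

#' Multi-scale regularizer configuration
#'
#' @param strategies subset of `"P3+P4"`, `"P+P4"`, `"P3+P"`. Strategy
#'   `"A+B"` encourages distribution A to match B by minimizing `KL(B || A)`
#'   pairs as follows: `P3+P4` adds `KL(P4 || P3)`, `P+P4` adds
#'   `KL(P4 || P)`, `P3+P` adds `KL(P || P3)`. The default full set performs
#'   best in the ablation grid.
#' @param alpha nonnegative weight of the regularizer in the total loss.
#' @param epsilon probability floor applied inside logarithms, in (0, 1e-4].
#' @return an object of class `msl_config`.
#' @export
msl_config <- function(strategies = c("P3+P4", "P+P4", "P3+P"), alpha = 1,
                       epsilon = 1e-8) {
  if (length(strategies) && !all(strategies %in% c("P3+P4", "P+P4", "P3+P")))
    stop("strategies must be a subset of {P3+P4, P+P4, P3+P}")
  if (alpha < 0) stop("alpha must be >= 0")
  if (epsilon <= 0 || epsilon > 1e-4) stop("epsilon must lie in (0, 1e-4]")
  structure(list(strategies = unique(strategies), alpha = alpha,
                 epsilon = epsilon), class = "msl_config")
}

#' The six matching-strategy sets of the ablation grid
#'
#' @return named list of the three single and three combined strategy sets.
#' @export
msl_strategy_sets <- function() {
  list(`P+P4` = "P+P4",
       `P3+P4` = "P3+P4",
       `P3+P` = "P3+P",
       `P3+P4,P+P4` = c("P3+P4", "P+P4"),
       `P3+P4,P3+P` = c("P3+P4", "P3+P"),
       `P3+P4,P+P4,P3+P` = c("P3+P4", "P+P4", "P3+P"))
}

check_pred_dist <- function(p, tol = 1e-5, what = "prediction distribution") {
  p <- as.matrix(p)
  if (any(p < -tol)) stop(sprintf("%s has negative entries", what))
  if (any(abs(rowSums(p) - 1) > tol))
    stop(sprintf("%s rows must sum to 1 (tolerance %g)", what, tol))
  p
}

#' Head prediction distributions
#'
#' `P3` and `P4` come from CBAM-gated taps pooled and classified by their own
#' fc layers; `P` is the softmax of the main-head logits.
#'
#' @param bundle output of [forward_features()].
#' @param msl_params auxiliary-head parameters (`cbam3`, `fc3`, `cbam4`,
#'   `fc4`), e.g. from a [build_model()] with `msl = TRUE` (`model$msl`).
#' @return list of N x C probability matrices `P3`, `P4`, `P`.
#' @export
head_predictions <- function(bundle, msl_params) {
  r <- heads_fwd(msl_params, bundle$F3, bundle$F4, bundle$logits)
  r[c("P3", "P4", "P")]
}

heads_fwd <- function(msl, F3, F4, logits) {
  aux <- function(f, cb, fc) {
    cf <- cbam_fwd(f, cb)
    pooled <- gap_fwd(cf$y)
    z <- linear_fwd(pooled, fc$w, fc$b)
    p <- softmax_rows(z)
    list(p = p, cache = list(cbam = cf$cache, ydim = dim(cf$y), pooled = pooled))
  }
  a3 <- aux(F3, msl$cbam3, msl$fc3)
  a4 <- aux(F4, msl$cbam4, msl$fc4)
  if (ncol(a3$p) != ncol(logits) || ncol(a4$p) != ncol(logits))
    stop("auxiliary and main heads disagree on the class count")
  list(P3 = a3$p, P4 = a4$p, P = softmax_rows(logits),
       cache = list(a3 = a3$cache, a4 = a4$cache))
}

# dP3/dP4 are gradients w.r.t. the head probability matrices; returns the
# gradients injected at the two tap points plus auxiliary-head param grads.
heads_bwd <- function(msl, cache, P3, P4, dP3, dP4) {
  aux_bwd <- function(cb, fc, ca, p, dp) {
    dz <- softmax_bwd(p, dp)
    l <- linear_bwd(dz, ca$pooled, fc$w)
    dy <- gap_bwd(l$gx, ca$ydim)
    cbb <- cbam_bwd(cb, ca$cbam, dy)
    list(gF = cbb$gx, fc = list(w = l$gw, b = l$gb), cbam = cbb$grads)
  }
  b3 <- aux_bwd(msl$cbam3, msl$fc3, cache$a3, P3, dP3)
  b4 <- aux_bwd(msl$cbam4, msl$fc4, cache$a4, P4, dP4)
  list(dF3 = b3$gF, dF4 = b4$gF,
       grads = list(cbam3 = b3$cbam, fc3 = b3$fc,
                    cbam4 = b4$cbam, fc4 = b4$fc))
}

#' KL-divergence between prediction distributions
#'
#' Batch-averaged Kullback-Leibler divergence `KL(Pa || Pb)`, in nats:
#' `(1/N) * sum_i sum_j pa_ij * log(pa_ij / pb_ij)`, with both arguments
#' floored at `eps` inside the logarithm.
#'
#' @param pa,pb N x C probability matrices (rows sum to 1).
#' @param eps probability floor.
#' @return a nonnegative scalar; zero iff `pa == pb` row-wise.
#' @export
kl_match <- function(pa, pb, eps = 1e-8) {
  pa <- check_pred_dist(pa); pb <- check_pred_dist(pb)
  if (!all(dim(pa) == dim(pb))) stop("distributions must share dimensions")
  af <- pmax(pa, eps); bf <- pmax(pb, eps)
  sum(af * log(af / bf)) / nrow(pa)
}

# gradients of kl_match w.r.t. both arguments (no stop-gradient on either)
kl_match_grads <- function(pa, pb, eps = 1e-8) {
  N <- nrow(pa)
  af <- pmax(pa, eps); bf <- pmax(pb, eps)
  list(dpa = (log(af / bf) + 1) / N, dpb = -(af / bf) / N)
}

#' Multi-scale matching loss
#'
#' Sum of the KL terms selected by the strategy set (see [msl_config()]);
#' an empty strategy set gives 0.
#'
#' @param p3,p4,p the three head distributions.
#' @param cfg an [msl_config()].
#' @return nonnegative scalar, in nats.
#' @export
msl_loss <- function(p3, p4, p, cfg = msl_config()) {
  tot <- 0
  for (s in cfg$strategies)
    tot <- tot + switch(s,
      "P3+P4" = kl_match(p4, p3, cfg$epsilon),
      "P+P4" = kl_match(p4, p, cfg$epsilon),
      "P3+P" = kl_match(p, p3, cfg$epsilon))
  tot
}

msl_loss_grads <- function(p3, p4, p, cfg = msl_config()) {
  z <- function(m) array(0, dim(m))
  d3 <- z(p3); d4 <- z(p4); dp <- z(p)
  for (s in cfg$strategies) {
    if (s == "P3+P4") {
      g <- kl_match_grads(p4, p3, cfg$epsilon); d4 <- d4 + g$dpa; d3 <- d3 + g$dpb
    } else if (s == "P+P4") {
      g <- kl_match_grads(p4, p, cfg$epsilon); d4 <- d4 + g$dpa; dp <- dp + g$dpb
    } else if (s == "P3+P") {
      g <- kl_match_grads(p, p3, cfg$epsilon); dp <- dp + g$dpa; d3 <- d3 + g$dpb
    }
  }
  list(d3 = d3, d4 = d4, dp = dp)
}

#' Classification loss over the three heads
#'
#' Cross-entropy of the mean distribution `(P3 + P4 + P) / 3` against the
#' one-hot labels, averaged over the batch. The literal summed form
#' (`P3 + P4 + P`, total mass 3) is available behind `literal_sum = TRUE`
#' for comparison; it can turn negative at confident agreement.
#'
#' @param p3,p4,p the three head distributions.
#' @param labels integer class labels in `1..C`.
#' @param eps probability floor inside the log.
#' @param literal_sum use the unnormalized summed argument.
#' @return scalar cross-entropy (nats).
#' @export
classification_loss <- function(p3, p4, p, labels, eps = 1e-8,
                                literal_sum = FALSE) {
  C <- ncol(p)
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > C))
    stop(sprintf("labels must lie in 1..%d", C))
  q <- if (literal_sum) p3 + p4 + p else (p3 + p4 + p) / 3
  -mean(log(pmax(q[cbind(seq_along(labels), labels)], eps)))
}

classification_loss_grads <- function(p3, p4, p, labels, eps = 1e-8,
                                      literal_sum = FALSE) {
  N <- nrow(p)
  q <- if (literal_sum) p3 + p4 + p else (p3 + p4 + p) / 3
  idx <- cbind(seq_len(N), as.integer(labels))
  dq <- array(0, dim(p))
  dq[idx] <- -1 / (pmax(q[idx], eps) * N)
  dk <- if (literal_sum) dq else dq / 3
  list(d3 = dk, d4 = dk, dp = dk)
}

#' Combined objective
#'
#' @param cls classification loss.
#' @param msl matching loss.
#' @param cfg an [msl_config()] (supplies `alpha`).
#' @return list of class `loss_values` with `cls`, `msl`,
#'   `total = cls + alpha * msl`.
#' @export
total_loss <- function(cls, msl, cfg = msl_config()) {
  if (!is.finite(cls) || !is.finite(msl)) stop("loss components must be finite")
  structure(list(cls = cls, msl = msl, total = cls + cfg$alpha * msl),
            class = "loss_values")
}
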