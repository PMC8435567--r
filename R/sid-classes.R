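# Parametric silhouette geometry for the 19 instrument classes. Each builder
# returns a capsule list (n x 6 matrix: x0, y0, x1, y1, half-width at each
# end, unit-square coordinates, tool axis along +x) with a "tip_bbox"
# attribute marking the fore-end region in which fine-grained partners
# differ. The grammar is deliberately schematic: the dataset contract is the
# class count, per-class counts, open/closed states, side-view angles, the
# near-black background and the fine-grained-pair structure - not
# photo-realism.

seg_ <- function(x0, y0, x1, y1, w0, w1 = w0) c(x0, y0, x1, y1, w0, w1)

ring_ <- function(cx, cy, r, w, n = 18L) {
  a <- seq(0, 2 * pi, length.out = n + 1L)
  x <- cx + r * cos(a); y <- cy + r * sin(a)
  cbind(x[-(n + 1L)], y[-(n + 1L)], x[-1L], y[-1L], w, w)
}

arc_ <- function(cx, cy, r, a0, a1, w0, w1, n = 10L) {
  a <- seq(a0, a1, length.out = n + 1L)
  x <- cx + r * cos(a); y <- cy + r * sin(a)
  w <- seq(w0, w1, length.out = n + 1L)
  cbind(x[-(n + 1L)], y[-(n + 1L)], x[-1L], y[-1L], w[-(n + 1L)], w[-1L])
}

rbindseg <- function(...) {
  m <- do.call(rbind, lapply(list(...), function(s)
    if (is.matrix(s)) s else matrix(s, 1L)))
  colnames(m) <- c("x0", "y0", "x1", "y1", "w0", "w1")
  m
}

with_tip <- function(m, bbox) { attr(m, "tip_bbox") <- bbox; m }

# Ring-handled clamp family: rings, crossed shanks, box lock, jaws whose
# fore-end style carries the fine-grained identity.
build_forceps <- function(p, state) {
  open <- identical(state, "open")
  px <- 0.46                                   # pivot
  ringy <- 0.055
  rings <- rbind(ring_(0.115, 0.5 + ringy, 0.042, 0.010),
                 ring_(0.115, 0.5 - ringy, 0.042, 0.010))
  shanks <- rbind(seg_(0.155, 0.5 + ringy, px, 0.5 + 0.008, 0.011, 0.009),
                  seg_(0.155, 0.5 - ringy, px, 0.5 - 0.008, 0.011, 0.009))
  lock <- seg_(px - 0.012, 0.5, px + 0.012, 0.5, 0.016, 0.016)
  jl <- p$jaw_len
  gap <- if (open) p$open_gap else p$closed_gap
  bend <- p$jaw_bend * pi / 180
  jaw <- function(s) {                         # s = +1 upper, -1 lower
    y0 <- 0.5 + s * 0.008
    mid <- c(px + jl * 0.5 * cos(bend * 0.5), y0 + s * gap * 0.5 +
               jl * 0.5 * sin(bend * 0.5))
    tip <- c(mid[1] + jl * 0.5 * cos(bend), mid[2] + s * gap * 0.5 +
               jl * 0.5 * sin(bend))
    rbind(seg_(px, y0, mid[1], mid[2], 0.009, p$jaw_w),
          seg_(mid[1], mid[2], tip[1], tip[2], p$jaw_w, p$tip_w))
  }
  ju <- jaw(1); jd <- jaw(-1)
  tipx <- max(ju[, 3], jd[, 3])
  segs <- rbindseg(rings, shanks, lock, ju, jd)
  # fore-end styles
  if (p$tip_style == "round_loop") {
    segs <- rbindseg(segs, arc_(tipx + 0.016, 0.5, 0.020 + p$tip_round * 0.016,
                                -pi, pi, 0.008, 0.008, 12L))
    tipx <- tipx + 0.052
  } else if (p$tip_style == "teeth") {
    tx <- tipx
    segs <- rbindseg(segs,
                     seg_(tx, 0.5 + 0.026, tx + 0.030, 0.5, 0.005, 0.002),
                     seg_(tx, 0.5 - 0.026, tx + 0.030, 0.5, 0.005, 0.002),
                     seg_(tx + 0.008, 0.5 + 0.020, tx + 0.034, 0.5, 0.004, 0.002),
                     seg_(tx + 0.008, 0.5 - 0.020, tx + 0.034, 0.5, 0.004, 0.002))
    tipx <- tipx + 0.034
  } else if (p$tip_style == "oval_loop") {
    segs <- rbindseg(segs, arc_(tipx + 0.035, 0.5, 0.040, -pi, pi,
                                0.008, 0.008, 14L))
    tipx <- tipx + 0.075
  } else if (p$tip_style == "point") {
    segs <- rbindseg(segs,
                     arc_(tipx, 0.5 + 0.030, 0.030, -pi / 2, pi / 2, 0.006, 0.002, 6L),
                     arc_(tipx, 0.5 - 0.030, 0.030, pi / 2, 3 * pi / 2, 0.002, 0.006, 6L))
  } else if (p$tip_style == "serrated") {
    for (k in 1:3) {
      tx <- px + jl * (0.4 + 0.2 * k)
      segs <- rbindseg(segs, seg_(tx, 0.5 - 0.012, tx, 0.5 + 0.012, 0.003))
    }
  }
  with_tip(segs, c(px + jl * 0.55, tipx + 0.08, 0.36, 0.64))
}

# Ring-handled scissors; tip curvature separates the curved / straight pair.
build_scissors <- function(p, state) {
  open <- identical(state, "open")
  px <- 0.48
  half <- if (open) p$open_deg else p$closed_deg
  rings <- rbind(ring_(0.13, 0.56, 0.045, 0.011),
                 ring_(0.13, 0.44, 0.045, 0.011))
  shanks <- rbind(seg_(0.17, 0.555, px, 0.505, 0.012, 0.012),
                  seg_(0.17, 0.445, px, 0.495, 0.012, 0.012))
  blade <- function(s) {
    a0 <- s * half * pi / 180
    bl <- p$blade_len
    straight <- bl * (1 - p$tip_frac)
    m <- c(px + straight * cos(a0), 0.5 + straight * sin(a0))
    b1 <- seg_(px, 0.5, m[1], m[2], p$blade_w, p$blade_w * 0.55)
    # curved fore-end: deflect the remaining blade by tip_curve degrees
    a1 <- a0 + p$tip_curve * pi / 180
    t1 <- c(m[1] + bl * p$tip_frac * 0.6 * cos((a0 + a1) / 2),
            m[2] + bl * p$tip_frac * 0.6 * sin((a0 + a1) / 2))
    t2 <- c(t1[1] + bl * p$tip_frac * 0.4 * cos(a1),
            t1[2] + bl * p$tip_frac * 0.4 * sin(a1))
    rbind(b1, seg_(m[1], m[2], t1[1], t1[2], p$blade_w * 0.55, p$blade_w * 0.3),
          seg_(t1[1], t1[2], t2[1], t2[2], p$blade_w * 0.3, 0.002))
  }
  segs <- rbindseg(rings, shanks, seg_(px, 0.5, px, 0.5, 0.015), blade(1), blade(-1))
  xt <- px + p$blade_len * (1 - p$tip_frac)
  with_tip(segs, c(xt - 0.02, 1.0, 0.30, 0.70))
}

# Spring tweezers: two arms meeting at the base; the tip treatment separates
# the dressing / tissue pair.
build_tweezers <- function(p, state) {
  open <- identical(state, "open")
  sep <- if (open) p$open_sep else 0.012
  base <- c(0.12, 0.5)
  al <- p$arm_len
  arm <- function(s) {
    tip <- c(base[1] + al, 0.5 + s * sep)
    rbind(seg_(base[1], base[2] + s * 0.004, base[1] + al * 0.35,
               0.5 + s * (0.004 + 0.55 * sep), 0.013, 0.011),
          seg_(base[1] + al * 0.35, 0.5 + s * (0.004 + 0.55 * sep),
               tip[1], tip[2], 0.011, p$tip_w))
  }
  segs <- rbindseg(seg_(base[1] - 0.015, 0.5, base[1], 0.5, 0.012),
                   arm(1), arm(-1))
  tipx <- base[1] + al
  if (p$tip_teeth) {
    segs <- rbindseg(segs,
                     seg_(tipx, 0.5 + sep, tipx + 0.022, 0.5 + sep - 0.012, p$tip_w, 0.002),
                     seg_(tipx, 0.5 - sep, tipx + 0.022, 0.5 - sep + 0.012, p$tip_w, 0.002))
  }
  with_tip(segs, c(tipx - 0.03, tipx + 0.06, 0.40, 0.60))
}

build_hook <- function(p, state) {
  if (p$style == "s") {
    segs <- rbindseg(seg_(0.30, 0.5, 0.70, 0.5, 0.016),
                     arc_(0.30, 0.5 + 0.085, 0.085, pi / 2, 3 * pi / 2, 0.022, 0.016, 12L),
                     arc_(0.70, 0.5 - 0.085, 0.085, pi / 2, -pi / 2, 0.016, 0.022, 12L))
    return(with_tip(segs, c(0.58, 0.92, 0.30, 0.62)))
  }
  if (p$style == "abdominal") {
    segs <- rbindseg(seg_(0.10, 0.5, 0.72, 0.5, 0.013),
                     ring_(0.085, 0.5, 0.030, 0.010),
                     seg_(0.72, 0.5, 0.78, 0.5, 0.013, 0.030),
                     arc_(0.78, 0.5 - 0.075, 0.075, pi / 2, -pi / 6, 0.030, 0.012, 10L))
    return(with_tip(segs, c(0.70, 0.95, 0.30, 0.62)))
  }
  # slender tissue hook
  segs <- rbindseg(seg_(0.10, 0.5, 0.80, 0.5, 0.008, 0.006),
                   seg_(0.085, 0.47, 0.085, 0.53, 0.010),
                   arc_(0.80, 0.5 - 0.028, 0.028, pi / 2, -pi / 3, 0.006, 0.002, 8L))
  with_tip(segs, c(0.76, 0.90, 0.40, 0.60))
}

build_simple <- function(p, state) {
  if (p$style == "tube") {
    segs <- rbindseg(seg_(0.08, 0.5, 0.60, 0.5, 0.017),
                     seg_(0.60, 0.5, 0.88, 0.545, 0.017, 0.013),
                     ring_(0.075, 0.5, 0.032, 0.012, 14L))
    return(with_tip(segs, c(0.80, 0.95, 0.46, 0.64)))
  }
  if (p$style == "plate") {
    segs <- rbindseg(arc_(0.5, 0.05, 0.47, pi / 2 - 0.72, pi / 2 + 0.72,
                          0.046, 0.046, 14L))
    return(with_tip(segs, c(0.80, 1.0, 0.35, 0.65)))
  }
  if (p$style == "spatula") {
    segs <- rbindseg(seg_(0.08, 0.5, 0.42, 0.5, 0.012),
                     seg_(0.42, 0.5, 0.86, 0.5, 0.020, 0.052))
    return(with_tip(segs, c(0.76, 0.95, 0.40, 0.60)))
  }
  # scalpel-style flat holder
  segs <- rbindseg(seg_(0.10, 0.5, 0.62, 0.5, 0.015),
                   seg_(0.44, 0.485, 0.50, 0.485, 0.006),
                   seg_(0.62, 0.5, 0.88, 0.5, 0.011, 0.006))
  with_tip(segs, c(0.80, 0.93, 0.44, 0.56))
}

# Integrated (spring-handle) scissors: one-piece arms plus straight blades.
build_spring_scissors <- function(p, state) {
  open <- identical(state, "open")
  half <- if (open) 7 else 2
  px <- 0.50
  segs <- rbindseg(
    arc_(0.16, 0.5, 0.060, pi / 2, 3 * pi / 2, 0.013, 0.013, 10L),
    seg_(0.16, 0.56, px, 0.506, 0.013, 0.013),
    seg_(0.16, 0.44, px, 0.494, 0.013, 0.013),
    seg_(px, 0.5 + 0.006, px + 0.33, 0.5 + 0.33 * sin(half * pi / 180), 0.015, 0.002),
    seg_(px, 0.5 - 0.006, px + 0.33, 0.5 - 0.33 * sin(half * pi / 180), 0.015, 0.002))
  with_tip(segs, c(px + 0.22, 0.95, 0.38, 0.62))
}

#' Class specifications of the synthetic instrument dataset
#'
#' Nineteen named tool classes covering clamp, scissors, tweezers, hook and
#' plate/tube families. Fine-grained partners share a family builder and
#' differ only in designated fore-end parameters (tip roundness, tip
#' curvature, jaw bend, tip teeth).
#'
#' @return named list of class specs (name, family, params, states,
#'   fine-grained partner).
#' @export
sid_class_specs <- function() {
  fp <- function(style, jaw_len = 0.30, jaw_bend = 0, tip_round = 0,
                 jaw_w = 0.008, tip_w = 0.004, open_gap = 0.075,
                 closed_gap = 0.012)
    list(tip_style = style, jaw_len = jaw_len, jaw_bend = jaw_bend,
         tip_round = tip_round, jaw_w = jaw_w, tip_w = tip_w,
         open_gap = open_gap, closed_gap = closed_gap)
  sc <- function(tip_curve, blade_len = 0.34, blade_w = 0.014,
                 open_deg = 11, closed_deg = 2.2, tip_frac = 0.45)
    list(tip_curve = tip_curve, blade_len = blade_len, blade_w = blade_w,
         open_deg = open_deg, closed_deg = closed_deg, tip_frac = tip_frac)
  tw <- function(teeth, arm_len = 0.70, tip_w = 0.006, open_sep = 0.055)
    list(tip_teeth = teeth, arm_len = arm_len, tip_w = tip_w,
         open_sep = open_sep)
  cls <- function(name, family, params, stateful = FALSE, partner = NA_character_)
    list(name = name, family = family, params = params,
         states = if (stateful) c("open", "closed") else "none",
         partner = partner)
  specs <- list(
    cls("Abdominal wall hook", "hook", list(style = "abdominal")),
    cls("Alice forceps", "forceps", fp("teeth"), TRUE, "Appendix forceps"),
    cls("Appendix forceps", "forceps", fp("round_loop", tip_round = 1), TRUE,
        "Alice forceps"),
    cls("Attraction tube", "simple", list(style = "tube")),
    cls("Bending plate", "simple", list(style = "plate")),
    cls("Curved tip surgical scissors", "scissors", sc(tip_curve = 55), TRUE,
        "Straight tip surgical scissors"),
    cls("Dressing tweezers", "tweezers", tw(FALSE), TRUE, "Tissue tweezers"),
    cls("Elbow hemostatic forceps", "forceps",
        fp("serrated", jaw_len = 0.26, jaw_bend = 38), TRUE,
        "Straight hemostatic forceps"),
    cls("Integrated tissue scissors", "spring_scissors", list(), TRUE),
    cls("Intestinal tract", "simple", list(style = "spatula")),
    cls("Needle holder", "forceps",
        fp("plain", jaw_len = 0.14, jaw_w = 0.011, tip_w = 0.007,
           open_gap = 0.045)),
    cls("No.4 tool holder", "simple", list(style = "holder")),
    cls("Oval forceps", "forceps", fp("oval_loop", jaw_len = 0.18), TRUE),
    cls("Pad towel forceps", "forceps", fp("point", jaw_len = 0.20), TRUE),
    cls("S deep pull hook", "hook", list(style = "s")),
    cls("Straight hemostatic forceps", "forceps",
        fp("serrated", jaw_len = 0.26, jaw_bend = 0), TRUE,
        "Elbow hemostatic forceps"),
    cls("Straight tip surgical scissors", "scissors", sc(tip_curve = 0), TRUE,
        "Curved tip surgical scissors"),
    cls("Tissue hook", "hook", list(style = "tissue")),
    cls("Tissue tweezers", "tweezers", tw(TRUE), TRUE, "Dressing tweezers")
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

instrument_skeleton <- function(spec, state) {
  switch(spec$family,
         forceps = build_forceps(spec$params, state),
         scissors = build_scissors(spec$params, state),
         spring_scissors = build_spring_scissors(spec$params, state),
         tweezers = build_tweezers(spec$params, state),
         hook = build_hook(spec$params, state),
         simple = build_simple(spec$params, state),
         stop(sprintf("unknown instrument family '%s'", spec$family)))
}
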