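# Shared fixtures built in code.

# Binary image with a filled axis-aligned square of side `side` whose
# top-left corner is at continuous (x0, y0); pixel centers inside count.
square_image <- function(n = 64, x0 = 22, y0 = 22, side = 20,
                         angle_deg = 0) {
  xs <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - 0.5, n, n)
  cx <- x0 + side / 2; cy <- y0 + side / 2
  t <- angle_deg * pi / 180
  xr <- (xs - cx) * cos(t) + (ys - cy) * sin(t)
  yr <- -(xs - cx) * sin(t) + (ys - cy) * cos(t)
  (abs(xr) <= side / 2 & abs(yr) <= side / 2) * 1
}

# Continuous corner positions of the square above, order SL, SR, IL, IR.
square_corners <- function(x0 = 22, y0 = 22, side = 20, angle_deg = 0) {
  cx <- x0 + side / 2; cy <- y0 + side / 2
  t <- angle_deg * pi / 180
  off <- rbind(c(-1, -1), c(1, -1), c(-1, 1), c(1, 1)) * side / 2
  rot <- cbind(c(cos(t), sin(t)), c(-sin(t), cos(t)))
  sweep(off %*% t(rot), 2, c(cx, cy), "+")
}

# Nearest-candidate distance for every reference point.
nearest_dist <- function(ref_xy, cand) {
  apply(ref_xy, 1, function(p)
    min(sqrt((cand$x - p[1])^2 + (cand$y - p[2])^2)))
}

# Corner-set recovery error against a phantom's true corners (pixels).
corner_errors <- function(true_cs, detected_cs) {
  m <- merge(as.data.frame(true_cs), as.data.frame(detected_cs),
             by = "corner")
  sqrt((m$x.x - m$x.y)^2 + (m$y.x - m$y.y)^2)
}

# Independent PR-staircase enumeration: given ranked TP flags and the
# ground-truth count, integrate max precision at recall >= r over the
# distinct recall levels.
staircase_ap <- function(tp_flags, n_gt) {
  prec <- cumsum(tp_flags) / seq_along(tp_flags)
  rec <- cumsum(tp_flags) / n_gt
  ap <- 0
  prev_r <- 0
  for (r in unique(rec[tp_flags])) {
    ap <- ap + (r - prev_r) * max(prec[rec >= r])
    prev_r <- r
  }
  ap
}

# Predictions equal to ground truth at full confidence.
gt_then_conf <- function(gt_sets) {
  lapply(gt_sets, function(g) { g$confidence <- 1; g })
}

# Independent shoelace polygon area.
shoelace <- function(x, y) {
  n <- length(x); j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
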