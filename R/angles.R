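#' Lordosis grading thresholds
#'
#' Normal lumbar lordosis spans lumbar lordotic angles of 39 to 53 degrees;
#' smaller angles are hypolordotic, larger ones hyperlordotic. Both
#' boundaries belong to the normal class.
#'
#' @param low,high Class boundaries in degrees, `0 < low < high < 90`.
#' @return A list of class `"grade_thresholds"`.
#' @export
grade_thresholds <- function(low = 39, high = 53) {
  stopifnot(low > 0, high > low, high < 90)
  structure(list(low = low, high = high), class = "grade_thresholds")
}

#' Slope of the line through two points
#'
#' `(p2y - p1y) / (p2x - p1x)`; returns the string `"vertical"` when the
#' horizontal separation is below 1e-12. Symmetric under argument swap.
#'
#' @param p1,p2 Numeric `c(x, y)` points; must differ.
#' @return A number, or `"vertical"`.
#' @export
slope <- function(p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2)
  dx <- p2[[1]] - p1[[1]]
  dy <- p2[[2]] - p1[[2]]
  if (abs(dx) < 1e-12 && abs(dy) < 1e-12)
    stop("slope undefined for identical points")
  if (abs(dx) < 1e-12) return("vertical")
  unname(dy / dx)
}

slope_direction <- function(m) {
  if (identical(m, "vertical")) c(0, 1) else c(1, as.numeric(m))
}

angle_between_directions <- function(d1, d2) {
  cross <- abs(d1[1] * d2[2] - d1[2] * d2[1])
  dot <- abs(d1[1] * d2[1] + d1[2] * d2[2])
  atan2(cross, dot) * 180 / pi
}

#' Acute angle between two lines given by their slopes
#'
#' The textbook formula is `atan |(m1 - m2) / (1 + m1 m2)|`; it is computed
#' here through direction vectors and `atan2`, so vertical lines and
#' near-perpendicular pairs (`1 + m1 m2 -> 0`) are handled exactly. The
#' result is the acute angle in degrees, in `[0, 90]`, symmetric in its
#' arguments.
#'
#' @param m1,m2 Slopes (numbers) or the string `"vertical"`.
#' @return Angle in degrees.
#' @export
angle_between <- function(m1, m2) {
  angle_between_directions(slope_direction(m1), slope_direction(m2))
}

endplate_points <- function(cs, side) {
  stopifnot(inherits(cs, "corner_set"))
  p1 <- corner_point(cs, paste0(side, "_left"))
  p2 <- corner_point(cs, paste0(side, "_right"))
  if (sqrt(sum((p2 - p1)^2)) < 1e-9)
    stop(sprintf("degenerate %s endplate: coincident corners", side))
  list(p1 = p1, p2 = p2)
}

endplate_angle <- function(ep_a, ep_b) {
  angle_between_directions(ep_a$p2 - ep_a$p1, ep_b$p2 - ep_b$p1)
}

#' Lumbar lordotic angle (LLA)
#'
#' The LLA is the acute angle between the superior endplate of L1 (the
#' line through its superior-left and superior-right corners) and the
#' superior endplate of the sacrum.
#'
#' @param corners_l1,corners_s `"corner_set"` objects for L1 and S.
#' @return List with `angle_deg`, and the endplate slopes `m_l1`, `m_s`
#'   (numbers or `"vertical"`).
#' @export
compute_lla <- function(corners_l1, corners_s) {
  a <- endplate_points(corners_l1, "superior")
  b <- endplate_points(corners_s, "superior")
  list(angle_deg = endplate_angle(a, b),
       m_l1 = slope(a$p1, a$p2), m_s = slope(b$p1, b$p2))
}

#' Lumbosacral angle (LSA)
#'
#' The LSA is the acute angle between the inferior endplate of L5 and the
#' superior endplate of the sacrum.
#'
#' @param corners_l5,corners_s `"corner_set"` objects for L5 and S.
#' @return List with `angle_deg`, `m_l5_inf`, `m_s`.
#' @export
compute_lsa <- function(corners_l5, corners_s) {
  a <- endplate_points(corners_l5, "inferior")
  b <- endplate_points(corners_s, "superior")
  list(angle_deg = endplate_angle(a, b),
       m_l5_inf = slope(a$p1, a$p2), m_s = slope(b$p1, b$p2))
}

#' Grade lumbar lordosis from the LLA
#'
#' Angles below `low` are hypolordotic, angles above `high` hyperlordotic,
#' and the closed interval `[low, high]` (39-53 degrees by default) is
#' normal.
#'
#' @param lla LLA in degrees, in `[0, 90)`; vectorized.
#' @param thresholds A [grade_thresholds()] object.
#' @return Character vector with values `"hypo"`, `"normal"`, `"hyper"`.
#' @export
grade_lordosis <- function(lla, thresholds = grade_thresholds()) {
  stopifnot(inherits(thresholds, "grade_thresholds"))
  if (any(!is.finite(lla)) || any(lla < 0) || any(lla >= 90))
    stop("LLA must lie in [0, 90)")
  ifelse(lla < thresholds$low, "hypo",
         ifelse(lla <= thresholds$high, "normal", "hyper"))
}
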