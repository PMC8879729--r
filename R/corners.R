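#' Parameters of the corner-detection stage
#'
#' The corner stage smooths a vertebra's binary mask with a Gaussian
#' (`smooth_sigma`, the classic value for this pipeline is 1 pixel), builds
#' the Harris response over the Gaussian-windowed structure tensor of the
#' image gradients, and keeps the strongest local maxima after greedy
#' non-maximum suppression.
#'
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels (> 0).
#' @param harris_k Harris sensitivity constant, in `(0, 0.25)`; the usual
#'   literature range is 0.04-0.06.
#' @param window_sigma Sigma of the Gaussian window that averages the
#'   structure-tensor components, in pixels.
#' @param nms_radius Non-maximum-suppression radius in pixels (>= 1).
#' @param rel_threshold Keep maxima whose response exceeds this fraction of
#'   the global maximum, in `(0, 1)`.
#' @param max_candidates Maximum number of candidate corners returned.
#' @return A list of class `"corner_params"`.
#' @export
corner_params <- function(smooth_sigma = 1, harris_k = 0.05,
                          window_sigma = 2, nms_radius = 5,
                          rel_threshold = 0.05, max_candidates = 12L) {
  stopifnot(smooth_sigma > 0, harris_k > 0, harris_k < 0.25,
            window_sigma > 0, nms_radius >= 1,
            rel_threshold > 0, rel_threshold < 1, max_candidates >= 4)
  structure(list(smooth_sigma = smooth_sigma, harris_k = harris_k,
                 window_sigma = window_sigma, nms_radius = nms_radius,
                 rel_threshold = rel_threshold,
                 max_candidates = as.integer(max_candidates)),
            class = "corner_params")
}

# Symmetric (reflective, edge included) padding indices for length n.
reflect_idx <- function(n, r) {
  left <- pmin(pmax(rev(seq_len(r)), 1L), n)
  right <- pmin(pmax(n + 1L - seq_len(r), 1L), n)
  c(left, seq_len(n), right)
}

# 1-D convolution of the rows (along = 1) or columns (along = 2) of a
# matrix with kernel k (odd length), reflective boundaries.
conv_sep <- function(m, k, along) {
  r <- (length(k) - 1L) %/% 2L
  if (along == 1L) {
    p <- m[reflect_idx(nrow(m), r), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (o in seq_along(k))
      out <- out + k[o] * p[o:(o + nrow(m) - 1L), , drop = FALSE]
  } else {
    p <- m[, reflect_idx(ncol(m), r), drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (o in seq_along(k))
      out <- out + k[o] * p[, o:(o + ncol(m) - 1L), drop = FALSE]
  }
  out
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

#' Gaussian smoothing of a 2-D grid
#'
#' Separable convolution with a normalized Gaussian kernel truncated at
#' four sigma, reflective boundary handling. A constant grid is preserved
#' exactly (the kernel sums to 1) and, with reflective boundaries, the
#' total pixel mass is conserved.
#'
#' @param m Numeric matrix.
#' @param sigma Gaussian sigma in pixels (> 0).
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(m, sigma) {
  stopifnot(is.matrix(m), length(m) > 0, sigma > 0)
  k <- gaussian_kernel_1d(sigma)
  conv_sep(conv_sep(m, k, 1L), k, 2L)
}

# Central-difference gradients with replicated edges.
gradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xp <- m[, c(2:nc, nc), drop = FALSE]
  xm <- m[, c(1, 1:(nc - 1)), drop = FALSE]
  yp <- m[c(2:nr, nr), , drop = FALSE]
  ym <- m[c(1, 1:(nr - 1)), , drop = FALSE]
  list(gx = (xp - xm) / 2, gy = (yp - ym) / 2)
}

#' Harris corner response
#'
#' Computes `R = det(M) - k * trace(M)^2` where `M` is the structure tensor
#' of the image gradients (central differences), with each tensor component
#' averaged by a Gaussian window of sigma `window_sigma`. Corners give
#' strongly positive responses, straight edges non-positive ones, flat
#' regions zero.
#'
#' @param m Numeric matrix, at least 3 x 3.
#' @param params A [corner_params()] object.
#' @return Response matrix of the same shape.
#' @export
harris_response <- function(m, params = corner_params()) {
  stopifnot(is.matrix(m), nrow(m) >= 3, ncol(m) >= 3)
  g <- gradients(m)
  ixx <- gaussian_smooth(g$gx * g$gx, params$window_sigma)
  iyy <- gaussian_smooth(g$gy * g$gy, params$window_sigma)
  ixy <- gaussian_smooth(g$gx * g$gy, params$window_sigma)
  (ixx * iyy - ixy^2) - params$harris_k * (ixx + iyy)^2
}

#' Select corner candidates from a Harris response grid
#'
#' Keeps local maxima (8-neighborhood) whose response exceeds
#' `rel_threshold` times the global maximum, applies greedy non-maximum
#' suppression of radius `nms_radius` starting from the strongest response
#' (ties broken by row-major position), and returns at most
#' `max_candidates` points sorted by response descending. Points are
#' reported at pixel centers (x = column + 0.5, y = row + 0.5, 0-based).
#'
#' @param response Numeric response matrix.
#' @param params A [corner_params()] object.
#' @return Data frame with columns `x`, `y`, `response`; zero rows when no
#'   candidate clears the threshold.
#' @export
detect_corners <- function(response, params = corner_params()) {
  stopifnot(is.matrix(response), all(is.finite(response)))
  empty <- data.frame(x = numeric(0), y = numeric(0), response = numeric(0))
  top <- max(response)
  if (top <= 0) return(empty)
  thr <- params$rel_threshold * top
  nr <- nrow(response); nc <- ncol(response)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- response
  ismax <- rep(TRUE, nr * nc)
  dim(ismax) <- c(nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax &
      response >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  cand <- which(ismax & response > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  resp <- response[cand]
  # response descending; ties by row-major (row, then column) position
  ord <- order(-resp, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  resp <- resp[ord]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) > 0) {
      d2 <- (cand[keep, 1] - cand[i, 1])^2 + (cand[keep, 2] - cand[i, 2])^2
      if (any(d2 <= params$nms_radius^2)) next
    }
    keep <- c(keep, i)
    if (length(keep) >= params$max_candidates) break
  }
  data.frame(x = cand[keep, 2] - 0.5, y = cand[keep, 1] - 0.5,
             response = resp[keep])
}

#' Assign candidate corners to anatomical positions
#'
#' Each candidate is placed in a quadrant relative to the vertebra
#' centroid; per quadrant, the candidate with the largest Harris response
#' wins. Quadrants are taken in the vertebra's own frame: `axis` is the
#' unit direction of the vertebral long axis (endplate direction), so a
#' point is "left" when its offset projects negatively on `axis` and
#' "superior" when it projects negatively on the perpendicular axis
#' (which points inferiorly in a head-up image). With the default
#' `axis = c(1, 0)` this reduces to plain image-aligned quadrants
#' (y above the centroid = superior, x left of it = left).
#'
#' @param candidates Data frame with columns `x`, `y`, `response` (at least
#'   4 rows).
#' @param centroid Numeric `c(x, y)` centroid of the vertebra mask.
#' @param axis Unit vector of the vertebral long axis; normalized
#'   internally, flipped to non-negative x so "left" is image-left.
#' @param flip Set `TRUE` for feet-up images (swaps superior/inferior).
#' @return Data frame of class `"corner_set"` with rows `superior_left`,
#'   `superior_right`, `inferior_left`, `inferior_right` and columns
#'   `corner`, `x`, `y`, `response`.
#' @export
assign_anatomical_corners <- function(candidates, centroid, axis = c(1, 0),
                                      flip = FALSE) {
  stopifnot(is.data.frame(candidates), length(centroid) == 2,
            length(axis) == 2)
  u <- axis / sqrt(sum(axis^2))
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  v <- c(-u[2], u[1])          # points inferiorly for a head-up image
  if (flip) v <- -v
  dx <- candidates$x - centroid[1]
  dy <- candidates$y - centroid[2]
  a <- dx * u[1] + dy * u[2]   # along long axis: < 0 -> left
  b <- dx * v[1] + dy * v[2]   # across: < 0 -> superior
  quad <- ifelse(b < 0,
                 ifelse(a < 0, "superior_left", "superior_right"),
                 ifelse(a < 0, "inferior_left", "inferior_right"))
  names4 <- c("superior_left", "superior_right",
              "inferior_left", "inferior_right")
  pick <- integer(4)
  for (q in seq_along(names4)) {
    in_q <- which(quad == names4[q])
    if (length(in_q) == 0)
      stop(sprintf("corner assignment failed: quadrant %s empty", names4[q]))
    pick[q] <- in_q[which.max(candidates$response[in_q])]
  }
  out <- data.frame(corner = names4,
                    x = candidates$x[pick], y = candidates$y[pick],
                    response = candidates$response[pick],
                    stringsAsFactors = FALSE)
  class(out) <- c("corner_set", class(out))
  out
}

harris_bias_cache <- new.env(parent = emptyenv())

#' Localization bias of the Harris operator at the working scale
#'
#' The maximum of the Harris response to a right-angle corner does not sit
#' on the corner: smoothing displaces it towards the shape interior by an
#' amount that grows with the smoothing and window scales (the classic
#' scale-space localization bias of derivative-based corner detectors),
#' and on a rasterized binary mask the displacement also depends on the
#' corner's orientation relative to the pixel grid. This function measures
#' the displacement for the given parameters and orientation by rendering
#' an ideal binary quarter-plane corner with edge directions `tilt_deg`
#' and `tilt_deg + 90`, running the same smooth / response / peak
#' pipeline, and averaging the displacement over a grid of sub-pixel
#' corner placements (so the pixel-quantization component averages out).
#' The result is cached per parameter set and orientation.
#'
#' @param params A [corner_params()] object.
#' @param tilt_deg Orientation of the first edge in degrees.
#' @return Numeric `c(along, across)`: mean inward displacement in pixels
#'   along the first and second edge direction.
#' @export
harris_corner_bias <- function(params, tilt_deg = 0) {
  key <- sprintf("%.6g_%.6g_%.6g_%.6g", params$smooth_sigma,
                 params$window_sigma, params$harris_k, tilt_deg)
  hit <- harris_bias_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- 48L
  phases <- c(0.125, 0.375, 0.625, 0.875)
  t <- tilt_deg * pi / 180
  e1 <- c(cos(t), sin(t))
  e2 <- c(-sin(t), cos(t))
  xs <- matrix(seq_len(n) - 0.5, n, n, byrow = TRUE)
  ys <- matrix(seq_len(n) - 0.5, n, n)
  acc <- c(0, 0)
  for (u in phases) for (v in phases) {
    cx <- n / 2 + u; cy <- n / 2 + v
    d1 <- (xs - cx) * e1[1] + (ys - cy) * e1[2]
    d2 <- (xs - cx) * e2[1] + (ys - cy) * e2[2]
    mask <- (d1 >= 0 & d2 >= 0) * 1
    resp <- harris_response(gaussian_smooth(mask, params$smooth_sigma),
                            params)
    # restrict to the interior so reflective-boundary artifacts never win
    resp[c(1:8, (n - 7):n), ] <- -Inf
    resp[, c(1:8, (n - 7):n)] <- -Inf
    peak <- which(resp == max(resp), arr.ind = TRUE)[1, ]
    d <- c(peak[2] - 0.5 - cx, peak[1] - 0.5 - cy)
    acc <- acc + c(sum(d * e1), sum(d * e2))
  }
  out <- acc / length(phases)^2
  harris_bias_cache[[key]] <- out
  out
}

# Principal axis of a set of pixel centers (unit vector, x >= 0).
principal_axis <- function(xy) {
  if (nrow(xy) < 2) return(c(1, 0))
  cc <- stats::cov(xy)
  e <- eigen(cc, symmetric = TRUE)
  u <- e$vectors[, 1]
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  u
}

#' Detect the four endplate corners of one vertebra
#'
#' Crops the vertebra's binary mask with a margin of `margin_sigmas *
#' window_sigma` pixels, smooths it (`smooth_sigma`), computes the Harris
#' response, selects candidate corners and assigns them anatomically using
#' the mask's principal axis as the vertebral long-axis direction. Points
#' are returned in whole-image coordinates.
#'
#' @param img Integer label matrix.
#' @param vertebra Vertebra name (e.g. `"L1"`) or integer label value.
#' @param params A [corner_params()] object.
#' @param label_map Named map from vertebra names to label values.
#' @param margin_sigmas Crop margin in units of `window_sigma` (default 4).
#' @param flip Set `TRUE` for feet-up images.
#' @param compensate_bias Subtract the operator's scale-space localization
#'   bias (see [harris_corner_bias()]) along each corner's bisector
#'   (default `TRUE`).
#' @return A `"corner_set"` data frame (see [assign_anatomical_corners()]).
#' @export
vertebra_corners <- function(img, vertebra, params = corner_params(),
                             label_map = default_label_map(),
                             margin_sigmas = 4, flip = FALSE,
                             compensate_bias = TRUE) {
  stopifnot(is.matrix(img))
  value <- if (is.character(vertebra)) {
    if (!vertebra %in% names(label_map))
      stop(sprintf("unknown vertebra name '%s'", vertebra))
    label_map[[vertebra]]
  } else as.integer(vertebra)
  idx <- which(img == value, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop(sprintf("vertebra %s (label %d) not present in image",
                 as.character(vertebra), value))
  m <- ceiling(margin_sigmas * params$window_sigma)
  # virtual crop window, zero-padded where it extends past the image so a
  # vertebra flush with the border keeps well-defined corners
  r0 <- min(idx[, 1]) - m; r1 <- max(idx[, 1]) + m
  c0 <- min(idx[, 2]) - m; c1 <- max(idx[, 2]) + m
  crop <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
  rr <- max(1L, r0):min(nrow(img), r1)
  cc <- max(1L, c0):min(ncol(img), c1)
  crop[rr - r0 + 1L, cc - c0 + 1L] <- (img[rr, cc, drop = FALSE] == value) * 1
  smoothed <- gaussian_smooth(crop, params$smooth_sigma)
  resp <- harris_response(smoothed, params)
  cand <- detect_corners(resp, params)
  if (nrow(cand) < 4)
    stop(sprintf("vertebra %s: only %d corner candidates found",
                 as.character(vertebra), nrow(cand)))
  # mask pixel centers in crop coordinates (0-based continuous)
  in_crop <- which(crop > 0, arr.ind = TRUE)
  xy <- cbind(x = in_crop[, 2] - 0.5, y = in_crop[, 1] - 0.5)
  ctr <- colMeans(xy)
  axis <- principal_axis(xy)
  cs <- assign_anatomical_corners(cand, ctr, axis = axis, flip = flip)
  if (compensate_bias) {
    u <- axis
    if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
    v <- c(-u[2], u[1])
    if (flip) v <- -v
    tilt <- round(atan2(u[2], u[1]) * 180 / pi * 2) / 2
    bp <- harris_corner_bias(params, tilt)   # superior-left corner type
    bm <- harris_corner_bias(params, -tilt)  # its mirror orientation
    # per corner type, the inward bias in the (u, v) frame follows from
    # the mirror symmetries of the calibration corner
    bias_ab <- list(superior_left = c(bp[1], bp[2]),
                    superior_right = c(-bm[1], bm[2]),
                    inferior_left = c(bm[1], -bm[2]),
                    inferior_right = c(-bp[1], -bp[2]))
    for (i in seq_len(nrow(cs))) {
      ab <- bias_ab[[cs$corner[i]]]
      disp <- ab[1] * u + ab[2] * v
      cs$x[i] <- cs$x[i] - disp[1]
      cs$y[i] <- cs$y[i] - disp[2]
    }
  }
  cs$x <- cs$x + (c0 - 1)
  cs$y <- cs$y + (r0 - 1)
  cs
}

#' @export
print.corner_set <- function(x, ...) {
  cat("Vertebra corner set:\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

corner_point <- function(cs, which) {
  i <- match(which, cs$corner)
  c(cs$x[i], cs$y[i])
}
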