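#' Ordered centroid polygon of the six vertebrae
#'
#' The centroid of L1 is connected to L2, L2 to L3, and so on down to S,
#' whose centroid closes the polygon back to L1, forming the enclosed
#' region whose pixel area is the severity proxy of the area-based
#' grading route.
#'
#' @param boxes Bounding-box data frame carrying exactly the six labels
#'   L1..L5, S (any order).
#' @return Data frame with columns `label`, `x`, `y` ordered L1..L5, S.
#' @export
centroid_polygon <- function(boxes) {
  validate_boxes(boxes)
  want <- vertebra_labels()
  if (!setequal(boxes$label, want) || nrow(boxes) != 6 ||
      anyDuplicated(boxes$label))
    stop("need exactly one box for each of L1..L5 and S")
  boxes <- boxes[match(want, boxes$label), , drop = FALSE]
  ctr <- box_centroid(boxes)
  data.frame(label = want, x = ctr$x, y = ctr$y, stringsAsFactors = FALSE)
}

# Rasterize a closed polygon (even-odd fill, boundary included) onto an
# H x W logical canvas; polygon vertices in continuous pixel coordinates.
rasterize_region <- function(poly, image_height, image_width) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  canvas <- matrix(FALSE, image_height, image_width)
  # interior: even-odd scanline over pixel-center rows
  for (i in seq_len(image_height)) {
    yc <- i - 0.5
    cross <- numeric(0)
    for (e in seq_len(n)) {
      x1 <- x[e]; y1 <- y[e]
      x2 <- x[e %% n + 1]; y2 <- y[e %% n + 1]
      if ((y1 <= yc && yc < y2) || (y2 <= yc && yc < y1))
        cross <- c(cross, x1 + (yc - y1) * (x2 - x1) / (y2 - y1))
    }
    cross <- sort(cross)
    for (p in seq_len(length(cross) %/% 2)) {
      a <- cross[2 * p - 1]; b <- cross[2 * p]
      j0 <- max(1L, floor(a - 0.5) + 2L)   # first center strictly > a
      j1 <- min(image_width, ceiling(b - 0.5))
      if (j0 <= j1) canvas[i, j0:j1] <- TRUE
    }
  }
  # boundary: dense sampling of each edge, pixels containing samples;
  # samples are nudged infinitesimally towards the polygon centroid so an
  # edge lying exactly on a pixel boundary marks the interior-side pixel
  cx <- mean(x); cy <- mean(y)
  eps <- 1e-6
  for (e in seq_len(n)) {
    x1 <- x[e]; y1 <- y[e]
    x2 <- x[e %% n + 1]; y2 <- y[e %% n + 1]
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    ts <- seq(0, 1, length.out = max(2L, ceiling(len * 4) + 1L))
    px <- x1 + ts * (x2 - x1)
    py <- y1 + ts * (y2 - y1)
    dxn <- cx - px; dyn <- cy - py
    nrm <- sqrt(dxn^2 + dyn^2)
    nz <- nrm > 0
    px[nz] <- px[nz] + eps * dxn[nz] / nrm[nz]
    py[nz] <- py[nz] + eps * dyn[nz] / nrm[nz]
    jj <- pmin(pmax(floor(px) + 1L, 1L), image_width)
    ii <- pmin(pmax(floor(py) + 1L, 1L), image_height)
    canvas[cbind(ii, jj)] <- TRUE
  }
  canvas
}

#' Pixel area of the enclosed centroid region
#'
#' Rasterizes the closed centroid polygon onto a zero canvas (even-odd
#' fill, boundary pixels counted as inside) and returns the number of
#' nonzero pixels times the squared pixel pitch (1 pixel, so the value is
#' in squared pixels). A degenerate, collinear polygon yields just its
#' rasterized boundary-line pixel count.
#'
#' @param poly Data frame with columns `x`, `y` (see [centroid_polygon()]).
#' @param image_height,image_width Canvas size in pixels.
#' @return Area in squared pixels.
#' @export
region_area <- function(poly, image_height, image_width) {
  stopifnot(is.data.frame(poly), nrow(poly) >= 3,
            all(is.finite(poly$x)), all(is.finite(poly$y)))
  if (any(poly$x < 0) || any(poly$x > image_width) ||
      any(poly$y < 0) || any(poly$y > image_height))
    stop("polygon extends outside the canvas")
  sum(rasterize_region(poly, image_height, image_width))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Calibrate area cut-points for lordosis grading
#'
#' The enclosed-region area orders the classes as hypolordosis < normal <
#' hyperlordosis, but no universal cut-points exist, so they are learned
#' from a labeled training set: an exhaustive search over all pairs of
#' candidate cuts (midpoints between consecutive distinct areas, plus
#' sentinels beyond the extremes) picks the pair maximizing training
#' accuracy of the rule `area < low_cut -> hypo`, `area <= high_cut ->
#' normal`, else `hyper`. Ties are broken by the maximal summed margin of
#' the cuts to the nearest training areas.
#'
#' @param areas Numeric region areas in squared pixels.
#' @param grades Matching true grades (`"hypo"`, `"normal"`, `"hyper"`);
#'   all three classes must be present.
#' @return A list of class `"area_thresholds"` with `low_cut`, `high_cut`,
#'   `accuracy` (training accuracy) and `n`.
#' @export
calibrate_area_thresholds <- function(areas, grades) {
  stopifnot(length(areas) == length(grades), all(is.finite(areas)))
  grades <- as.character(grades)
  if (!all(c("hypo", "normal", "hyper") %in% grades))
    stop("all three grades must be present in the training data")
  s <- sort(unique(areas))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- NULL
  for (ilo in seq_along(cand)) {
    for (ihi in ilo:length(cand)) {
      lo <- cand[ilo]; hi <- cand[ihi]
      if (lo <= 0 || hi <= lo) next
      pred <- ifelse(areas < lo, "hypo",
                     ifelse(areas <= hi, "normal", "hyper"))
      acc <- mean(pred == grades)
      margin <- min(abs(areas - lo)) + min(abs(areas - hi))
      if (is.null(best) || acc > best$accuracy ||
          (acc == best$accuracy && margin > best$margin)) {
        best <- list(low_cut = lo, high_cut = hi, accuracy = acc,
                     margin = margin)
      }
    }
  }
  structure(list(low_cut = best$low_cut, high_cut = best$high_cut,
                 accuracy = best$accuracy, n = length(areas)),
            class = "area_thresholds")
}

#' @export
print.area_thresholds <- function(x, ...) {
  cat(sprintf(paste0("Area grading cut-points: hypo < %.1f <= normal <= ",
                     "%.1f < hyper px^2\n"), x$low_cut, x$high_cut))
  cat(sprintf("Training accuracy: %.3f on %d cases\n", x$accuracy, x$n))
  invisible(x)
}

#' @export
predict.area_thresholds <- function(object, newdata, ...) {
  grade_by_area(newdata, object)
}

#' Grade lordosis from the enclosed-region area
#'
#' `area < low_cut` is hypolordotic, `low_cut <= area <= high_cut` normal,
#' larger areas hyperlordotic (the boundaries belong to normal, mirroring
#' the angle-grading convention).
#'
#' @param area Numeric areas in squared pixels; vectorized.
#' @param thresholds An [calibrate_area_thresholds()] result.
#' @return Character vector of grades.
#' @export
grade_by_area <- function(area, thresholds) {
  stopifnot(inherits(thresholds, "area_thresholds"))
  ifelse(area < thresholds$low_cut, "hypo",
         ifelse(area <= thresholds$high_cut, "normal", "hyper"))
}
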