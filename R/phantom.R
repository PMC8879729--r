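#' Specification of a synthetic spine phantom
#'
#' The phantom emulates a mid-sagittal, head-up label image of the lumbar
#' spine: six near-rectangular vertebral bodies (L1-L5 and the sacrum S)
#' stacked superior to inferior along a curve, rasterized as instance
#' labels 1..6 on a zero background. Each vertebra is a rectangle of
#' `vertebra_width x vertebra_height` pixels rotated by its endplate tilt;
#' consecutive bodies are spaced `gap` pixels apart along the local column
#' direction, so the column bends according to the tilt profile exactly as
#' endplate tilts and spinal curvature co-vary in a real lordotic spine.
#' The default tilt profile yields a normal-lordosis geometry with the
#' sacrum as the most tilted element.
#'
#' @param image_height,image_width Canvas size in pixels (default 320).
#' @param n_vertebrae Number of bodies; fixed at 6 (L1..L5, S).
#' @param vertebra_height,vertebra_width Body size in pixels along /
#'   across the column.
#' @param gap Inter-vertebral spacing along the column, pixels.
#' @param endplate_tilts Six per-vertebra tilts in degrees (tilt of the
#'   endplate direction from horizontal, image convention: positive tips
#'   the right end inferiorly).
#' @param curve_offset_amplitude Extra horizontal bow, pixels: a half-sine
#'   displacement added to the vertebra centers on top of the
#'   tilt-following arc (default 0).
#' @param boundary_jitter_px Uniform corner jitter half-width in pixels
#'   (>= 0); perturbs the true quadrilateral, so ground truth reflects it.
#' @param salt_pepper_fraction Fraction of pixels corrupted in the optional
#'   grayscale render (never in the label raster), in `[0, 1]`.
#' @param seed Integer RNG seed; the same spec always generates a
#'   bit-identical phantom.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(image_height = 320, image_width = 320,
                         n_vertebrae = 6L,
                         vertebra_height = 24, vertebra_width = 38,
                         gap = 10,
                         endplate_tilts = c(-20, -11, -2, 7, 16, 26),
                         curve_offset_amplitude = 0,
                         boundary_jitter_px = 0,
                         salt_pepper_fraction = 0,
                         seed = 0L) {
  stopifnot(image_height > 0, image_width > 0,
            identical(as.integer(n_vertebrae), 6L),
            vertebra_height > 0, vertebra_width > 0, gap > 0,
            length(endplate_tilts) == 6, all(is.finite(endplate_tilts)),
            boundary_jitter_px >= 0,
            salt_pepper_fraction >= 0, salt_pepper_fraction <= 1)
  structure(list(image_height = image_height, image_width = image_width,
                 n_vertebrae = 6L,
                 vertebra_height = vertebra_height,
                 vertebra_width = vertebra_width, gap = gap,
                 endplate_tilts = as.numeric(endplate_tilts),
                 curve_offset_amplitude = curve_offset_amplitude,
                 boundary_jitter_px = boundary_jitter_px,
                 salt_pepper_fraction = salt_pepper_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

rot2 <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

# Corner offsets of an untilted body, order SL, SR, IR, IL (cyclic).
body_offsets <- function(w, h) {
  rbind(c(-w / 2, -h / 2), c(w / 2, -h / 2),
        c(w / 2, h / 2), c(-w / 2, h / 2))
}

is_convex_quad <- function(q) {
  s <- 0
  for (i in 1:4) {
    a <- q[i, ]; b <- q[i %% 4 + 1, ]; cpt <- q[(i + 1) %% 4 + 1, ]
    cr <- (b[1] - a[1]) * (cpt[2] - a[2]) - (b[2] - a[2]) * (cpt[1] - a[1])
    if (abs(cr) < 1e-9) return(FALSE)
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

# Mark pixels of `canvas` whose centers fall inside (or on) convex quad q
# with `value`; returns NULL on collision with an existing nonzero label.
rasterize_quad <- function(canvas, q, value, tol = 1e-9) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  j0 <- max(1L, floor(min(q[, 1]))); j1 <- min(nc, ceiling(max(q[, 1])) + 1L)
  i0 <- max(1L, floor(min(q[, 2]))); i1 <- min(nr, ceiling(max(q[, 2])) + 1L)
  if (j0 > j1 || i0 > i1) return(canvas)
  xs <- (j0:j1) - 0.5
  ys <- (i0:i1) - 0.5
  px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  py <- matrix(ys, length(ys), length(xs))
  inside <- matrix(TRUE, length(ys), length(xs))
  # fix winding so interior cross products are positive
  a1 <- q[2, ] - q[1, ]; a2 <- q[3, ] - q[2, ]
  if (a1[1] * a2[2] - a1[2] * a2[1] < 0) q <- q[4:1, ]
  for (i in 1:4) {
    a <- q[i, ]; b <- q[i %% 4 + 1, ]
    cr <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    inside <- inside & (cr >= -tol)
  }
  sub <- canvas[i0:i1, j0:j1, drop = FALSE]
  if (any(sub[inside] != 0)) return(NULL)
  sub[inside] <- value
  canvas[i0:i1, j0:j1] <- sub
  canvas
}

phantom_geometry <- function(spec) {
  t <- spec$endplate_tilts
  h <- spec$vertebra_height; w <- spec$vertebra_width
  step <- h + spec$gap
  centers <- matrix(0, 6, 2)
  for (k in 1:5) {
    m <- (t[k] + t[k + 1]) / 2 * pi / 180
    centers[k + 1, ] <- centers[k, ] + step * c(-sin(m), cos(m))
  }
  centers[, 1] <- centers[, 1] +
    spec$curve_offset_amplitude * sin(pi * (0:5) / 5)
  quads <- lapply(1:6, function(k) {
    off <- body_offsets(w, h) %*% t(rot2(t[k]))
    sweep(off, 2, centers[k, ], "+")
  })
  j <- spec$boundary_jitter_px
  if (j > 0)
    quads <- lapply(quads, function(q) q + matrix(stats::runif(8, -j, j), 4, 2))
  # center the assembly on the canvas
  allc <- do.call(rbind, quads)
  shift <- c((spec$image_width - max(allc[, 1]) - min(allc[, 1])) / 2,
             (spec$image_height - max(allc[, 2]) - min(allc[, 2])) / 2)
  quads <- lapply(quads, function(q) sweep(q, 2, shift, "+"))
  allc <- do.call(rbind, quads)
  if (min(allc) < 1 || max(allc[, 1]) > spec$image_width - 1 ||
      max(allc[, 2]) > spec$image_height - 1)
    stop("phantom does not fit inside the image; reduce sizes or tilts")
  quads
}

quad_to_corner_set <- function(q) {
  out <- data.frame(corner = c("superior_left", "superior_right",
                               "inferior_left", "inferior_right"),
                    x = q[c(1, 2, 4, 3), 1], y = q[c(1, 2, 4, 3), 2],
                    response = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("corner_set", class(out))
  out
}

#' Generate a synthetic spine phantom with known ground truth
#'
#' Builds the six vertebra quadrilaterals from a [phantom_spec()],
#' rasterizes them as instance labels 1..6 (1 = L1 topmost, 6 = S), and
#' records the exact ground truth: the (possibly jittered) corner
#' positions, the tight boxes around the rasterized masks, the true LLA
#' and LSA computed from the corner geometry, and the lordosis grade of
#' the true LLA. With corner jitter, overlapping bodies trigger one
#' regeneration attempt before failing.
#'
#' @param spec A [phantom_spec()].
#' @param max_attempts Jitter redraws allowed before giving up.
#' @return A list of class `"phantom_case"` with elements `label_image`,
#'   `boxes`, `true_corners` (named list of corner sets), `true_lla_deg`,
#'   `true_lsa_deg`, `true_grade` and `spec`.
#' @export
generate_phantom <- function(spec, max_attempts = 20L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  for (attempt in seq_len(max_attempts)) {
    quads <- phantom_geometry(spec)
    if (!all(vapply(quads, is_convex_quad, logical(1)))) next
    canvas <- matrix(0L, spec$image_height, spec$image_width)
    ok <- TRUE
    for (k in 1:6) {
      canvas <- rasterize_quad(canvas, quads[[k]], k)
      if (is.null(canvas)) { ok <- FALSE; break }
    }
    if (!ok) next
    counts <- tabulate(canvas[canvas > 0], nbins = 6)
    if (any(counts == 0)) stop("a vertebra rasterized to zero pixels")
    boxes <- boxes_from_label_image(canvas)
    true_corners <- stats::setNames(lapply(quads, quad_to_corner_set),
                                    vertebra_labels())
    lla <- compute_lla(true_corners$L1, true_corners$S)$angle_deg
    lsa <- compute_lsa(true_corners$L5, true_corners$S)$angle_deg
    return(structure(list(label_image = canvas, boxes = boxes,
                          true_corners = true_corners,
                          true_lla_deg = lla, true_lsa_deg = lsa,
                          true_grade = grade_lordosis(lla), spec = spec),
                     class = "phantom_case"))
  }
  stop(sprintf("vertebrae still overlap after %d jitter redraws",
               max_attempts))
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("Spine phantom %dx%d: LLA %.2f deg, LSA %.2f deg, grade %s\n",
              x$spec$image_width, x$spec$image_height,
              x$true_lla_deg, x$true_lsa_deg, x$true_grade))
  invisible(x)
}

#' Grayscale render of a phantom, with optional salt-and-pepper noise
#'
#' A companion intensity image (vertebrae bright on a dark background) for
#' exercising intensity-based stages. Noise is applied only here; the
#' label raster always stays exact ground truth.
#'
#' @param case A `"phantom_case"`.
#' @param fg,bg Foreground / background intensity in `[0, 1]`.
#' @return Numeric matrix in `[0, 1]`.
#' @export
render_grayscale <- function(case, fg = 0.75, bg = 0.1) {
  stopifnot(inherits(case, "phantom_case"))
  g <- ifelse(case$label_image > 0, fg, bg)
  f <- case$spec$salt_pepper_fraction
  if (f > 0) {
    set.seed(case$spec$seed + 1L)
    n <- length(g)
    hit <- sample.int(n, round(f * n))
    g[hit] <- sample(c(0, 1), length(hit), replace = TRUE)
  }
  g
}

corner_set_to_list <- function(cs) {
  key <- c(superior_left = "sl", superior_right = "sr",
           inferior_left = "il", inferior_right = "ir")
  out <- lapply(seq_len(nrow(cs)), function(i) c(cs$x[i], cs$y[i]))
  stats::setNames(out, unname(key[cs$corner]))
}

#' Write a phantom case to disk
#'
#' Emits `<basename>.png` (8-bit label image), `<basename>.txt`
#' (YOLO-format ground-truth boxes, single class 0 = "V") and
#' `<basename>.json` (true corners, angles and grade). The files
#' round-trip losslessly through [read_phantom_case()] up to the 6-decimal
#' quantization of the normalized box coordinates.
#'
#' @param case A `"phantom_case"`.
#' @param out_dir Output directory (created if absent).
#' @param basename File stem, default `"case"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(case, out_dir, basename = "case") {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(out_dir, basename)
  write_label_png(case$label_image, paste0(stem, ".png"))
  write_yolo(case$boxes, paste0(stem, ".txt"),
             case$spec$image_height, case$spec$image_width)
  sidecar <- list(corners = lapply(case$true_corners, corner_set_to_list),
                  lla_deg = case$true_lla_deg, lsa_deg = case$true_lsa_deg,
                  grade = case$true_grade)
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(png = paste0(stem, ".png"), txt = paste0(stem, ".txt"),
              json = paste0(stem, ".json")))
}

#' Read a phantom case back from disk
#'
#' @param dir Directory holding the files written by [write_phantom()].
#' @param basename File stem.
#' @return List with `label_image`, `boxes` (pixel coordinates), and the
#'   sidecar fields `corners`, `lla_deg`, `lsa_deg`, `grade`.
#' @export
read_phantom_case <- function(dir, basename = "case") {
  img <- read_label_png(file.path(dir, paste0(basename, ".png")))
  boxes <- read_yolo(file.path(dir, paste0(basename, ".txt")),
                     nrow(img), ncol(img))
  sidecar <- jsonlite::read_json(file.path(dir, paste0(basename, ".json")),
                                 simplifyVector = TRUE)
  list(label_image = img, boxes = boxes, corners = sidecar$corners,
       lla_deg = sidecar$lla_deg, lsa_deg = sidecar$lsa_deg,
       grade = sidecar$grade)
}

grade_intervals <- function() {
  list(hypo = c(5, 39), normal = c(39, 53), hyper = c(53, 85))
}

#' Generate a cohort of phantoms with a prescribed grade mix
#'
#' Target grades are allocated either exactly (largest-remainder rounding
#' of `n * grade_mix`, the default) or by multinomial sampling. For each
#' case the sacrum-versus-L1 tilt difference — which equals the true LLA
#' of the noise-free geometry — is drawn uniformly from the target class's
#' angle interval (hypo `[5, 39)`, normal `[39, 53]`, hyper `(53, 85]`)
#' and spread symmetrically over the column as a linear tilt profile.
#' The recorded `true_grade` is always the grading function applied to the
#' realized true LLA, so with corner jitter a case drawn near a class
#' boundary may legitimately realize the neighboring grade.
#'
#' @param n Number of cases (>= 1).
#' @param grade_mix Numeric proportions for (hypo, normal, hyper); must sum
#'   to 1. Default: the 6/19/26 split of a 51-case clinical test set.
#' @param base_spec [phantom_spec()] providing everything except the tilts
#'   and per-case seed.
#' @param seed Cohort seed; drives the class shuffle, the angle draws and
#'   the per-case phantom seeds.
#' @param allocation `"exact"` or `"sample"`.
#' @return List of `"phantom_case"` objects; each carries its
#'   `target_grade`.
#' @export
generate_cohort <- function(n, grade_mix = c(6, 19, 26) / 51,
                            base_spec = phantom_spec(), seed = 0L,
                            allocation = c("exact", "sample")) {
  allocation <- match.arg(allocation)
  stopifnot(n >= 1, length(grade_mix) == 3, all(grade_mix >= 0),
            abs(sum(grade_mix) - 1) < 1e-9)
  set.seed(as.integer(seed))
  grades <- c("hypo", "normal", "hyper")
  counts <- if (allocation == "exact") {
    base <- floor(n * grade_mix)
    rem <- n - sum(base)
    frac <- n * grade_mix - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
    base
  } else {
    as.vector(stats::rmultinom(1, n, grade_mix))
  }
  targets <- sample(rep(grades, counts))
  iv <- grade_intervals()
  diffs <- vapply(targets, function(g) stats::runif(1, iv[[g]][1],
                                                    iv[[g]][2]), 0)
  case_seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    spec_i <- base_spec
    spec_i$endplate_tilts <- diffs[i] * ((0:5) / 5 - 0.5)
    spec_i$seed <- case_seeds[i]
    case <- generate_phantom(spec_i)
    case$target_grade <- targets[i]
    case
  })
}
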