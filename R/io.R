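#' Vertebra labels in anatomical order
#'
#' The six elements measured by the pipeline, superior to inferior:
#' lumbar vertebrae L1 to L5 and the first sacral vertebra S.
#'
#' @return Character vector `c("L1","L2","L3","L4","L5","S")`.
#' @export
vertebra_labels <- function() c("L1", "L2", "L3", "L4", "L5", "S")

#' Default label-value map for instance label images
#'
#' Label images encode each vertebra instance as an integer pixel value,
#' background as 0. The conventional coding is 1..6 for L1..L5, S.
#'
#' @return Named integer vector mapping vertebra name to pixel value.
#' @export
default_label_map <- function() {
  stats::setNames(1:6, vertebra_labels())
}

#' Construct bounding boxes
#'
#' Boxes are axis-aligned, in continuous pixel coordinates with the origin
#' at the top-left corner, x increasing rightwards and y downwards. An
#' integer pixel (row r, column c), counted from 0, occupies the continuous
#' square `[c, c+1) x [r, r+1)`, so a tight box around a mask is half-open
#' and mask area equals box area for exact rectangles.
#'
#' @param xmin,ymin,xmax,ymax Box edges in pixels; recycled to a common
#'   length. Must satisfy `xmin <= xmax`, `ymin <= ymax`, all `>= 0`.
#' @param label Optional vertebra label (see [vertebra_labels()]), `NA` when
#'   not yet assigned.
#' @param confidence Optional detector confidence in `[0, 1]`, `NA` for
#'   ground-truth boxes.
#' @return A data frame with one row per box and columns `label`, `xmin`,
#'   `ymin`, `xmax`, `ymax`, `confidence`.
#' @export
bounding_box <- function(xmin, ymin, xmax, ymax, label = NA_character_,
                         confidence = NA_real_) {
  if (length(xmin) == 0) {
    b <- data.frame(label = character(0), xmin = numeric(0),
                    ymin = numeric(0), xmax = numeric(0), ymax = numeric(0),
                    confidence = numeric(0), stringsAsFactors = FALSE)
    return(b)
  }
  b <- data.frame(label = as.character(label),
                  xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                  xmax = as.numeric(xmax), ymax = as.numeric(ymax),
                  confidence = as.numeric(confidence),
                  stringsAsFactors = FALSE)
  validate_boxes(b)
  b
}

validate_boxes <- function(boxes) {
  stopifnot(is.data.frame(boxes))
  need <- c("xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(boxes)))
    stop("boxes must have columns xmin, ymin, xmax, ymax")
  if (nrow(boxes) == 0) return(invisible(boxes))
  if (any(!is.finite(as.matrix(boxes[, need]))))
    stop("box coordinates must be finite")
  if (any(boxes$xmin > boxes$xmax) || any(boxes$ymin > boxes$ymax))
    stop("boxes must satisfy xmin <= xmax and ymin <= ymax")
  if (any(boxes$xmin < 0) || any(boxes$ymin < 0))
    stop("box coordinates must be non-negative")
  invisible(boxes)
}

#' Read a YOLO-format annotation or detection file
#'
#' Each row is `class cx cy w h` (ground truth) or `class cx cy w h conf`
#' (detections), with center/size normalized to `[0, 1]`. Values are
#' de-normalized to pixel coordinates: `xmin = (cx - w/2) * width` and so
#' on. Rows are preserved in file order; anatomical labels are assigned
#' later by [sort_vertebrae()] because the detector uses the single class
#' "V" for every vertebra.
#'
#' @param path Path to the text file.
#' @param image_height,image_width Image size in pixels used for
#'   de-normalization.
#' @return A bounding-box data frame (see [bounding_box()]) with an extra
#'   `class` column holding the integer class id.
#' @export
read_yolo <- function(path, image_height, image_width) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (!(length(fields) %in% c(5L, 6L)))
      stop(sprintf("%s line %d: expected 5 or 6 fields, found %d",
                   path, i, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop(sprintf("%s line %d: non-numeric field", path, i))
    if (any(vals[2:5] < 0 | vals[2:5] > 1))
      stop(sprintf("%s line %d: normalized coordinate outside [0, 1]",
                   path, i))
    conf <- if (length(vals) == 6L) vals[6] else NA_real_
    if (!is.na(conf) && (conf < 0 || conf > 1))
      stop(sprintf("%s line %d: confidence outside [0, 1]", path, i))
    rows[[i]] <- c(class = vals[1], cx = vals[2], cy = vals[3],
                   w = vals[4], h = vals[5], conf = conf)
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) {
    b <- bounding_box(numeric(0), numeric(0), numeric(0), numeric(0))
    b$class <- numeric(0)
    return(b)
  }
  b <- data.frame(label = NA_character_,
                  xmin = (m[, "cx"] - m[, "w"] / 2) * image_width,
                  ymin = (m[, "cy"] - m[, "h"] / 2) * image_height,
                  xmax = (m[, "cx"] + m[, "w"] / 2) * image_width,
                  ymax = (m[, "cy"] + m[, "h"] / 2) * image_height,
                  confidence = m[, "conf"],
                  class = m[, "class"],
                  stringsAsFactors = FALSE)
  rownames(b) <- NULL
  b
}

#' Write boxes to a YOLO-format text file
#'
#' Inverse of [read_yolo()]: pixel boxes are normalized by the image size
#' and written as `class cx cy w h [conf]` with six decimals. Coordinates
#' are written as-is, never clamped.
#'
#' @param boxes Bounding-box data frame; an optional `class` column supplies
#'   the class id (default 0, the single vertebra class "V").
#' @param path Output file path.
#' @param image_height,image_width Image size in pixels.
#' @return `path`, invisibly.
#' @export
write_yolo <- function(boxes, path, image_height, image_width) {
  validate_boxes(boxes)
  cls <- if ("class" %in% names(boxes)) boxes$class else rep(0L, nrow(boxes))
  cx <- (boxes$xmin + boxes$xmax) / 2 / image_width
  cy <- (boxes$ymin + boxes$ymax) / 2 / image_height
  w <- (boxes$xmax - boxes$xmin) / image_width
  h <- (boxes$ymax - boxes$ymin) / image_height
  conf <- boxes$confidence
  lines <- character(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    lines[i] <- if (is.na(conf[i]))
      sprintf("%d %.6f %.6f %.6f %.6f", as.integer(cls[i]), cx[i], cy[i],
              w[i], h[i])
    else
      sprintf("%d %.6f %.6f %.6f %.6f %.6f", as.integer(cls[i]), cx[i],
              cy[i], w[i], h[i], conf[i])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Box centroids
#'
#' The centroid of an axis-aligned box is the midpoint of its corners,
#' `((xmin + xmax)/2, (ymin + ymax)/2)`.
#'
#' @param boxes Bounding-box data frame.
#' @return Data frame with columns `x` and `y`, one row per box.
#' @export
box_centroid <- function(boxes) {
  validate_boxes(boxes)
  data.frame(x = (boxes$xmin + boxes$xmax) / 2,
             y = (boxes$ymin + boxes$ymax) / 2)
}

#' Tight bounding boxes from an instance label image
#'
#' For every nonzero label value present in the image, returns the tight
#' box over its pixels in the half-open continuous convention:
#' `xmin` = leftmost column, `xmax` = rightmost column + 1 (0-based), and
#' likewise for rows. Labels listed in `label_map` but absent from the
#' raster are omitted with a warning.
#'
#' @param img Integer matrix (rows = y, columns = x), background 0.
#' @param label_map Named vector mapping vertebra names to pixel values;
#'   values found in the image but not in the map keep `NA` labels.
#' @return Bounding-box data frame ordered by increasing pixel value.
#' @export
boxes_from_label_image <- function(img, label_map = default_label_map()) {
  stopifnot(is.matrix(img))
  values <- sort(unique(as.vector(img)))
  values <- values[values != 0]
  if (length(values) == 0) {
    warning("label image contains no nonzero labels")
    return(bounding_box(numeric(0), numeric(0), numeric(0), numeric(0)))
  }
  missing <- setdiff(label_map, values)
  if (length(missing) > 0)
    warning(sprintf("labels absent from image: %s",
                    paste(names(label_map)[match(missing, label_map)],
                          collapse = ", ")))
  out <- lapply(values, function(v) {
    idx <- which(img == v, arr.ind = TRUE)
    name <- names(label_map)[match(v, label_map)]
    if (is.null(name)) name <- NA_character_
    bounding_box(xmin = min(idx[, 2]) - 1, ymin = min(idx[, 1]) - 1,
                 xmax = max(idx[, 2]), ymax = max(idx[, 1]),
                 label = name)
  })
  do.call(rbind, out)
}

#' Sort vertebra boxes superiorly to inferiorly and name them
#'
#' The detector localizes every vertebra as the same class, so anatomical
#' identity is assigned geometrically: boxes are sorted by centroid y
#' ascending (superior = smaller row index in a head-up sagittal image) and
#' labeled L1, L2, L3, L4, L5, S in that order. Ties in centroid y are
#' broken by centroid x ascending.
#'
#' @param boxes Bounding-box data frame.
#' @param expected Number of vertebrae expected (default 6).
#' @return The boxes reordered, with `label` filled in.
#' @export
sort_vertebrae <- function(boxes, expected = 6L) {
  validate_boxes(boxes)
  if (nrow(boxes) != expected)
    stop(sprintf("expected %d vertebra boxes, found %d", expected,
                 nrow(boxes)))
  ctr <- box_centroid(boxes)
  ord <- order(ctr$y, ctr$x)
  boxes <- boxes[ord, , drop = FALSE]
  boxes$label <- vertebra_labels()[seq_len(expected)]
  rownames(boxes) <- NULL
  boxes
}

#' Read / write an 8-bit instance label image as PNG
#'
#' Label images are single-channel 8-bit PNGs whose pixel values are the
#' instance labels (0 background, 1..6 = L1..L5, S by default).
#'
#' @param path PNG file path.
#' @return `read_label_png()`: an integer matrix.
#' @export
read_label_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  m <- round(x * 255)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_label_png
#' @param img Integer matrix of labels in `0..255`.
#' @export
write_label_png <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 255))
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read / write a per-case angle and grade table
#'
#' Plain CSV with header `case_id,lla_deg,lsa_deg,grade`.
#'
#' @param path CSV path.
#' @return `read_angle_table()`: a data frame.
#' @export
read_angle_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_angle_table
#' @param tab Data frame with columns `case_id`, `lla_deg`, `lsa_deg`,
#'   `grade` (extra columns are kept).
#' @export
write_angle_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
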