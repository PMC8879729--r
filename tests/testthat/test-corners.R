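test_that("Gaussian smoothing preserves constants, mass, and the kernel", {
  m <- matrix(3.7, 20, 25)
  expect_equal(gaussian_smooth(m, 1), m, tolerance = 1e-9)

  set.seed(2)
  r <- matrix(runif(30 * 30), 30, 30)
  expect_equal(sum(gaussian_smooth(r, 1.5)), sum(r), tolerance = 1e-6)

  # unit impulse: center equals the separable discrete kernel at (0, 0)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussian_smooth(imp, 1)
  g <- dnorm(-4:4, sd = 1); g <- g / sum(g)
  expect_equal(sm[11, 11], g[5]^2, tolerance = 1e-12)
})

test_that("Harris response is zero on flat images and favors corners over edges", {
  expect_equal(harris_response(matrix(1, 10, 10)),
               matrix(0, 10, 10), tolerance = 1e-12)

  # step edge: interior responses are non-positive; square corner: positive
  edge <- matrix(0, 64, 64); edge[, 33:64] <- 1
  r_edge <- harris_response(gaussian_smooth(edge, 1))
  interior <- r_edge[20:44, 20:44]
  sq <- square_image()
  r_sq <- harris_response(gaussian_smooth(sq, 1))
  expect_lte(max(interior), 0)
  expect_gt(max(r_sq), 0)
  expect_gt(max(r_sq), 100 * max(interior))
})

test_that("Harris response is equivariant under quarter-turn rotation", {
  set.seed(9)
  m <- gaussian_smooth(matrix(runif(40 * 40), 40, 40), 1)
  r1 <- harris_response(m)
  rot90 <- function(x) t(x)[, nrow(x):1, drop = FALSE]
  r2 <- harris_response(rot90(m))
  expect_equal(r2, rot90(r1), tolerance = 1e-6)
})

test_that("corner candidates recover square corners, rotated or not", {
  expect_equal(nrow(detect_corners(matrix(0, 10, 10))), 0)

  for (ang in c(0, 30)) {
    img <- square_image(angle_deg = ang)
    resp <- harris_response(gaussian_smooth(img, 1))
    cand <- detect_corners(resp)
    truth <- square_corners(angle_deg = ang)
    expect_gte(nrow(cand), 4)
    # the raw response peak carries the operator's inward localization
    # bias of about 1.5 px on the diagonal; the full vertebra pipeline
    # compensates it (see the phantom recovery tests)
    expect_true(all(nearest_dist(truth, cand) <= 2.5),
                label = sprintf("square at %d deg within 2.5 px", ang))
  }
})

test_that("anatomical assignment picks one corner per quadrant by response", {
  rect <- data.frame(x = c(10, 30, 10, 30), y = c(10, 10, 20, 20),
                     response = c(5, 4, 4, 5))
  cs <- assign_anatomical_corners(rect, centroid = c(20, 15))
  expect_s3_class(cs, "corner_set")
  expect_equal(cs$x, c(10, 30, 10, 30))
  expect_equal(cs$y, c(10, 10, 20, 20))

  # spurious lower-response mid-edge points are ignored
  spur <- rbind(rect, data.frame(x = c(20, 10), y = c(9.5, 15),
                                 response = c(1, 1)))
  cs2 <- assign_anatomical_corners(spur, centroid = c(20, 15))
  expect_equal(cs2[, c("x", "y")], cs[, c("x", "y")])

  expect_error(assign_anatomical_corners(rect[1:3, ], centroid = c(20, 15)),
               "quadrant.*empty")
})

test_that("assigned corner sets satisfy the frame invariants", {
  set.seed(21)
  for (rep in 1:20) {
    pts <- data.frame(x = runif(8, 0, 40), y = runif(8, 0, 40),
                      response = runif(8))
    ctr <- c(mean(pts$x), mean(pts$y))
    cs <- tryCatch(assign_anatomical_corners(pts, ctr),
                   error = function(e) NULL)
    if (is.null(cs)) next
    expect_lte(cs$y[cs$corner == "superior_left"],
               cs$y[cs$corner == "inferior_left"])
    expect_lte(cs$x[cs$corner == "superior_left"],
               cs$x[cs$corner == "superior_right"])
  }
})

test_that("vertebra corners recover phantom ground truth", {
  case <- generate_phantom(phantom_spec(seed = 8))
  for (v in c("L1", "L5", "S")) {
    cs <- vertebra_corners(case$label_image, v)
    errs <- corner_errors(case$true_corners[[v]], cs)
    expect_true(all(errs <= 2), label = sprintf("%s corners within 2 px", v))
  }
})

test_that("corner detection is stable to the crop margin", {
  case <- generate_phantom(phantom_spec(seed = 12))
  a <- vertebra_corners(case$label_image, "L5", margin_sigmas = 4)
  b <- vertebra_corners(case$label_image, "L5", margin_sigmas = 6)
  expect_true(all(sqrt((a$x - b$x)^2 + (a$y - b$y)^2) <= 0.5))
})

test_that("corner detection is translation-equivariant", {
  case <- generate_phantom(phantom_spec(seed = 15))
  img <- case$label_image
  shifted <- matrix(0L, nrow(img), ncol(img))
  shifted[11:nrow(img), 6:ncol(img)] <-
    img[1:(nrow(img) - 10), 1:(ncol(img) - 5)]
  a <- vertebra_corners(img, "L1")
  b <- vertebra_corners(shifted, "L1")
  expect_equal(b$x, a$x + 5, tolerance = 1e-9)
  expect_equal(b$y, a$y + 10, tolerance = 1e-9)
})

test_that("a mask touching the image border still yields four corners", {
  img <- matrix(0L, 40, 40)
  img[1:12, 1:20] <- 1L
  cs <- vertebra_corners(img, 1, label_map = c(L1 = 1))
  expect_equal(nrow(cs), 4)
  expect_equal(sort(cs$corner),
               sort(c("superior_left", "superior_right",
                      "inferior_left", "inferior_right")))
})

test_that("absent vertebra raises a lookup error", {
  img <- matrix(0L, 20, 20); img[5:10, 5:10] <- 1L
  expect_error(vertebra_corners(img, "S"), "not present")
  expect_error(vertebra_corners(img, "nope"), "unknown vertebra")
})
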