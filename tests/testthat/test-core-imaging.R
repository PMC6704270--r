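test_that("TIFF round-trip preserves synthetic scenes bit-exactly", {
  sc <- make_node_scene(1.5, seed = 11)
  tmp <- withr::local_tempfile(fileext = ".tif")
  write_image(sc$image, tmp)
  back <- read_image(tmp, c(TDTOMATO = 0, CASPR = 1, MBP = 2), pixel_size = 0.05)
  expect_identical(back$channels, sc$image$channels)
  expect_equal(back$pixel_size, 0.05)

  # z-stacks round-trip through the channel-major plane layout too
  st <- make_node_scene(1.0, seed = 3, n_slices = 3)
  tmp2 <- withr::local_tempfile(fileext = ".tif")
  write_image(st$image, tmp2)
  back2 <- read_image(tmp2, c(TDTOMATO = 0, CASPR = 1, MBP = 2),
                      pixel_size = 0.05, n_slices = 3)
  expect_identical(back2$channels, st$image$channels)
})

test_that("read_image validates files, channel bounds and calibration", {
  expect_error(read_image(tempfile(), c(MBP = 0), 0.1), class = "myelin_missing_file")
  sc <- make_node_scene(1, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".tif")
  write_image(sc$image, tmp)
  expect_error(read_image(tmp, c(MBP = 3), 0.1), class = "myelin_bad_role")
  expect_error(read_image(tmp, c(MBP = 0), -1), class = "myelin_bad_calibration")
})

test_that("calibrated_image enforces its invariants", {
  m <- matrix(1, 4, 4)
  expect_error(calibrated_image(list(BOGUS = m), 0.1), class = "myelin_bad_role")
  expect_error(calibrated_image(list(MBP = m, MBP = m), 0.1), class = "myelin_bad_role")
  expect_error(calibrated_image(list(MBP = m - 2), 0.1), class = "myelin_bad_image")
  expect_error(calibrated_image(list(MBP = m), 0), class = "myelin_bad_calibration")
  expect_error(calibrated_image(list(MBP = m, CASPR = matrix(1, 3, 3)), 0.1),
               class = "myelin_bad_image")
})

test_that("max_project computes elementwise maxima and caps at five slices", {
  s1 <- matrix(c(1, 3, 5, 0), 2, 2, byrow = TRUE)
  s2 <- matrix(c(4, 0, 2, 7), 2, 2, byrow = TRUE)
  stack <- calibrated_image(list(MBP = array(c(s1, s2), c(2, 2, 2))), 0.1)
  out <- max_project(stack, c(1, 2))
  expect_equal(channel(out, "MBP"), matrix(c(4, 3, 5, 7), 2, 2, byrow = TRUE))

  # idempotent over identical slices, commutative over selection order
  same <- calibrated_image(list(MBP = array(rep(s1, 3), c(2, 2, 3))), 0.1)
  expect_equal(channel(max_project(same), "MBP"), s1)
  expect_equal(channel(max_project(stack, c(2, 1)), "MBP"),
               channel(max_project(stack, c(1, 2)), "MBP"))

  big <- calibrated_image(list(MBP = array(0, c(2, 2, 7))), 0.1)
  expect_error(max_project(big, 1:6), class = "myelin_bad_slices")
  expect_error(max_project(big, integer()), class = "myelin_bad_slices")
  expect_error(max_project(big, c(1, 8)), class = "myelin_bad_slices")

  # projection dominates every input slice pixelwise
  sc <- make_node_scene(1, seed = 5, n_slices = 3)
  proj <- channel(max_project(sc$image), "CASPR")
  for (s in 1:3) expect_true(all(proj >= channel(sc$image, "CASPR")[, , s]))
})

test_that("extract_profile averages the perpendicular band with calibration", {
  const <- tiny_image(matrix(7, 32, 32))
  p <- polyline_path(rbind(c(5, 16), c(25, 16)), thickness = 5)
  prof <- extract_profile(const, "MBP", p)
  expect_true(all(prof$intensities == 7))
  expect_equal(max(prof$positions), 20 * 0.1)      # 20 px at 0.1 um/px

  # vertical gradient I(x, y) = y, horizontal path at y = 10, thickness 3:
  # every sample is mean(rows 9, 10, 11) = 10
  grad <- tiny_image(row(matrix(0, 32, 32)) - 1)
  p3 <- polyline_path(rbind(c(4, 10), c(28, 10)), thickness = 3)
  prof3 <- extract_profile(grad, "MBP", p3)
  expect_equal(prof3$intensities, rep(10, length(prof3$intensities)))

  # positions strictly increasing; last equals arc length within a sample
  expect_true(all(diff(prof3$positions) > 0))
  expect_lt(abs(max(prof3$positions) - 24 * 0.1), 0.1)

  expect_error(extract_profile(const, "MBP", polyline_path(rbind(c(0, 0), c(40, 0)))),
               class = "myelin_path_out_of_bounds")
  expect_error(extract_profile(const, "CASPR", p), class = "myelin_missing_role")
})

test_that("polyline_path rejects degenerate geometry and even thickness", {
  expect_error(polyline_path(rbind(c(0, 0))), class = "myelin_bad_path")
  expect_error(polyline_path(rbind(c(0, 0), c(0, 0))), class = "myelin_bad_path")
  expect_error(polyline_path(rbind(c(0, 0), c(5, 5)), thickness = 4),
               class = "myelin_bad_path")
})

test_that("binarize matches the exhaustive Otsu oracle and fixed thresholds", {
  m <- matrix(c(0, 10, 4, 6), 2, 2, byrow = TRUE)
  bm <- binarize(tiny_image(m), "MBP", method = "fixed", threshold = 5)
  expect_equal(bm$pixels, matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2, byrow = TRUE))

  # bimodal: Otsu must select exactly the bright class
  set.seed(42)
  v <- sample(c(rep(10, 60), rep(200, 40)))
  bim <- tiny_image(matrix(v, 10, 10))
  bo <- binarize(bim, "MBP", method = "otsu")
  expect_equal(sum(bo$pixels), 40)
  expect_equal(bo$provenance$threshold, 200)

  # random images agree with the definitional search
  for (s in 1:5) {
    set.seed(s)
    vals <- sample(0:30, 100, replace = TRUE)
    expect_equal(otsu_threshold(vals), oracle_otsu(vals))
  }

  expect_error(binarize(tiny_image(matrix(0, 4, 4)), "MBP"),
               class = "myelin_constant_image")
})

test_that("Otsu agrees with EBImage's histogram implementation on [0,1] data", {
  skip_if_not_installed("EBImage")
  set.seed(7)
  v <- c(rnorm(300, 0.25, 0.04), rnorm(200, 0.7, 0.05))
  v <- pmin(pmax(round(v * 255) / 255, 0), 1)
  mine <- otsu_threshold(v)
  theirs <- EBImage::otsu(matrix(v, 25, 20), range = c(0, 1), levels = 256)
  # the between-class variance is flat across the empty gap between classes,
  # so thresholds may differ within it: the induced masks must agree
  expect_identical(v >= mine, v > theirs)
})

test_that("fixed-threshold mask cardinality is non-increasing in the threshold", {
  set.seed(10)
  img <- tiny_image(matrix(sample(0:100, 400, TRUE), 20, 20))
  counts <- vapply(seq(0, 100, by = 10),
                   function(t) sum(binarize(img, "MBP", "fixed", threshold = t)$pixels),
                   0)
  expect_true(all(diff(counts) <= 0))
})
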