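spot_image <- function(centers, amps, size = 64L, sigma = 2.5, background = 0) {
  m <- matrix(background, size, size)
  half <- ceiling(4 * sigma)
  off <- seq(-half, half)
  for (i in seq_len(nrow(centers))) {
    blob <- amps[i] * exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
    rows <- centers[i, 2] + off + 1
    cols <- centers[i, 1] + off + 1
    m[rows, cols] <- m[rows, cols] + blob
  }
  tiny_image(round(m), role = "OLIG2", pixel_size = 1)
}

test_that("find_maxima applies the prominence (noise tolerance) rule", {
  one <- spot_image(cbind(30, 30), 150)
  d <- find_maxima(one, "OLIG2", 100)
  expect_equal(nrow(d$points), 1L)
  expect_lt(max(abs(d$points[1, c("x", "y")] - c(30, 30))), 1 + 1e-9)

  low <- spot_image(rbind(c(18, 18), c(45, 45)), c(90, 90))
  expect_equal(nrow(find_maxima(low, "OLIG2", 100)$points), 0L)

  mix <- spot_image(rbind(c(12, 12), c(32, 48), c(52, 12)), c(150, 110, 90))
  expect_equal(nrow(find_maxima(mix, "OLIG2", 100)$points), 2L)
})

test_that("find_maxima agrees with the brute-force prominence oracle", {
  # distinct values: the definitional oracle assumes no summit plateaus or
  # tied peak heights (how ties merge is a convention, not a property)
  set.seed(31)
  for (rep in 1:12) {
    m <- matrix(sample(0:999, 12 * 12), 12, 12)
    for (tol in c(3, 10, 25)) {
      got <- nrow(find_maxima(tiny_image(m, pixel_size = 1), "MBP", tol)$points)
      expect_equal(got, oracle_maxima_count(m, tol),
                   info = sprintf("rep %d tol %d", rep, tol))
    }
  }
})

test_that("summit plateaus yield one detection at the plateau centroid", {
  m <- matrix(0, 20, 20)
  m[10:11, 8:9] <- 50                       # 2x2 plateau
  d <- find_maxima(tiny_image(m, pixel_size = 1), "MBP", 10)
  expect_equal(nrow(d$points), 1L)
  expect_equal(d$points$x, 7.5)             # 0-based centroid of cols 8:9
  expect_equal(d$points$y, 9.5)
})

test_that("detection count is monotone non-increasing in noise tolerance", {
  f <- make_nucleus_field(n_a = 35, seed = 17)
  counts <- vapply(seq(0, 200, by = 20),
                   function(tol) nrow(find_maxima(f$image, "OLIG2", tol)$points), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("planted nuclei are recovered exactly and localised within 1 px", {
  for (s in 1:10) {
    f <- make_nucleus_field(n_a = 20 + 3 * s, n_b = 15, seed = s)
    d <- find_maxima(f$image, "OLIG2", 110)
    truth <- f$truth$truths$centers_a
    expect_equal(nrow(d$points), nrow(truth))
    dmat <- sqrt(outer(d$points$x, truth[, 1], "-")^2 +
                   outer(d$points$y, truth[, 2], "-")^2)
    expect_lt(max(apply(dmat, 2, min)), 1 + 1e-9)
  }
})

test_that("double-positive counting is a maximum one-to-one matching", {
  a <- fake_detection(rbind(c(0, 0)))
  b <- fake_detection(rbind(c(0, 0.5), c(0, 0.8)), marker = "CC1")
  expect_equal(count_double_positive(a, b, radius_um = 1), 1L)

  same <- fake_detection(rbind(c(1, 1), c(5, 5), c(9, 2)))
  expect_equal(count_double_positive(same, same, radius_um = 0.5), 3L)

  far_a <- fake_detection(rbind(c(0, 0), c(50, 50)))
  far_b <- fake_detection(rbind(c(20, 20), c(70, 70)), marker = "CC1")
  expect_equal(count_double_positive(far_a, far_b, radius_um = 3), 0L)

  # a case where greedy nearest-first would fail but maximum matching gets 2:
  # a1 is nearest to b1, but a2 can only use b1
  a2 <- fake_detection(rbind(c(0, 0), c(2, 0)))
  b2 <- fake_detection(rbind(c(1.2, 0), c(-0.9, 0)), marker = "CC1")
  expect_equal(count_double_positive(a2, b2, radius_um = 1.3), 2L)

  expect_error(count_double_positive(a, fake_detection(rbind(c(0, 0)), dim = c(50L, 50L)),
                                     radius_um = 1),
               class = "myelin_bad_image")
})

test_that("matching equals brute-force optimum and is symmetric on random sets", {
  set.seed(77)
  for (rep in 1:20) {
    na <- sample(0:8, 1); nb <- sample(0:8, 1)
    A <- matrix(runif(2 * na, 0, 10), ncol = 2)
    B <- matrix(runif(2 * nb, 0, 10), ncol = 2)
    da <- fake_detection(A); db <- fake_detection(B, marker = "CC1")
    r <- runif(1, 0.5, 6)
    got <- if (na && nb) count_double_positive(da, db, radius_um = r) else 0L
    d_ok <- if (na && nb)
      sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2) <= r
    else matrix(FALSE, na, nb)
    expect_equal(got, oracle_matching(d_ok))
    if (na && nb) {
      expect_equal(got, count_double_positive(db, da, radius_um = r))
      expect_lte(got, min(na, nb))
    }
  }
})

test_that("densities convert counts through the calibrated area", {
  f <- make_nucleus_field(n_a = 50, n_b = 20, frac_double = 0, seed = 3,
                          size_px = c(500L, 1000L), pixel_size_um = 1)
  a <- find_maxima(f$image, "OLIG2", 110)
  b <- find_maxima(f$image, "CC1", 90)
  dens <- marker_density(a, b, 0, f$image)
  expect_equal(dens$area_mm2, 0.5)
  expect_equal(dens$density_a, 100)          # 50 cells on 0.5 mm^2
  expect_equal(dens$density_double, 0)

  # 1000 x 1000 px at 1 um/px is exactly 1 mm^2
  f2 <- make_nucleus_field(n_a = 270, n_b = 0, frac_double = 0, seed = 4,
                           size_px = c(1000L, 1000L), min_sep_px = 14)
  a2 <- find_maxima(f2$image, "OLIG2", 110)
  b2 <- find_maxima(f2$image, "CC1", 90)
  dens2 <- marker_density(a2, b2, 0, f2$image)
  expect_equal(dens2$area_mm2, 1)
  expect_equal(dens2$density_a, 270)
})
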