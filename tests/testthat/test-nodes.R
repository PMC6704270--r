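test_that("the piecewise-linear worked example gives exactly 1.0 um", {
  prof <- line_profile(0:4, c(40, 100, 40, 100, 40))
  m <- node_length_from_profile(prof)
  expect_equal(m$peak_left_int, 100)
  expect_equal(m$valley_min_int, 40)
  expect_equal(m$half_level_left, 70)
  expect_equal(m$halfmax_left_pos, 1.5)
  expect_equal(m$halfmax_right_pos, 2.5)
  expect_equal(m$node_length, 1.0)
})

test_that("Gaussian paranodes give half-max crossings at peak +/- sigma*sqrt(2 ln 2)", {
  sigma <- 0.2
  x <- seq(1.5, 4.5, by = 0.01)
  prof <- line_profile(x - 1.5,
                       100 * (exp(-(x - 2)^2 / (2 * sigma^2)) +
                                exp(-(x - 4)^2 / (2 * sigma^2))))
  m <- node_length_from_profile(prof)
  hw <- sigma * sqrt(2 * log(2))
  expect_lt(abs(m$halfmax_left_pos - (2 - 1.5 + hw)), 0.01)   # one sample spacing
  expect_lt(abs(m$halfmax_right_pos - (4 - 1.5 - hw)), 0.01)
  expect_lt(abs(m$node_length - (2 - 2 * hw)), 0.02)
})

test_that("node length is mirror-symmetric, offset- and scale-invariant", {
  set.seed(8)
  for (i in 1:10) {
    sc <- make_node_scene(runif(1, 0.8, 2), seed = i)
    prof <- extract_profile(max_project(sc$image), "CASPR", sc$path)
    m <- node_length_from_profile(prof)

    rev_prof <- line_profile(max(prof$positions) - rev(prof$positions),
                             rev(prof$intensities))
    expect_equal(node_length_from_profile(rev_prof)$node_length, m$node_length,
                 tolerance = 1e-10)

    scaled <- line_profile(prof$positions, prof$intensities * 3.7)
    expect_equal(node_length_from_profile(scaled)$node_length, m$node_length)

    offset <- line_profile(prof$positions, prof$intensities + 55)
    expect_equal(node_length_from_profile(offset)$node_length, m$node_length)
  }
})

test_that("node measurements satisfy their structural invariants", {
  set.seed(41)
  for (i in 1:15) {
    gap <- runif(1, 0.5, 2.5)
    sc <- make_node_scene(gap, seed = i + 100)
    m <- measure_node(sc$image, sc$path)
    expect_lt(m$peak_left_pos, m$halfmax_left_pos)
    expect_lte(m$halfmax_left_pos, m$halfmax_right_pos)
    expect_lt(m$halfmax_right_pos, m$peak_right_pos)
    expect_equal(m$node_length, m$halfmax_right_pos - m$halfmax_left_pos)
    expect_lt(m$valley_min_int, min(m$peak_left_int, m$peak_right_int))
    expect_equal(m$half_level_left,
                 m$valley_min_int + (m$peak_left_int - m$valley_min_int) / 2)
  }
})

test_that("unquantifiable profiles raise distinct named failures", {
  expect_error(node_length_from_profile(line_profile(0:3, c(1, 2, 1, 2))),
               class = "myelin_node_no_peaks")
  expect_error(node_length_from_profile(line_profile(0:5, rep(5, 6))),
               class = "myelin_node_flat")
  # abutting paranodes: planted gap 0 must not yield a quiet wrong answer
  sc0 <- make_node_scene(0, seed = 2, snr = Inf)
  res <- tryCatch(measure_node(sc0$image, sc0$path),
                  myelin_error = function(e) e)
  if (inherits(res, "node_measurement")) {
    expect_lt(res$node_length, 0.05)         # below one sampling step
  } else {
    expect_s3_class(res, "myelin_error")
  }
})

test_that("candidate validation requires axon, paranodes and flanking myelin", {
  sc <- make_node_scene(1.5, seed = 6)
  cand <- validate_candidate(sc$image, sc$path)
  expect_true(cand$accepted)

  no_caspr <- sc$image
  no_caspr$channels$CASPR[] <- 1
  # fixed thresholds: otsu is undefined on the ablated constant channel
  rules <- list(TDTOMATO = 100, CASPR = 100, MBP = 100)
  c2 <- validate_candidate(no_caspr, sc$path, rules = rules)
  expect_false(c2$checks[["paranodes_present"]])
  expect_false(c2$accepted)

  no_mbp <- sc$image
  no_mbp$channels$MBP[] <- 1
  c3 <- validate_candidate(no_mbp, sc$path, rules = rules)
  expect_false(c3$checks[["myelin_flanking"]])
  expect_false(c3$accepted)

  expect_error(validate_candidate(tiny_image(matrix(1, 8, 8)), sc$path),
               class = "myelin_missing_role")
})

test_that("planted nodal gaps are recovered from rendered scenes", {
  sc <- make_node_scene(1.5, seed = 9, snr = 10)
  m <- measure_node(sc$image, sc$path)
  expect_lt(abs(m$node_length - 1.5), 0.1)

  # thickness robustness at high SNR
  sc2 <- make_node_scene(1.5, seed = 10, snr = 20)
  m5 <- measure_node(sc2$image, sc2$path)
  path1 <- polyline_path(sc2$path$vertices, thickness = 1)
  m1 <- measure_node(sc2$image, path1)
  expect_lt(abs(m5$node_length - m1$node_length), 0.1)

  # stacks: projection of <= 5 slices feeds the same measurement
  st <- make_node_scene(1.2, seed = 12, n_slices = 5)
  ms <- measure_node(st$image, st$path, slices = 1:5)
  expect_lt(abs(ms$node_length - 1.2), 0.1)
})

test_that("measure_nodes tabulates successes and failure reasons", {
  sc <- make_node_scene(1.5, seed = 13, snr = Inf)
  flat <- polyline_path(rbind(c(2, 2), c(30, 2)), thickness = 1)  # off-axon line
  out <- measure_nodes(sc$image, list(good = sc$path, off = flat))
  expect_equal(nrow(out), 2L)
  expect_equal(out$failure[out$node_id == "good"], "")
  expect_false(is.na(out$node_length[out$node_id == "good"]))
  expect_match(out$failure[out$node_id == "off"], "myelin_node")
  expect_true(is.na(out$node_length[out$node_id == "off"]))
})
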