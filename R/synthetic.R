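# Seeded scene generators. Every generator: (1) calls set.seed(seed) so the
# same (parameters, seed) pair reproduces the image exactly; (2) quantizes
# intensities to integers in [0, 65535] so scenes survive 16-bit TIFF
# round-trips bit-for-bit; (3) returns a ground-truth record from which every
# planted quantity can be re-derived.

new_ground_truth <- function(seed, scene_kind, parameters, truths) {
  structure(list(seed = seed, scene_kind = scene_kind,
                 parameters = parameters, truths = truths),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s (seed %d)\n", x$scene_kind, x$seed))
  invisible(x)
}

# Gaussian-blurred boxcar evaluated analytically: the along-axis intensity of
# a structure occupying [lo, hi] um imaged with a Gaussian PSF of sd `psf` um.
blurred_boxcar <- function(x, lo, hi, psf) {
  if (psf <= 0) return(as.numeric(x >= lo & x <= hi))
  pnorm((x - lo) / psf) - pnorm((x - hi) / psf)
}

# Signal-dependent shot-like noise: Gaussian, sd scaled as the square root of
# the local expected signal, calibrated so that sd equals `sd_at_peak` where
# the clean image reaches `peak`. snr = Inf disables noise.
add_shot_noise <- function(clean, peak, sd_at_peak) {
  if (!is.finite(sd_at_peak) || sd_at_peak <= 0) return(quantize_intensity(clean))
  sdmap <- sd_at_peak * sqrt(pmax(clean, 1) / peak)
  quantize_intensity(clean + rnorm(length(clean), 0, sdmap))
}

#' Synthetic Node of Ranvier scene
#'
#' Renders a three-channel fluorescence scene around one node: a straight
#' tdTomato axon across the field, two Caspr paranode plateaus of length
#' `paranode_len_um` separated by `gap_um` (the true nodal length, measured
#' between the half-maximum positions of the blurred plateau edges), and MBP
#' sheaths flanking beyond the paranodes. Structures are evaluated
#' analytically (blurred boxcar along the axon times a Gaussian radial
#' profile) and corrupted by seeded signal-dependent noise.
#'
#' SNR is defined as `(peak - background) / noise sd at the peak signal
#' level`; `snr = Inf` gives a noise-free scene.
#'
#' @param gap_um true nodal gap in micrometres (>= 0).
#' @param paranode_len_um paranode plateau length (default 2 um).
#' @param amplitude peak intensity above background (default 200).
#' @param snr signal-to-noise ratio (default 10).
#' @param pixel_size_um pixel size (default 0.05 um).
#' @param seed RNG seed.
#' @param background baseline intensity (default 10).
#' @param height_px field height (default 48).
#' @param margin_um dark margin beyond the MBP sheaths (default 2 um).
#' @param axon_sigma_um radial (cross-axon) Gaussian sd (default 0.15 um).
#' @param psf_sigma_um along-axis blur sd (default 0.1 um).
#' @param thickness measurement-line thickness in pixels (default 5).
#' @param n_slices z-slices; > 1 renders a stack with an axial intensity
#'   falloff so the in-focus content is recovered by [max_project()].
#' @param z_step_um slice spacing (default 0.482 um).
#' @return `list(image, path, truth)`: the [calibrated_image()], the
#'   measurement [polyline_path()] spanning the paranode pair, and the
#'   `ground_truth` (with `truths$gap_um` the plantable nodal length).
#' @export
make_node_scene <- function(gap_um, paranode_len_um = 2, amplitude = 200,
                            snr = 10, pixel_size_um = 0.05, seed = 1,
                            background = 10, height_px = 48, margin_um = 2,
                            axon_sigma_um = 0.15, psf_sigma_um = 0.1,
                            thickness = 5L, n_slices = 1L, z_step_um = 0.482) {
  stopifnot(gap_um >= 0, snr > 0, pixel_size_um > 0, paranode_len_um > 0)
  set.seed(seed)
  width_um <- gap_um + 2 * paranode_len_um + 2 * margin_um
  width_px <- ceiling(width_um / pixel_size_um) + 1L
  xu <- (seq_len(width_px) - 1) * pixel_size_um
  yu <- (seq_len(height_px) - 1) * pixel_size_um
  xc <- (width_px - 1) * pixel_size_um / 2
  yc <- (height_px - 1) * pixel_size_um / 2

  gl <- xc - gap_um / 2                      # inner paranode edges
  gr <- xc + gap_um / 2
  pl <- gl - paranode_len_um                 # outer paranode edges
  pr <- gr + paranode_len_um

  radial <- exp(-(yu - yc)^2 / (2 * axon_sigma_um^2))
  radial_wide <- exp(-(yu - yc)^2 / (2 * (2 * axon_sigma_um)^2))

  ax_caspr <- blurred_boxcar(xu, pl, gl, psf_sigma_um) +
    blurred_boxcar(xu, gr, pr, psf_sigma_um)
  ax_td <- rep(1, width_px)
  ax_mbp <- blurred_boxcar(xu, margin_um / 2, pl, psf_sigma_um) +
    blurred_boxcar(xu, pr, width_um - margin_um / 2, psf_sigma_um)

  amp <- amplitude - background
  clean <- list(
    TDTOMATO = background + amp * outer(radial, ax_td),
    CASPR = background + amp * outer(radial, ax_caspr),
    MBP = background + amp * outer(radial_wide, ax_mbp))

  sd_peak <- if (is.finite(snr)) amp / snr else 0
  render <- function(m) add_shot_noise(m, peak = amplitude, sd_at_peak = sd_peak)
  channels <- if (n_slices > 1L) {
    mid <- (n_slices + 1) / 2
    w <- exp(-((seq_len(n_slices) - mid) * z_step_um)^2 / (2 * 0.5^2))
    lapply(clean, function(m) {
      array(unlist(lapply(w, function(wk) render(background + (m - background) * wk))),
            dim = c(dim(m), n_slices))
    })
  } else {
    lapply(clean, render)
  }
  img <- calibrated_image(channels, pixel_size_um, unit = "um",
                          z_step = if (n_slices > 1L) z_step_um else NULL)

  inset_um <- min(0.3, paranode_len_um / 4)  # path ends inside the plateaus
  path <- polyline_path(rbind(c((pl + inset_um) / pixel_size_um, (height_px - 1) / 2),
                              c((pr - inset_um) / pixel_size_um, (height_px - 1) / 2)),
                        thickness = thickness)
  params <- list(gap_um = gap_um, paranode_len_um = paranode_len_um,
                 amplitude = amplitude, snr = snr, pixel_size_um = pixel_size_um,
                 background = background, height_px = height_px,
                 margin_um = margin_um, axon_sigma_um = axon_sigma_um,
                 psf_sigma_um = psf_sigma_um, thickness = thickness,
                 n_slices = n_slices, z_step_um = z_step_um)
  truth <- new_ground_truth(seed, "node_scene", params,
                            list(gap_um = gap_um, node_center_um = xc,
                                 paranode_edges_um = c(pl, gl, gr, pr)))
  list(image = img, path = path, truth = truth)
}

# Rasterize one smooth random curve into TRUE pixels of `mask`, 3 px wide.
draw_fiber <- function(mask, start, angle0) {
  nr <- nrow(mask); nc <- ncol(mask)
  n_steps <- nr + nc
  angles <- angle0 + cumsum(rnorm(n_steps, 0, 0.05))
  x <- start[1] + cumsum(cos(angles))
  y <- start[2] + cumsum(sin(angles))
  keep <- x >= 1 & x <= nc - 2 & y >= 1 & y <= nr - 2
  x <- round(x[keep]); y <- round(y[keep])
  if (!length(x)) return(list(mask = mask, order = integer()))
  idx <- cbind(y + 1, x + 1)
  for (d in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    mask[idx + rep(d, each = nrow(idx))] <- TRUE
  }
  list(mask = mask, order = unique((x) * nr + (y + 1)))  # along-fiber pixel order
}

#' Synthetic field of reporter-labelled axons with partial myelin coverage
#'
#' Generates a tdTomato channel of sparse smooth curvilinear fibres and an MBP
#' channel in which a prescribed set of pixels is bright: a contiguous
#' fraction of each fibre (`sheath_fraction`) plus, when `coverage_target` is
#' given, additional off-fibre myelin pixels (or a random thinning) so that
#' exactly `round(coverage_target * n_pixels)` pixels are suprathreshold.
#' Background noise is bounded (discrete uniform) so the planted coverage is
#' exact under a background mean + 2 sd threshold: no background pixel can
#' cross it. A fibre-free rectangle is reserved for background estimation and
#' recorded in the truth.
#'
#' @param coverage_target fraction of the image that must be MBP+ (`NULL` to
#'   let coverage follow from the sheaths alone).
#' @param sheath_fraction fraction of each fibre's length that is ensheathed.
#' @param seed RNG seed.
#' @param size_px field size `c(rows, cols)` (default 512 x 512).
#' @param pixel_size_um pixel size (default 0.3 um).
#' @param n_fibers number of fibres (default 30).
#' @param amplitude,amplitude_mbp bright-pixel intensities for reporter and
#'   myelin (defaults 180 and 200).
#' @param background baseline (default 10).
#' @return `list(image, truth)`; `truth$truths` records the exact coverage
#'   fraction, the fibre and MBP masks (as logical matrices), the reserved
#'   background rectangle and the realised threshold gap.
#' @export
make_axon_field <- function(coverage_target = NULL, sheath_fraction = 0.5, seed = 1,
                            size_px = c(512L, 512L), pixel_size_um = 0.3,
                            n_fibers = 30L, amplitude = 180, amplitude_mbp = 200,
                            background = 10) {
  stopifnot(is.null(coverage_target) ||
              (coverage_target >= 0 && coverage_target <= 1),
            sheath_fraction >= 0, sheath_fraction <= 1)
  set.seed(seed)
  nr <- size_px[1]; nc <- size_px[2]
  bg_roi <- pixel_rect(4L, 4L, 48L, 48L)

  fiber <- matrix(FALSE, nr, nc)
  sheath_sets <- list()
  for (f in seq_len(n_fibers)) {
    start <- c(runif(1, 2, nc - 3), runif(1, 2, nr - 3))
    res <- draw_fiber(fiber, start, runif(1, 0, 2 * pi))
    fiber <- res$mask
    ord <- res$order
    if (length(ord) && sheath_fraction > 0) {
      len <- max(1L, round(sheath_fraction * length(ord)))
      s0 <- if (len >= length(ord)) 1L else sample.int(length(ord) - len + 1L, 1L)
      sheath_sets[[f]] <- ord[s0:(s0 + len - 1L)]
    }
  }
  # clear the reserved background rectangle
  clear <- matrix(TRUE, nr, nc)
  clear[(bg_roi$y + 1):(bg_roi$y + bg_roi$height),
        (bg_roi$x + 1):(bg_roi$x + bg_roi$width)] <- FALSE
  fiber <- fiber & clear

  # dilate sheath centrelines to the fibre width
  sheath <- matrix(FALSE, nr, nc)
  cl <- unlist(sheath_sets)
  if (length(cl)) {
    row1 <- ((cl - 1) %% nr) + 1          # cl are matrix linear indices
    col1 <- ((cl - 1) %/% nr) + 1
    ok <- row1 >= 2 & row1 <= nr - 1 & col1 >= 2 & col1 <= nc - 1
    row1 <- row1[ok]; col1 <- col1[ok]
    for (d in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      sheath[cbind(row1 + d[1], col1 + d[2])] <- TRUE
    }
  }
  sheath <- sheath & fiber

  mbp_mask <- sheath
  if (!is.null(coverage_target)) {
    target_n <- round(coverage_target * nr * nc)
    have <- which(mbp_mask)
    if (length(have) > target_n) {
      drop <- sample(have, length(have) - target_n)
      mbp_mask[drop] <- FALSE
    } else if (length(have) < target_n) {
      pool <- which(!mbp_mask & clear)
      add <- sample(pool, target_n - length(have))
      mbp_mask[add] <- TRUE
    }
  }

  # bounded discrete-uniform noise keeps background strictly below
  # mean + 2 sd: sd of U{-5..5} is sqrt(10) = 3.16, so the threshold sits
  # near background + 6.3 while no background pixel exceeds background + 5.
  unoise <- function(n, a) sample(seq(-a, a), n, replace = TRUE)
  td <- matrix(background + unoise(nr * nc, 5), nr, nc)
  td[fiber] <- amplitude + unoise(sum(fiber), 10)
  mbp <- matrix(background + unoise(nr * nc, 5), nr, nc)
  mbp[mbp_mask] <- amplitude_mbp + unoise(sum(mbp_mask), 10)

  img <- calibrated_image(list(TDTOMATO = quantize_intensity(td),
                               MBP = quantize_intensity(mbp)),
                          pixel_size_um, unit = "um")
  params <- list(coverage_target = coverage_target, sheath_fraction = sheath_fraction,
                 size_px = size_px, pixel_size_um = pixel_size_um,
                 n_fibers = n_fibers, amplitude = amplitude,
                 amplitude_mbp = amplitude_mbp, background = background)
  truth <- new_ground_truth(seed, "axon_field", params,
                            list(coverage_fraction = sum(mbp_mask) / (nr * nc),
                                 n_mbp = sum(mbp_mask),
                                 fiber_mask = fiber, mbp_mask = mbp_mask,
                                 bg_roi = bg_roi))
  list(image = img, truth = truth)
}

#' Synthetic two-marker nucleus field
#'
#' Plants Gaussian blobs at integer-pixel centres with a minimum separation,
#' some shared between the two marker channels (double-positive cells), over a
#' low bounded-noise background.
#'
#' @param n_a,n_b number of cells positive for markers a (OLIG2) and b (CC1).
#' @param frac_double fraction of `min(n_a, n_b)` that is double-positive.
#' @param amplitudes blob peak heights `c(a, b)` above background.
#' @param seed RNG seed.
#' @param size_px field size (default 512 x 512).
#' @param pixel_size_um pixel size (default 1 um).
#' @param min_sep_px minimum centre separation (default 14 px).
#' @param sigma_px blob sd (default 3 px).
#' @param background baseline (default 10).
#' @return `list(image, truth)`; truth records all centres per marker and the
#'   shared (double-positive) centres.
#' @export
make_nucleus_field <- function(n_a = 40L, n_b = 30L, frac_double = 0.3,
                               amplitudes = c(a = 150, b = 130), seed = 1,
                               size_px = c(512L, 512L), pixel_size_um = 1,
                               min_sep_px = 14, sigma_px = 3, background = 10) {
  stopifnot(n_a >= 0, n_b >= 0, frac_double >= 0, frac_double <= 1)
  set.seed(seed)
  nr <- size_px[1]; nc <- size_px[2]
  n_double <- round(frac_double * min(n_a, n_b))
  n_centers <- n_a + n_b - n_double

  margin <- ceiling(4 * sigma_px)
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < n_centers) {
    tries <- tries + 1L
    if (tries > 200L * max(1L, n_centers)) {
      myelin_error("could not place cells at the requested density / separation",
                   "myelin_packing_failure")
    }
    cand <- c(sample(margin:(nc - 1 - margin), 1), sample(margin:(nr - 1 - margin), 1))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2))) >= min_sep_px) {
      centers <- rbind(centers, cand)
    }
  }
  idx_double <- seq_len(n_double)
  idx_a <- c(idx_double, n_double + seq_len(n_a - n_double))
  idx_b <- c(idx_double, n_double + (n_a - n_double) + seq_len(n_b - n_double))

  render_marker <- function(idx, amp) {
    m <- matrix(background + sample(seq(-3, 3), nr * nc, replace = TRUE), nr, nc)
    half <- ceiling(4 * sigma_px)
    off <- seq(-half, half)
    blob <- amp * exp(-outer(off^2, off^2, "+") / (2 * sigma_px^2))
    for (i in idx) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      rows <- (cy - half):(cy + half) + 1
      cols <- (cx - half):(cx + half) + 1
      m[rows, cols] <- m[rows, cols] + blob
    }
    quantize_intensity(m)
  }
  img <- calibrated_image(list(OLIG2 = render_marker(idx_a, amplitudes[[1]]),
                               CC1 = render_marker(idx_b, amplitudes[[2]])),
                          pixel_size_um, unit = "um")
  params <- list(n_a = n_a, n_b = n_b, frac_double = frac_double,
                 amplitudes = amplitudes, size_px = size_px,
                 pixel_size_um = pixel_size_um, min_sep_px = min_sep_px,
                 sigma_px = sigma_px, background = background)
  truth <- new_ground_truth(seed, "nucleus_field", params,
                            list(centers_a = centers[idx_a, , drop = FALSE],
                                 centers_b = centers[idx_b, , drop = FALSE],
                                 centers_double = centers[idx_double, , drop = FALSE],
                                 n_double = n_double))
  list(image = img, truth = truth)
}

#' Synthetic electron-microscopy field of myelinated axon cross-sections
#'
#' Packs non-overlapping annuli (axon disc + myelin ring) with inner diameters
#' and g-ratios drawn from truncated normal distributions, rasterised into the
#' labelled-mask convention of [annotations_from_labels()] (inner = 2k, ring =
#' 2k + 1). Centres are continuous, so the pixel-counted areas are unbiased
#' estimates of the true disc areas.
#'
#' @param n_axons number of axons to place (the default 20 per 1024 px tile
#'   matches a tissue-like ~40 percent areal fill at the default diameters;
#'   larger cohorts are built from multiple tiles/seeds).
#' @param diameter_dist `c(mean, sd)` of the inner (axon) diameter in nm
#'   (truncated at 160 nm; default 1000 +/- 250).
#' @param g_dist `c(mean, sd)` of the g-ratio, truncated to (0.5, 0.95). The
#'   default per-axon spread of 0.06 is typical of EM morphometry; much larger
#'   values are unphysical for a quantity bounded in (0, 1) and would distort
#'   the realised mean through truncation.
#' @param pixel_size_nm nm per pixel (default 8).
#' @param seed RNG seed.
#' @param size_px field size (default 1024 x 1024).
#' @return `list(labels, truth)`: the integer label matrix and truth with
#'   per-axon centres, true inner diameters (nm) and true g-ratios.
#' @export
make_em_field <- function(n_axons = 20L, diameter_dist = c(1000, 250),
                          g_dist = c(0.8, 0.06), pixel_size_nm = 8, seed = 1,
                          size_px = c(1024L, 1024L)) {
  stopifnot(n_axons >= 0, g_dist[1] > 0, g_dist[1] < 1, pixel_size_nm > 0)
  set.seed(seed)
  nr <- size_px[1]; nc <- size_px[2]
  labels <- matrix(0L, nr, nc)
  if (n_axons == 0L) {
    return(list(labels = labels,
                truth = new_ground_truth(seed, "em_field",
                                         list(n_axons = 0L), list(n_placed = 0L))))
  }
  rtrunc <- function(n, mean, sd, lo, hi) {
    out <- rnorm(n, mean, sd)
    bad <- out < lo | out > hi
    while (any(bad)) {
      out[bad] <- rnorm(sum(bad), mean, sd)
      bad <- out < lo | out > hi
    }
    out
  }
  d_in <- rtrunc(n_axons, diameter_dist[1], max(diameter_dist[2], 1e-9), 160, Inf)
  g <- rtrunc(n_axons, g_dist[1], max(g_dist[2], 1e-9), 0.5, 0.95)
  # place the largest fibres first: random sequential packing then succeeds at
  # the tissue-like fill fractions the defaults produce
  ord <- order(d_in / g, decreasing = TRUE)
  d_in <- d_in[ord]; g <- g[ord]
  r_in_px <- d_in / 2 / pixel_size_nm
  r_out_px <- r_in_px / g

  centers <- matrix(NA_real_, n_axons, 2)
  placed <- logical(n_axons)
  for (k in seq_len(n_axons)) {
    r <- r_out_px[k]
    if (2 * r + 4 > min(nr, nc)) {
      myelin_error("axon larger than the field", "myelin_packing_failure")
    }
    ok <- FALSE
    for (try in seq_len(2000L)) {
      cand <- c(runif(1, r + 1, nc - r - 2), runif(1, r + 1, nr - r - 2))
      prev <- which(placed)
      if (!length(prev) ||
          all(sqrt((centers[prev, 1] - cand[1])^2 + (centers[prev, 2] - cand[2])^2) >=
                r + r_out_px[prev] + 1)) {
        centers[k, ] <- cand
        placed[k] <- TRUE
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      myelin_error(sprintf("packing failure after placing %d of %d axons",
                           sum(placed), n_axons), "myelin_packing_failure")
    }
  }

  for (k in seq_len(n_axons)) {
    cx <- centers[k, 1]; cy <- centers[k, 2]; ro <- r_out_px[k]; ri <- r_in_px[k]
    cols <- max(1, floor(cx - ro)):min(nc, ceiling(cx + ro) + 1)
    rows <- max(1, floor(cy - ro)):min(nr, ceiling(cy + ro) + 1)
    d2 <- outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, "+")
    sub <- labels[rows, cols]
    sub[d2 <= ri^2] <- 2L * k
    sub[d2 > ri^2 & d2 <= ro^2] <- 2L * k + 1L
    labels[rows, cols] <- sub
  }
  params <- list(n_axons = n_axons, diameter_dist = diameter_dist, g_dist = g_dist,
                 pixel_size_nm = pixel_size_nm, size_px = size_px)
  truth <- new_ground_truth(seed, "em_field", params,
                            list(centers_px = centers, inner_diameter_nm = d_in,
                                 g_ratio = g, n_placed = n_axons))
  list(labels = labels, truth = truth)
}
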