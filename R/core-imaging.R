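#' Channel roles understood by the pipeline
#'
#' Roles name what a channel shows, not its position on the microscope:
#' `TDTOMATO` (axon reporter), `MBP` (myelin), `CASPR` (paranodes), `DAPI`,
#' `OLIG2`, `CC1` (nuclear markers) and `EM` (electron-microscopy plane).
#'
#' @export
CHANNEL_ROLES <- c("TDTOMATO", "MBP", "CASPR", "DAPI", "OLIG2", "CC1", "EM")

#' Calibrated multichannel image
#'
#' The container every measurement consumes: one intensity array per channel
#' role plus the spatial calibration. Channels are matrices (2-D images,
#' `[row, col]`) or 3-D arrays (`[row, col, slice]` z-stacks); all channels of
#' one image share dimensions. Intensities are handled as non-negative doubles
#' regardless of the on-disk integer type.
#'
#' Pixel coordinates throughout the package are 0-based with
#' `(x, y) = (column, row)` and pixel centres at integer coordinates.
#'
#' @param channels named list of numeric matrices/arrays; names are roles from
#'   [CHANNEL_ROLES] (case-insensitive), each role at most once.
#' @param pixel_size length of one pixel side, in `unit`s; must be positive.
#' @param unit `"um"` (fluorescence) or `"nm"` (electron microscopy).
#' @param z_step optional slice spacing in `unit`s for z-stacks.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(channels, pixel_size, unit = c("um", "nm"), z_step = NULL) {
  unit <- match.arg(unit)
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels))) {
    myelin_error("`channels` must be a non-empty named list", "myelin_bad_image")
  }
  names(channels) <- toupper(names(channels))
  bad <- setdiff(names(channels), CHANNEL_ROLES)
  if (length(bad)) {
    myelin_error(paste0("unknown channel role(s): ", paste(bad, collapse = ", ")),
                 "myelin_bad_role")
  }
  if (anyDuplicated(names(channels))) {
    myelin_error("each channel role may appear at most once", "myelin_bad_role")
  }
  if (!is_scalar_num(pixel_size) || pixel_size <= 0) {
    myelin_error("pixel_size must be a positive number", "myelin_bad_calibration")
  }
  dims <- lapply(channels, function(ch) dim(ch) %||% length(ch))
  if (length(unique(lapply(dims, identity))) != 1L) {
    myelin_error("all channels must share the same dimensions", "myelin_bad_image")
  }
  for (ch in channels) {
    if (!is.numeric(ch) || anyNA(ch) || min(ch) < 0) {
      myelin_error("channel intensities must be non-negative and finite", "myelin_bad_image")
    }
    nd <- length(dim(ch) %||% integer())
    if (!nd %in% c(2L, 3L)) {
      myelin_error("channels must be 2-D matrices or 3-D arrays", "myelin_bad_image")
    }
    if (nd == 3L && dim(ch)[3] < 1L) {
      myelin_error("3-D channels need at least one slice", "myelin_bad_image")
    }
  }
  if (!is.null(z_step) && (!is_scalar_num(z_step) || z_step <= 0)) {
    myelin_error("z_step must be a positive number", "myelin_bad_calibration")
  }
  structure(list(channels = channels, pixel_size = pixel_size, unit = unit,
                 z_step = z_step),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<calibrated_image> %d x %d px%s, %g %s/px\n",
              d[2], d[1],
              if (length(d) == 3) sprintf(" x %d slices", d[3]) else "",
              x$pixel_size, x$unit))
  cat("  roles:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Access one channel of a calibrated image
#'
#' @param img a [calibrated_image()].
#' @param role channel role name (case-insensitive).
#' @return The channel's matrix or 3-D array.
#' @export
channel <- function(img, role) {
  stopifnot(inherits(img, "calibrated_image"))
  role <- toupper(role)
  if (!role %in% names(img$channels)) {
    myelin_error(paste0("role ", role, " not present in image"), "myelin_missing_role")
  }
  img$channels[[role]]
}

#' Pixel size of an image expressed in micrometres
#' @param img a [calibrated_image()].
#' @return Pixel side length in um.
#' @export
pixel_size_um <- function(img) {
  if (img$unit == "nm") img$pixel_size / 1000 else img$pixel_size
}

n_slices <- function(img) {
  d <- dim(img$channels[[1]])
  if (length(d) == 3L) d[3] else 1L
}

#' Read a TIFF / OME-TIFF into a calibrated image
#'
#' Planes are stored channel-major: all z-slices of the first mapped channel,
#' then the next channel, and so on ([write_image()] writes this layout).
#' Intensities are read bit-exactly (`as.is = TRUE`) and converted to doubles.
#' An explicit `pixel_size` argument always overrides any file metadata.
#'
#' @param path TIFF file path.
#' @param role_map named integer vector mapping roles to 0-based channel
#'   indices, e.g. `c(TDTOMATO = 0, MBP = 1)`.
#' @param pixel_size,unit,z_step calibration, as in [calibrated_image()].
#' @param n_slices number of z-slices per channel (default 1, a 2-D image).
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, role_map, pixel_size, unit = c("um", "nm"),
                       n_slices = 1L, z_step = NULL) {
  if (!file.exists(path)) {
    myelin_error(paste0("no such file: ", path), "myelin_missing_file")
  }
  stopifnot(is_count(n_slices), n_slices >= 1)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  role_map <- setNames(as.integer(role_map), toupper(names(role_map)))
  n_chan_avail <- length(planes) %/% n_slices
  if (any(role_map < 0) || any(role_map >= n_chan_avail)) {
    myelin_error(sprintf("role_map references channel %d but the file holds %d channel(s)",
                         max(role_map), n_chan_avail), "myelin_bad_role")
  }
  channels <- lapply(role_map, function(ci) {
    sl <- lapply(seq_len(n_slices), function(s) {
      m <- planes[[ci * n_slices + s]]
      storage.mode(m) <- "double"
      if (length(dim(m)) == 3L) m <- m[, , 1]  # tolerate grey written as RGB
      m
    })
    if (n_slices == 1L) sl[[1]] else array(unlist(sl), dim = c(dim(sl[[1]]), n_slices))
  })
  calibrated_image(channels, pixel_size, unit = unit, z_step = z_step)
}

#' Write a calibrated image as a multi-plane 16-bit TIFF
#'
#' The inverse of [read_image()]: channel-major planes, one per slice.
#' Intensities must be integers in `[0, 65535]`; the round-trip is then
#' bit-exact.
#'
#' @param img a [calibrated_image()].
#' @param path output file.
#' @return `path`, invisibly. The on-disk channel order is the order of
#'   `img$channels`, so the matching `role_map` is
#'   `setNames(seq_along(img$channels) - 1, names(img$channels))`.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "calibrated_image"))
  planes <- list()
  for (ch in img$channels) {
    if (any(ch != round(ch)) || max(ch) > 65535) {
      myelin_error("write_image stores 16-bit integers; intensities must be whole numbers <= 65535",
                   "myelin_bad_image")
    }
    if (length(dim(ch)) == 3L) {
      for (s in seq_len(dim(ch)[3])) planes <- c(planes, list(ch[, , s] / 65535))
    } else {
      planes <- c(planes, list(ch / 65535))
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Maximum-intensity projection of selected z-slices
#'
#' Collapses a z-stack to a 2-D image by the pixelwise maximum over at most
#' five slices, the cap used when projecting confocal stacks around a node.
#'
#' @param img a [calibrated_image()] (3-D channels; 2-D images are returned
#'   unchanged when the selection is trivial).
#' @param slice_indices 1-based slice indices, between 1 and 5 of them,
#'   distinct. Default: all slices (must then be <= 5).
#' @return A 2-D [calibrated_image()] with the same calibration and roles.
#' @export
max_project <- function(img, slice_indices = NULL) {
  stopifnot(inherits(img, "calibrated_image"))
  nz <- n_slices(img)
  slice_indices <- slice_indices %||% seq_len(nz)
  slice_indices <- as.integer(slice_indices)
  if (length(slice_indices) < 1L) {
    myelin_error("empty slice selection", "myelin_bad_slices")
  }
  if (length(slice_indices) > 5L) {
    myelin_error("at most five slices may be projected", "myelin_bad_slices")
  }
  if (anyDuplicated(slice_indices) || any(slice_indices < 1L) || any(slice_indices > nz)) {
    myelin_error("slice indices must be distinct and within the stack", "myelin_bad_slices")
  }
  channels <- lapply(img$channels, function(ch) {
    if (length(dim(ch)) == 2L) return(ch)
    out <- ch[, , slice_indices[1]]
    for (s in slice_indices[-1]) out <- pmax(out, ch[, , s])
    out
  })
  calibrated_image(channels, img$pixel_size, unit = img$unit)
}

#' Polyline measurement path
#'
#' An ordered open polyline in 0-based pixel coordinates along which intensity
#' profiles are extracted, with an odd pixel `thickness` averaged perpendicular
#' to the path (default 5, the line width used for paranode profiles).
#'
#' @param vertices numeric matrix with columns x, y (>= 2 rows, consecutive
#'   vertices distinct).
#' @param thickness odd integer >= 1.
#' @return An object of class `polyline_path`.
#' @export
polyline_path <- function(vertices, thickness = 5L) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L || anyNA(vertices)) {
    myelin_error("vertices must be a numeric matrix of >= 2 (x, y) rows", "myelin_bad_path")
  }
  seg <- diff(vertices)
  if (any(rowSums(seg^2) == 0)) {
    myelin_error("consecutive vertices must be distinct", "myelin_bad_path")
  }
  if (!is_count(thickness) || thickness < 1 || thickness %% 2 == 0) {
    myelin_error("thickness must be an odd integer >= 1", "myelin_bad_path")
  }
  structure(list(vertices = unname(vertices), thickness = as.integer(thickness)),
            class = "polyline_path")
}

path_length_px <- function(path) {
  sum(sqrt(rowSums(diff(path$vertices)^2)))
}

# Arc-length parameterisation: returns point and unit tangent at arc positions
# s (pixels) along the polyline.
path_point_tangent <- function(path, s) {
  v <- path$vertices
  seg <- diff(v)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  f <- (s - cum[i]) / len[i]
  pt <- v[i, , drop = FALSE] + seg[i, , drop = FALSE] * f
  tg <- seg[i, , drop = FALSE] / len[i]
  list(point = pt, tangent = tg)
}

#' Line intensity profile
#'
#' Arc-length positions (micrometres, starting at 0) and the mean intensity
#' across the perpendicular thickness band at each sample.
#'
#' @param positions strictly increasing numeric vector (um), first element 0.
#' @param intensities non-negative numeric vector, same length.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(positions, intensities) {
  if (length(positions) != length(intensities) || length(positions) < 2L) {
    myelin_error("positions and intensities must have equal length >= 2", "myelin_bad_profile")
  }
  if (any(diff(positions) <= 0)) {
    myelin_error("positions must be strictly increasing", "myelin_bad_profile")
  }
  if (anyNA(intensities) || min(intensities) < 0) {
    myelin_error("intensities must be non-negative", "myelin_bad_profile")
  }
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities)),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples over %.3f um\n",
              length(x$positions), max(x$positions)))
  invisible(x)
}

#' @export
plot.line_profile <- function(x, ...) {
  graphics::plot(x$positions, x$intensities, type = "l",
                 xlab = "arc length (um)", ylab = "mean intensity", ...)
  invisible(x)
}

#' Extract an averaged line intensity profile along a polyline
#'
#' Samples the named channel at ~1 pixel arc-length spacing. Each sample is
#' the mean of `thickness` bilinearly interpolated values taken perpendicular
#' to the local path direction, mirroring a thick measurement line drawn over
#' the paranodes. Positions are converted to micrometres via the calibration.
#'
#' @param img a 2-D [calibrated_image()] (project stacks first).
#' @param role channel role to sample.
#' @param path a [polyline_path()]; the whole thickness band must stay inside
#'   the image.
#' @return A [line_profile()].
#' @export
extract_profile <- function(img, role, path) {
  stopifnot(inherits(path, "polyline_path"))
  ch <- channel(img, role)
  if (length(dim(ch)) == 3L) {
    myelin_error("extract_profile needs a 2-D image; apply max_project() first",
                 "myelin_bad_image")
  }
  L <- path_length_px(path)
  s <- seq(0, L, by = 1)
  if (L - s[length(s)] > 1e-9) s <- c(s, L)
  if (length(s) < 2L) s <- c(0, L)
  pt <- path_point_tangent(path, s)
  normal <- cbind(-pt$tangent[, 2], pt$tangent[, 1])
  h <- (path$thickness - 1L) / 2L
  offsets <- seq(-h, h)
  xs <- outer(pt$point[, 1], rep(1, length(offsets))) + outer(normal[, 1], offsets)
  ys <- outer(pt$point[, 2], rep(1, length(offsets))) + outer(normal[, 2], offsets)
  if (min(xs) < 0 || min(ys) < 0 || max(xs) > ncol(ch) - 1 || max(ys) > nrow(ch) - 1) {
    myelin_error("path (including its thickness band) exits the image", "myelin_path_out_of_bounds")
  }
  vals <- matrix(interp_bilinear(ch, as.vector(xs), as.vector(ys)), nrow = length(s))
  line_profile(s * pixel_size_um(img), rowMeans(vals))
}

#' Otsu threshold by exhaustive search
#'
#' Scans every observed intensity as a candidate threshold (foreground =
#' intensity >= threshold) and returns the candidate maximising the
#' between-class variance. Exact on arbitrary-valued data; no histogram
#' binning.
#'
#' @param values numeric vector of intensities (>= 2 distinct values).
#' @return The optimal threshold, one of the observed values.
#' @export
otsu_threshold <- function(values) {
  u <- sort(unique(as.vector(values)))
  if (length(u) < 2L) {
    myelin_error("Otsu thresholding needs at least two distinct intensities; use a fixed threshold",
                 "myelin_constant_image")
  }
  # Candidate thresholds are the distinct values except the minimum (which
  # would leave the background class empty). With values sorted, background =
  # everything strictly below the candidate, so class means come from
  # cumulative sums in one pass.
  v <- sort(as.vector(values))
  n <- length(v)
  cums <- cumsum(v)
  first_idx <- which(diff(v) > 0) + 1L      # index where each candidate starts
  n0 <- first_idx - 1L
  mu0 <- cums[n0] / n0
  mu1 <- (cums[n] - cums[n0]) / (n - n0)
  w0 <- n0 / n
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  v[first_idx[which.max(bcv)]]
}

#' Binarize one channel of an image
#'
#' @param img a [calibrated_image()].
#' @param role channel role to binarize.
#' @param method `"otsu"` (default) or `"fixed"`; for `"fixed"` supply
#'   `threshold`.
#' @param threshold fixed threshold (intensity units).
#' @return An object of class `binary_mask`: logical `pixels` congruent with
#'   the channel (TRUE where intensity >= threshold) and a `provenance` record
#'   of the rule and the realised threshold.
#' @export
binarize <- function(img, role, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  ch <- channel(img, role)
  if (length(dim(ch)) == 3L) {
    myelin_error("binarize needs a 2-D image; apply max_project() first", "myelin_bad_image")
  }
  t <- switch(method,
    otsu = otsu_threshold(ch),
    fixed = {
      if (!is_scalar_num(threshold)) {
        myelin_error("fixed binarization needs a numeric `threshold`", "myelin_bad_threshold")
      }
      threshold
    })
  structure(list(pixels = ch >= t,
                 provenance = list(role = toupper(role), method = method, threshold = t)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s via %s (threshold %g): %d / %d px TRUE\n",
              x$provenance$role, x$provenance$method, x$provenance$threshold,
              sum(x$pixels), length(x$pixels)))
  invisible(x)
}
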