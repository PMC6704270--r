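#' Detect cells as local intensity maxima with a noise tolerance
#'
#' Finds local maxima whose topographic prominence — height above the highest
#' saddle connecting them to higher terrain — strictly exceeds
#' `noise_tolerance`, the semantics of the classic ImageJ Find Maxima
#' "noise tolerance" used to count marker-positive nuclei (conventional values:
#' 110 for Olig2, 90 for CC1, the midpoints of the ranges used in practice).
#' Summit plateaus yield a single point at the plateau centroid.
#'
#' @param img a 2-D [calibrated_image()].
#' @param role marker channel to detect in.
#' @param noise_tolerance minimum prominence (intensity units, >= 0).
#' @return An object of class `cell_detection`: data.frame `points` with
#'   columns `x`, `y` (0-based pixel coordinates) and `value` (peak height),
#'   plus `marker` and `noise_tolerance`.
#' @export
find_maxima <- function(img, role, noise_tolerance) {
  stopifnot(is_scalar_num(noise_tolerance), noise_tolerance >= 0)
  ch <- channel(img, role)
  if (length(dim(ch)) == 3L) {
    myelin_error("find_maxima needs a 2-D image; apply max_project() first", "myelin_bad_image")
  }
  pts <- .find_maxima_cpp(ch, noise_tolerance)
  pts <- as.data.frame(pts)
  pts <- pts[order(-pts$value, pts$y, pts$x), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, marker = toupper(role),
                 noise_tolerance = noise_tolerance,
                 image_dim = dim(ch), pixel_size_um = pixel_size_um(img)),
            class = "cell_detection")
}

#' @export
print.cell_detection <- function(x, ...) {
  cat(sprintf("<cell_detection> %s: %d maxima (noise tolerance %g)\n",
              x$marker, nrow(x$points), x$noise_tolerance))
  invisible(x)
}

# Maximum bipartite matching (Kuhn's augmenting-path algorithm) over an
# adjacency list from side A to side B. Returns the matching cardinality.
max_bipartite_matching <- function(adj, n_b) {
  match_b <- integer(n_b)                 # 0 = unmatched
  matched <- 0L
  for (i in seq_along(adj)) {
    visited <- logical(n_b)
    augment <- function(u) {
      for (j in adj[[u]]) {
        if (!visited[j]) {
          visited[j] <<- TRUE
          if (match_b[j] == 0L || augment(match_b[j])) {
            match_b[j] <<- u
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (augment(i)) matched <- matched + 1L
  }
  matched
}

#' Count double-positive cells by object-based matching
#'
#' Pairs detections from two markers one-to-one when their centres lie within
#' `radius_um` of each other and returns the size of the maximum such
#' matching — the object-based colocalization count used for double-positive
#' (e.g. Olig2+/CC1+) cells.
#'
#' @param a,b [find_maxima()] detections from congruent images.
#' @param radius_um maximum centre-to-centre pairing distance in micrometres
#'   (default 5, about half a nuclear diameter).
#' @param pixel_size_um pixel size; defaults to the calibration recorded in
#'   the detections.
#' @return Integer: the number of matched (double-positive) cells.
#' @export
count_double_positive <- function(a, b, radius_um = 5, pixel_size_um = NULL) {
  stopifnot(inherits(a, "cell_detection"), inherits(b, "cell_detection"),
            is_scalar_num(radius_um), radius_um > 0)
  if (!identical(a$image_dim, b$image_dim)) {
    myelin_error("detections come from images of different geometry", "myelin_bad_image")
  }
  pixel_size_um <- pixel_size_um %||% a$pixel_size_um
  na <- nrow(a$points); nb <- nrow(b$points)
  if (na == 0L || nb == 0L) return(0L)
  dx <- outer(a$points$x, b$points$x, "-")
  dy <- outer(a$points$y, b$points$y, "-")
  d_um <- sqrt(dx^2 + dy^2) * pixel_size_um
  adj <- lapply(seq_len(na), function(i) which(d_um[i, ] <= radius_um))
  max_bipartite_matching(adj, nb)
}

#' Cell densities per square millimetre
#'
#' Converts marker counts and a double-positive count into densities over the
#' calibrated image area.
#'
#' @param a,b [find_maxima()] detections for the two markers.
#' @param n_double double-positive count, e.g. from [count_double_positive()].
#' @param img the [calibrated_image()] the detections came from (provides the
#'   area).
#' @return An object of class `density_result`: counts, `area_mm2` and
#'   `density_a`, `density_b`, `density_double` in cells per mm^2.
#' @export
marker_density <- function(a, b, n_double, img) {
  stopifnot(inherits(a, "cell_detection"), inherits(b, "cell_detection"),
            is_count(n_double))
  n_a <- nrow(a$points); n_b <- nrow(b$points)
  if (n_double > min(n_a, n_b)) {
    myelin_error("double-positive count exceeds a marker count", "myelin_bad_counts")
  }
  d <- dim(channel(img, names(img$channels)[1]))
  area_mm2 <- d[1] * d[2] * (pixel_size_um(img) / 1000)^2
  if (area_mm2 == 0) myelin_error("image has zero area", "myelin_bad_calibration")
  structure(list(n_marker_a = n_a, n_marker_b = n_b, n_double = n_double,
                 marker_a = a$marker, marker_b = b$marker,
                 area_mm2 = area_mm2,
                 density_a = n_a / area_mm2,
                 density_b = n_b / area_mm2,
                 density_double = n_double / area_mm2),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("<density_result> %.4f mm^2\n", x$area_mm2))
  cat(sprintf("  %s: %d (%.1f /mm^2)  %s: %d (%.1f /mm^2)  double: %d (%.1f /mm^2)\n",
              x$marker_a, x$n_marker_a, x$density_a,
              x$marker_b, x$n_marker_b, x$density_b,
              x$n_double, x$density_double))
  invisible(x)
}
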