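#' Node of Ranvier length from a paranodal line profile
#'
#' Implements the half-maximum rule on a Caspr line intensity profile spanning
#' a paranode pair:
#' \enumerate{
#'   \item the two paranode peaks are the highest samples strictly left and
#'     right of the global interior minimum (ties broken toward the profile
#'     ends, the conservative, wider-node choice);
#'   \item the valley is the minimum intensity between the two peaks;
#'   \item each paranode gets its own half-maximum level,
#'     `valley + (peak - valley) / 2` (the valley is subtracted from the peak
#'     before halving, so a constant offset on the whole profile cancels);
#'   \item the half-maximum crossing is located on the node-facing flank of
#'     each peak, walking from the peak toward the valley and linearly
#'     interpolating the first bracketing sample pair (the crossing nearest
#'     the peak, robust to noise on the valley floor);
#'   \item the node length is the distance between the two crossings.
#' }
#'
#' @param profile a [line_profile()] with >= 5 samples containing two peaks
#'   separated by a valley.
#' @param smooth optional odd moving-average window applied before analysis
#'   (recorded in the result); default none.
#' @return An object of class `node_measurement` with peak positions/heights,
#'   the valley minimum, per-paranode half levels, half-maximum crossing
#'   positions and `node_length` (um).
#'
#' @section Failure modes: distinct condition classes let batch runs report
#'   why a profile was not quantifiable: `myelin_node_no_peaks` (no sample on
#'   one side of the interior minimum), `myelin_node_flat` (peak does not
#'   exceed the valley), `myelin_node_no_crossing` (no bracketing pair on a
#'   flank) and `myelin_node_degenerate` (crossings out of order, e.g.
#'   abutting paranodes).
#' @export
node_length_from_profile <- function(profile, smooth = NULL) {
  stopifnot(inherits(profile, "line_profile"))
  pos <- profile$positions
  int <- profile$intensities
  if (!is.null(smooth)) {
    stopifnot(is_count(smooth), smooth %% 2 == 1, smooth >= 3)
    k <- rep(1 / smooth, smooth)
    h <- (smooth - 1) / 2
    padded <- c(rep(int[1], h), int, rep(int[length(int)], h))
    int <- as.numeric(stats::filter(padded, k, sides = 2))[(h + 1):(h + length(int))]
  }
  n <- length(int)
  if (n < 5L) {
    myelin_error("profile too short: need >= 5 samples", "myelin_node_no_peaks")
  }
  interior <- 2:(n - 1)
  v0 <- interior[which.min(int[interior])]

  left_idx <- 1:(v0 - 1)
  right_idx <- (v0 + 1):n
  # ties toward the profile ends: first max on the left, last max on the right
  pl <- left_idx[which.max(int[left_idx])]
  pr <- right_idx[max(which(int[right_idx] == max(int[right_idx])))]
  if (pl >= v0 || pr <= v0) {
    myelin_error("could not find two peaks flanking the interior minimum",
                 "myelin_node_no_peaks")
  }

  between <- pl:pr
  vi <- between[which.min(int[between])]
  valley <- int[vi]
  if (int[pl] <= valley || int[pr] <= valley) {
    myelin_error("flat profile: paranode peak does not exceed the valley",
                 "myelin_node_flat")
  }

  half_l <- valley + (int[pl] - valley) / 2
  half_r <- valley + (int[pr] - valley) / 2

  cross_toward_valley <- function(peak, valley_i, half) {
    step <- if (valley_i > peak) 1L else -1L
    i <- peak
    while (i != valley_i) {
      j <- i + step
      if (int[i] > half && int[j] <= half) {
        f <- (int[i] - half) / (int[i] - int[j])
        return(pos[i] + f * (pos[j] - pos[i]))
      }
      i <- j
    }
    myelin_error("half-maximum crossing not bracketed on the node-facing flank",
                 "myelin_node_no_crossing")
  }
  xl <- cross_toward_valley(pl, vi, half_l)
  xr <- cross_toward_valley(pr, vi, half_r)
  if (xr < xl) {
    myelin_error("half-maximum crossings out of order (abutting paranodes?)",
                 "myelin_node_degenerate")
  }

  structure(list(
    peak_left_pos = pos[pl], peak_right_pos = pos[pr],
    peak_left_int = int[pl], peak_right_int = int[pr],
    valley_min_int = valley,
    half_level_left = half_l, half_level_right = half_r,
    halfmax_left_pos = xl, halfmax_right_pos = xr,
    node_length = xr - xl,
    smooth = smooth, profile = profile),
    class = "node_measurement")
}

#' @export
print.node_measurement <- function(x, ...) {
  cat(sprintf("<node_measurement> length %.3f um (half-maxima at %.3f / %.3f um)\n",
              x$node_length, x$halfmax_left_pos, x$halfmax_right_pos))
  cat(sprintf("  peaks %.1f @ %.3f um and %.1f @ %.3f um, valley %.1f\n",
              x$peak_left_int, x$peak_left_pos, x$peak_right_int, x$peak_right_pos,
              x$valley_min_int))
  invisible(x)
}

#' @export
plot.node_measurement <- function(x, ...) {
  plot(x$profile, ...)
  graphics::abline(v = c(x$halfmax_left_pos, x$halfmax_right_pos), lty = 2)
  graphics::abline(h = x$valley_min_int, lty = 3)
  invisible(x)
}

#' Validate a node candidate against the selection criteria
#'
#' A node is measurable only when an axon projection runs under the line, a
#' Caspr paranode sits under each outer third of the line, and myelin flanks
#' both ends. The three checks are evaluated from thresholded intensity along
#' (and beyond) the measurement path.
#'
#' @param img a 2-D [calibrated_image()] with TDTOMATO, CASPR and MBP roles.
#' @param path a [polyline_path()] over the paranode pair.
#' @param rules optional named numeric thresholds per role; any missing role's
#'   threshold defaults to the Otsu threshold of its channel.
#' @param flank_um how far beyond each path end to look for myelin (default
#'   2 um).
#' @return An object of class `node_candidate` with logical `checks`
#'   (`axon_present`, `paranodes_present`, `myelin_flanking`) and `accepted`
#'   (all three true).
#' @export
validate_candidate <- function(img, path, rules = NULL, flank_um = 2) {
  for (role in c("TDTOMATO", "CASPR", "MBP")) channel(img, role)  # role checks
  thr <- function(role) {
    rules[[role]] %||% otsu_threshold(channel(img, role))
  }
  third <- function(prof, which) {
    p <- prof$positions; L <- max(p)
    keep <- switch(which,
                   first  = p <= L / 3,
                   middle = p > L / 3 & p < 2 * L / 3,
                   last   = p >= 2 * L / 3)
    prof$intensities[keep]
  }
  td <- extract_profile(img, "TDTOMATO", path)
  cp <- extract_profile(img, "CASPR", path)
  axon_present <- any(third(td, "middle") > thr("TDTOMATO"))
  paranodes_present <- any(third(cp, "first") > thr("CASPR")) &&
    any(third(cp, "last") > thr("CASPR"))

  # myelin beyond both path ends: sample MBP along the collinear extension
  ch <- channel(img, "MBP")
  flank_px <- flank_um / pixel_size_um(img)
  v <- path$vertices
  flank_ok <- function(end_pt, direction) {
    diru <- direction / sqrt(sum(direction^2))
    s <- seq(1, flank_px, by = 1)
    pts <- cbind(end_pt[1] + s * diru[1], end_pt[2] + s * diru[2])
    inb <- pts[, 1] >= 0 & pts[, 1] <= ncol(ch) - 1 &
      pts[, 2] >= 0 & pts[, 2] <= nrow(ch) - 1
    if (!any(inb)) return(FALSE)
    any(interp_bilinear(ch, pts[inb, 1], pts[inb, 2]) > thr("MBP"))
  }
  myelin_flanking <-
    flank_ok(v[1, ], v[1, ] - v[2, ]) &&
    flank_ok(v[nrow(v), ], v[nrow(v), ] - v[nrow(v) - 1, ])

  checks <- c(axon_present = axon_present,
              paranodes_present = paranodes_present,
              myelin_flanking = myelin_flanking)
  structure(list(path = path, checks = checks, accepted = all(checks)),
            class = "node_candidate")
}

#' @export
print.node_candidate <- function(x, ...) {
  cat("<node_candidate>", if (x$accepted) "accepted" else "rejected", "\n")
  for (nm in names(x$checks)) cat(sprintf("  %s: %s\n", nm, x$checks[nm]))
  invisible(x)
}

#' Measure a node from an image: project, profile, half-maxima
#'
#' Composes the full per-node pipeline: maximum-intensity projection of at
#' most five slices (for stacks), extraction of the Caspr line profile along
#' the measurement path, and [node_length_from_profile()]. The realised
#' profile is kept on the result for audit.
#'
#' @param img a [calibrated_image()] (2-D or z-stack).
#' @param path a [polyline_path()] (thickness 5 is the conventional width).
#' @param slices slice selection for [max_project()] (<= 5; default all).
#' @param smooth optional smoothing window, see [node_length_from_profile()].
#' @return A `node_measurement`.
#' @export
measure_node <- function(img, path, slices = NULL, smooth = NULL) {
  if (n_slices(img) > 1L) img <- max_project(img, slices)
  node_length_from_profile(extract_profile(img, "CASPR", path), smooth = smooth)
}

#' Measure a batch of node paths, recording failures
#'
#' @param img a [calibrated_image()].
#' @param paths named list of [polyline_path()]s.
#' @param slices,smooth passed to [measure_node()].
#' @return A data.frame with one row per path: node id, all
#'   `node_measurement` scalars (NA on failure) and `failure` (condition
#'   class, `""` on success) — the per-node CSV layout.
#' @export
measure_nodes <- function(img, paths, slices = NULL, smooth = NULL) {
  ids <- names(paths) %||% as.character(seq_along(paths))
  rows <- lapply(seq_along(paths), function(i) {
    res <- tryCatch(measure_node(img, paths[[i]], slices = slices, smooth = smooth),
                    myelin_error = function(e) e)
    if (inherits(res, "node_measurement")) {
      data.frame(node_id = ids[i],
                 peak_left_pos = res$peak_left_pos, peak_right_pos = res$peak_right_pos,
                 peak_left_int = res$peak_left_int, peak_right_int = res$peak_right_int,
                 valley_min_int = res$valley_min_int,
                 halfmax_left_pos = res$halfmax_left_pos,
                 halfmax_right_pos = res$halfmax_right_pos,
                 node_length = res$node_length, failure = "")
    } else {
      data.frame(node_id = ids[i],
                 peak_left_pos = NA_real_, peak_right_pos = NA_real_,
                 peak_left_int = NA_real_, peak_right_int = NA_real_,
                 valley_min_int = NA_real_,
                 halfmax_left_pos = NA_real_, halfmax_right_pos = NA_real_,
                 node_length = NA_real_, failure = class(res)[1])
    }
  })
  do.call(rbind, rows)
}
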