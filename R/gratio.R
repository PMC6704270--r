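#' Annotation of one myelinated axon cross-section
#'
#' The measurement substrate for g-ratio morphometry: the axoplasm
#' (`inner`) and the whole fibre, axon plus myelin (`outer`), given either as
#' pixel sets (`type = "mask"`: n x 2 matrices of 0-based x, y integer pixel
#' coordinates, inner a subset of outer) or as closed polygon contours
#' (`type = "contour"`: vertices in 0-based pixel coordinates).
#'
#' @param axon_id identifier.
#' @param inner,outer n x 2 matrices (columns x, y).
#' @param type `"mask"` or `"contour"`.
#' @return An object of class `axon_annotation`.
#' @export
axon_annotation <- function(axon_id, inner, outer, type = c("mask", "contour")) {
  type <- match.arg(type)
  inner <- as.matrix(inner); outer <- as.matrix(outer)
  if (ncol(inner) != 2L || ncol(outer) != 2L || nrow(inner) < 1L || nrow(outer) < 1L) {
    myelin_error("inner and outer must be n x 2 coordinate matrices", "myelin_bad_annotation")
  }
  if (type == "contour" && (nrow(inner) < 3L || nrow(outer) < 3L)) {
    myelin_error("contours need at least 3 vertices", "myelin_bad_annotation")
  }
  structure(list(axon_id = axon_id, inner = unname(inner), outer = unname(outer),
                 type = type),
            class = "axon_annotation")
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:nrow(v), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

region_area_px <- function(coords, type) {
  if (type == "mask") nrow(unique(coords)) else polygon_area(coords)
}

region_centroid <- function(coords, type) {
  if (type == "mask") return(colMeans(coords))
  # polygon centroid (uniform lamina)
  x <- coords[, 1]; y <- coords[, 2]
  j <- c(2:nrow(coords), 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

#' Measure one annotated axon: diameters and g-ratio
#'
#' Diameters are area-equivalent circle diameters, `d = 2 * sqrt(area / pi)`,
#' robust to non-circular cross-sections; the g-ratio is the inner (axon)
#' diameter divided by the outer (fibre) diameter.
#'
#' @param ann an [axon_annotation()].
#' @param pixel_size_nm pixel side length in nanometres (8 nm is the
#'   conventional SEM setting).
#' @return An object of class `axon_measurement` with `inner_diameter_nm`,
#'   `outer_diameter_nm` and `g_ratio` (in (0, 1)).
#' @export
measure_axon <- function(ann, pixel_size_nm = 8) {
  stopifnot(inherits(ann, "axon_annotation"), is_scalar_num(pixel_size_nm),
            pixel_size_nm > 0)
  a_in <- region_area_px(ann$inner, ann$type)
  a_out <- region_area_px(ann$outer, ann$type)
  if (a_in <= 0 || a_out <= 0) {
    myelin_error("zero-area region in annotation", "myelin_bad_annotation")
  }
  if (ann$type == "mask") {
    key <- function(m) paste(m[, 1], m[, 2])
    if (!all(key(ann$inner) %in% key(ann$outer))) {
      myelin_error("inner region is not contained in the outer region", "myelin_bad_annotation")
    }
  }
  if (a_in >= a_out) {
    myelin_error("inner area must be smaller than outer area (no myelin annulus?)",
                 "myelin_bad_annotation")
  }
  d_in <- 2 * sqrt(a_in / pi) * pixel_size_nm
  d_out <- 2 * sqrt(a_out / pi) * pixel_size_nm
  structure(list(axon_id = ann$axon_id,
                 inner_diameter_nm = d_in, outer_diameter_nm = d_out,
                 g_ratio = d_in / d_out),
            class = "axon_measurement")
}

#' @export
print.axon_measurement <- function(x, ...) {
  cat(sprintf("<axon_measurement> %s: d_in %.0f nm, d_out %.0f nm, g = %.3f\n",
              as.character(x$axon_id), x$inner_diameter_nm, x$outer_diameter_nm,
              x$g_ratio))
  invisible(x)
}

#' Build axon annotations from a labelled-mask image
#'
#' Label convention: for axon `k` (k = 1, 2, ...), the axoplasm pixels carry
#' label `2k` and the myelin ring pixels label `2k + 1`; the outer (fibre)
#' region is their union. Label 0/1 is background.
#'
#' @param labels integer matrix of labels.
#' @return A list of [axon_annotation()]s (mask type), ordered by `k`.
#' @export
annotations_from_labels <- function(labels) {
  labels <- as.matrix(labels)
  nr <- nrow(labels)
  idx <- which(labels >= 2)
  lab <- labels[idx]
  xy <- cbind(x = (idx - 1L) %/% nr, y = (idx - 1L) %% nr)   # 0-based
  by_label <- split(seq_along(idx), lab)
  ks <- sort(unique(lab %/% 2))
  lapply(ks, function(k) {
    inner <- xy[by_label[[as.character(2 * k)]], , drop = FALSE]
    ring <- xy[by_label[[as.character(2 * k + 1)]] %||% integer(), , drop = FALSE]
    if (nrow(inner) == 0L) {
      myelin_error(sprintf("axon %d has no inner pixels", k), "myelin_bad_annotation")
    }
    axon_annotation(k, inner, rbind(inner, ring), type = "mask")
  })
}

#' Read axon contour annotations from JSON
#'
#' Expects an array of objects `{axon_id, inner: [[x, y], ...],
#' outer: [[x, y], ...]}` in 0-based pixel coordinates.
#'
#' @param path JSON file.
#' @return A list of [axon_annotation()]s (contour type).
#' @export
read_axon_contours <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    to_mat <- function(v) do.call(rbind, lapply(v, function(p) c(p[[1]], p[[2]])))
    axon_annotation(r$axon_id, to_mat(r$inner), to_mat(r$outer), type = "contour")
  })
}

#' Measure all annotated axons whose fibre centroid lies in a rectangular ROI
#'
#' Applies [measure_axon()] to every annotation whose outer-region centroid
#' falls inside the ROI (centroid inclusion avoids double counting fibres cut
#' by the ROI edge when tiling). The default ROI is the 32.5 um x 42.5 um box
#' used for dorsal-column quantification.
#'
#' @param annotations list of [axon_annotation()]s (may be empty).
#' @param pixel_size_nm nanometres per pixel (default 8).
#' @param roi_um ROI extent `c(width, height)` in micrometres; `NULL` measures
#'   everything.
#' @param roi_origin_um ROI top-left corner in micrometres (default `c(0, 0)`).
#' @return A data.frame with one row per measured axon (`axon_id`,
#'   `inner_diameter_nm`, `outer_diameter_nm`, `g_ratio`) and a `summary`
#'   attribute: `n`, `mean_g`, `sem_g`, `mean_inner_diameter_nm`,
#'   `sem_inner_diameter_nm`.
#' @export
measure_roi <- function(annotations, pixel_size_nm = 8,
                        roi_um = c(32.5, 42.5), roi_origin_um = c(0, 0)) {
  keep <- vapply(annotations, function(ann) {
    if (is.null(roi_um)) return(TRUE)
    cen_um <- region_centroid(ann$outer, ann$type) * pixel_size_nm / 1000
    cen_um[1] >= roi_origin_um[1] && cen_um[1] <= roi_origin_um[1] + roi_um[1] &&
      cen_um[2] >= roi_origin_um[2] && cen_um[2] <= roi_origin_um[2] + roi_um[2]
  }, logical(1))
  rows <- lapply(annotations[keep], function(ann) {
    m <- measure_axon(ann, pixel_size_nm)
    data.frame(axon_id = m$axon_id, inner_diameter_nm = m$inner_diameter_nm,
               outer_diameter_nm = m$outer_diameter_nm, g_ratio = m$g_ratio)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(axon_id = integer(), inner_diameter_nm = numeric(),
               outer_diameter_nm = numeric(), g_ratio = numeric())
  n <- nrow(out)
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  attr(out, "summary") <- list(
    n = n,
    mean_g = if (n) mean(out$g_ratio) else NA_real_,
    sem_g = sem(out$g_ratio),
    mean_inner_diameter_nm = if (n) mean(out$inner_diameter_nm) else NA_real_,
    sem_inner_diameter_nm = sem(out$inner_diameter_nm))
  class(out) <- c("gratio_measurements", "data.frame")
  out
}

#' @export
print.gratio_measurements <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<gratio_measurements> n = %d axons", s$n))
  if (s$n > 0) {
    cat(sprintf(": mean g = %.3f (SEM %.4f), mean axon diameter = %.0f nm (SEM %.1f)",
                s$mean_g, s$sem_g, s$mean_inner_diameter_nm, s$sem_inner_diameter_nm))
  }
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}
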