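#' Pooled background statistics from signal-free ROIs
#'
#' Computes the mean and population standard deviation of intensity over the
#' pooled pixels of rectangles devoid of labelled fibres, across any number of
#' images. Pooling across images (and ages) is the convention for the
#' onset-of-myelination analysis; per-image statistics can be had by calling
#' the function once per image.
#'
#' @param images a [calibrated_image()] or list of them.
#' @param rois a list parallel to `images`, each element a list of
#'   [pixel_rect()]s (or a single list of rects when one image is supplied).
#' @param role channel whose background is characterised (default `"MBP"`).
#' @return An object of class `background_stats` with fields `mean`, `sd`
#'   (population, divide-by-n), `n_pixels` and `source`.
#' @export
estimate_background <- function(images, rois, role = "MBP") {
  if (inherits(images, "calibrated_image")) {
    images <- list(images)
    looks_like_rect <- length(rois) &&
      (inherits(rois[[1]], "pixel_rect") || "x" %in% names(rois[[1]]))
    if (looks_like_rect) rois <- list(rois)
  }
  stopifnot(length(images) == length(rois))
  px <- numeric(0)
  src <- list()
  for (i in seq_along(images)) {
    ch <- channel(images[[i]], role)
    for (r in rois[[i]]) {
      r <- as_pixel_rect(r)
      px <- c(px, rect_pixels(ch, r))
      src <- c(src, list(c(image = i, x = r$x, y = r$y, width = r$width, height = r$height)))
    }
  }
  if (length(px) < 2L) {
    myelin_error("background estimation needs at least one ROI with >= 2 pixels",
                 "myelin_empty_background")
  }
  structure(list(mean = mean(px), sd = pop_sd(px), n_pixels = length(px),
                 sd_type = "population", role = toupper(role), source = src),
            class = "background_stats")
}

#' @export
print.background_stats <- function(x, ...) {
  cat(sprintf("<background_stats> %s: mean %.3f, %s sd %.3f (n = %d px, %d ROIs)\n",
              x$role, x$mean, x$sd_type, x$sd, x$n_pixels, length(x$source)))
  invisible(x)
}

#' Percentage of an image covered by suprathreshold pixels
#'
#' The onset-of-myelination statistic: a pixel counts as marker-positive when
#' its intensity strictly exceeds `background mean + k_sd * background sd`
#' (k_sd = 2 by default), and the result is the percentage of all pixels of
#' the channel that are suprathreshold.
#'
#' @param img a 2-D [calibrated_image()].
#' @param role channel to threshold (default `"MBP"`).
#' @param bg a [estimate_background()] result.
#' @param k_sd number of background standard deviations above the mean
#'   (>= 0; default 2).
#' @return An object of class `coverage_result` with `percent_area`,
#'   `threshold_used`, `n_supra`, `n_total`.
#' @export
coverage <- function(img, role = "MBP", bg, k_sd = 2) {
  stopifnot(inherits(bg, "background_stats"), is_scalar_num(k_sd), k_sd >= 0)
  ch <- channel(img, role)
  thr <- bg$mean + k_sd * bg$sd
  n_supra <- sum(ch > thr)          # strictly above: ties are background
  n_total <- length(ch)
  structure(list(percent_area = 100 * n_supra / n_total,
                 threshold_used = thr, n_supra = n_supra, n_total = n_total,
                 role = toupper(role), k_sd = k_sd),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %s: %.3f%% suprathreshold (%d / %d px > %.3f)\n",
              x$role, x$percent_area, x$n_supra, x$n_total, x$threshold_used))
  invisible(x)
}
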