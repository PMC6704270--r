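#' Mean intensity of one channel inside a mask defined by another
#'
#' Binarizes the `mask_role` channel and reports the mean of the
#' `measured_role` channel over the mask together with the mask area. With
#' `mask_role = "TDTOMATO", measured_role = "MBP"` this is the callosal
#' reporter-defined MBP intensity; with `mask_role = measured_role = "MBP"` it
#' is the striatal variant where the MBP signal itself defines the ROIs in
#' which the un-thresholded MBP intensity is quantified.
#'
#' @param img a 2-D [calibrated_image()].
#' @param mask_role channel that is binarized to define the ROI.
#' @param measured_role channel whose mean intensity is reported.
#' @param method,threshold binarization rule, see [binarize()].
#' @return An object of class `roi_intensity_result`: `mean_intensity`,
#'   `mask_area_px`, `mask_area_um2`, the two roles and the realised threshold.
#' @export
roi_intensity <- function(img, mask_role = "TDTOMATO", measured_role = "MBP",
                          method = c("otsu", "fixed"), threshold = NULL) {
  mask <- binarize(img, mask_role, method = method, threshold = threshold)
  area <- sum(mask$pixels)
  if (area == 0L) {
    myelin_error(paste0("binarized ", toupper(mask_role),
                        " mask is empty: no labelled fibres to measure in"),
                 "myelin_empty_mask")
  }
  ch <- channel(img, measured_role)
  structure(list(mean_intensity = mean(ch[mask$pixels]),
                 mask_area_px = area,
                 mask_area_um2 = area * pixel_size_um(img)^2,
                 mask_role = toupper(mask_role), measured_role = toupper(measured_role),
                 threshold = mask$provenance$threshold,
                 method = mask$provenance$method),
            class = "roi_intensity_result")
}

#' @export
print.roi_intensity_result <- function(x, ...) {
  cat(sprintf("<roi_intensity_result> mean %s = %.3f over %d px of %s mask (%.2f um^2)\n",
              x$measured_role, x$mean_intensity, x$mask_area_px, x$mask_role,
              x$mask_area_um2))
  invisible(x)
}

#' Outlier decisions for a cohort of box means
#'
#' The per-image rejection rule applied to mean intensities measured in a
#' fixed-size box: an image is discarded when its box mean deviates from the
#' cohort mean of all box means by strictly more than one population standard
#' deviation.
#'
#' @param box_means numeric vector of per-image box means (length >= 2).
#' @param image_id optional identifiers (default `seq_along(box_means)`).
#' @return A data.frame with one row per image: `image_id`, `box_mean`,
#'   `cohort_mean`, `cohort_sd`, `discarded`.
#' @export
outlier_decisions <- function(box_means, image_id = seq_along(box_means)) {
  stopifnot(is.numeric(box_means), length(box_means) >= 2,
            length(image_id) == length(box_means))
  m <- mean(box_means)
  s <- pop_sd(box_means)
  data.frame(image_id = image_id, box_mean = box_means,
             cohort_mean = m, cohort_sd = s,
             discarded = abs(box_means - m) > s)
}

#' Box-based outlier filter over a cohort of images
#'
#' Measures the mean intensity of the `measured_role` channel in a 200 x 125
#' pixel box placed in a region without reporter signal on each image, then
#' flags images whose box mean lies strictly more than one population SD from
#' the cohort mean of all boxes (see [outlier_decisions()]). If a box contains
#' suprathreshold reporter signal the image is still scored but a warning is
#' raised, since the rule assumes reporter-free boxes.
#'
#' @param images list of 2-D [calibrated_image()]s (>= 2).
#' @param boxes list of [pixel_rect()]s, one per image; each must have exactly
#'   `box_size` dimensions and lie within its image.
#' @param box_size required box dimensions `c(width, height)` in pixels.
#' @param measured_role channel measured in the box (default `"MBP"`).
#' @param reporter_role channel that must be absent from the box (default
#'   `"TDTOMATO"`; checked with an Otsu threshold over the whole channel,
#'   skipped when that channel is constant).
#' @return The [outlier_decisions()] data.frame.
#' @export
box_outlier_filter <- function(images, boxes, box_size = c(200L, 125L),
                               measured_role = "MBP", reporter_role = "TDTOMATO") {
  stopifnot(is.list(images), length(images) >= 2, length(boxes) == length(images))
  box_means <- numeric(length(images))
  for (i in seq_along(images)) {
    b <- as_pixel_rect(boxes[[i]])
    if (b$width != box_size[1] || b$height != box_size[2]) {
      myelin_error(sprintf("box %d is %d x %d px; the filter requires %d x %d",
                           i, b$width, b$height, box_size[1], box_size[2]),
                   "myelin_bad_box")
    }
    box_means[i] <- mean(rect_pixels(channel(images[[i]], measured_role), b))
    if (toupper(reporter_role) %in% names(images[[i]]$channels)) {
      rep_ch <- channel(images[[i]], reporter_role)
      if (length(unique(as.vector(rep_ch))) > 1L) {
        thr <- otsu_threshold(rep_ch)
        if (any(rect_pixels(rep_ch, b) >= thr)) {
          warning(sprintf("box %d contains suprathreshold %s signal; mean computed anyway",
                          i, toupper(reporter_role)))
        }
      }
    }
  }
  outlier_decisions(box_means)
}

#' Propose a reporter-free box placement
#'
#' Convenience helper (placement was manual in the original workflow): returns
#' the in-bounds box of the required size whose summed reporter intensity is
#' minimal, found with an integral image.
#'
#' @param img a 2-D [calibrated_image()].
#' @param box_size `c(width, height)` in pixels.
#' @param role channel to avoid (default `"TDTOMATO"`).
#' @return A [pixel_rect()].
#' @export
propose_box <- function(img, box_size = c(200L, 125L), role = "TDTOMATO") {
  ch <- channel(img, role)
  w <- box_size[1]; h <- box_size[2]
  if (w > ncol(ch) || h > nrow(ch)) {
    myelin_error("image is smaller than the requested box", "myelin_bad_box")
  }
  # Summed-area table with a zero border so window sums are a 4-term lookup.
  sat <- matrix(0, nrow(ch) + 1, ncol(ch) + 1)
  sat[-1, -1] <- apply(apply(ch, 2, cumsum), 1, cumsum) |> t()
  r1 <- 1:(nrow(ch) - h + 1); c1 <- 1:(ncol(ch) - w + 1)
  sums <- sat[r1 + h, c1 + w, drop = FALSE] - sat[r1, c1 + w, drop = FALSE] -
    sat[r1 + h, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
  best <- arrayInd(which.min(sums), dim(sums))
  pixel_rect(x = best[2] - 1L, y = best[1] - 1L, width = w, height = h)
}
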