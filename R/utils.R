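#' @useDynLib myelinmetrics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm pt rnorm runif sd oneway.test setNames
#' @importFrom utils combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Condition constructor shared by all modules: every domain failure carries a
# machine-readable class so batch runs can tabulate failure reasons.
myelin_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "myelin_error"), call = call))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Population (divide-by-n) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Rectangle in pixel coordinates
#'
#' Rectangles use the package-wide pixel convention: 0-based coordinates,
#' `x` = column of the left edge, `y` = row of the top edge, pixel centres at
#' integer positions. A rectangle covers `width * height` whole pixels.
#'
#' @param x,y 0-based column/row of the top-left pixel.
#' @param width,height extent in pixels (>= 1).
#' @return A named list of class `pixel_rect`.
#' @export
pixel_rect <- function(x, y, width, height) {
  stopifnot(is_count(x), is_count(y), is_count(width), is_count(height),
            width >= 1, height >= 1)
  structure(list(x = x, y = y, width = width, height = height), class = "pixel_rect")
}

as_pixel_rect <- function(r) {
  if (inherits(r, "pixel_rect")) return(r)
  r <- as.list(r)
  pixel_rect(r$x, r$y, r$width, r$height)
}

# Extract the pixels of a rectangle from an intensity matrix; errors when the
# rectangle leaves the image.
rect_pixels <- function(mat, rect) {
  rect <- as_pixel_rect(rect)
  rows <- (rect$y + 1):(rect$y + rect$height)
  cols <- (rect$x + 1):(rect$x + rect$width)
  if (rect$x < 0 || rect$y < 0 ||
      max(rows) > nrow(mat) || max(cols) > ncol(mat)) {
    myelin_error("rectangle lies outside the image bounds", "myelin_roi_out_of_bounds")
  }
  as.vector(mat[rows, cols])
}

# Vectorised bilinear interpolation on a matrix. x = 0-based column, y =
# 0-based row, pixel centres at integers. Callers guarantee in-bounds input.
interp_bilinear <- function(mat, x, y) {
  nr <- nrow(mat); nc <- ncol(mat)
  x0 <- pmin(floor(x), nc - 2L); x0 <- pmax(x0, 0L)
  y0 <- pmin(floor(y), nr - 2L); y0 <- pmax(y0, 0L)
  fx <- x - x0; fy <- y - y0
  i00 <- mat[cbind(y0 + 1, x0 + 1)]
  i01 <- mat[cbind(y0 + 1, x0 + 2)]
  i10 <- mat[cbind(y0 + 2, x0 + 1)]
  i11 <- mat[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Seeded integer noise used by all generators: Gaussian, rounded to integer
# intensities, clamped to the 16-bit range so images survive TIFF round-trips.
quantize_intensity <- function(x) {
  pmin(pmax(round(x), 0), 65535)
}
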