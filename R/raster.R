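#' RGB raster images
#'
#' A `raster_image` is a numeric `height x width x 3` array with channel values
#' in \[0, 255\] plus bookkeeping attributes (`image_id`, `chamber`,
#' `timepoint`). Pixel coordinates are 1-based, `x` indexing columns
#' (rightwards) and `y` indexing rows (downwards).
#'
#' @param x Numeric array of dimension `c(height, width, 3)`, values in
#'   \[0, 255\].
#' @param image_id Character identifier of the image.
#' @param chamber Integer chamber id (1--21 in the study design), or `NA`.
#' @param timepoint Integer time-point index, or `NA`.
#' @return A `raster_image` object.
#' @export
raster_image <- function(x, image_id = "img", chamber = NA_integer_,
                         timepoint = NA_integer_) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("`x` must be a height x width x 3 array")
  storage.mode(x) <- "double"
  structure(x,
            image_id = as.character(image_id),
            chamber = as.integer(chamber),
            timepoint = as.integer(timepoint),
            class = c("raster_image", "array"))
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image %s: %d x %d px, chamber %s, timepoint %s>\n",
              attr(x, "image_id"), d[2], d[1],
              attr(x, "chamber"), attr(x, "timepoint")))
  invisible(x)
}

image_id <- function(img) attr(img, "image_id") %||% "img"

`%||%` <- function(a, b) if (is.null(a)) b else a

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Read and write raster images as PNG
#'
#' @param img A [raster_image()].
#' @param path File path.
#' @param ... Passed to [raster_image()] when reading (image metadata).
#' @return `write_image()` returns `path` invisibly; `read_image()` returns a
#'   [raster_image()].
#' @export
write_image <- function(img, path) {
  arr <- unclass(img) / 255
  attributes(arr) <- list(dim = dim(img))
  png::writePNG(pmin(pmax(arr, 0), 1), target = path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, ...) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  raster_image(arr * 255, ...)
}

#' Circular mean of angles in degrees
#'
#' Mean direction of a set of angles, computed on the unit circle
#' (`atan2` of the mean sine and cosine). Used for hue averaging, where
#' 350 and 10 degrees must average to 0, not 180.
#'
#' @param deg Numeric vector of angles in degrees.
#' @param na.rm Drop missing values first.
#' @return Mean angle in degrees, in \[0, 360). `NA` if no data.
#' @export
circular_mean <- function(deg, na.rm = TRUE) {
  if (na.rm) deg <- deg[!is.na(deg)]
  if (length(deg) == 0L) return(NA_real_)
  rad <- deg * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  (m + 360) %% 360
}

# RGB (0..255, n x 3 matrix) -> HSV with hue in degrees, s and v in [0, 1].
rgb_to_hsv_deg <- function(m) {
  if (!is.matrix(m)) m <- matrix(m, ncol = 3L)
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 255)
  list(h = hsv[1, ] * 360, s = hsv[2, ], v = hsv[3, ])
}

# HSV (h degrees, s, v in [0,1]) -> RGB vector 0..255
hsv_to_rgb255 <- function(h, s, v) {
  h <- ((h %% 360) + 360) %% 360
  grDevices::col2rgb(grDevices::hsv(h / 360, s, v))[, 1]
}

# Nearest-neighbour resize of a 2-d matrix to new dimensions (used for
# ground-truth masks, which must stay binary under zoom resampling).
resize_nearest <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  yi <- pmin(h, pmax(1L, as.integer(round((seq_len(nh) - 0.5) * h / nh + 0.5))))
  xi <- pmin(w, pmax(1L, as.integer(round((seq_len(nw) - 0.5) * w / nw + 0.5))))
  m[yi, xi, drop = FALSE]
}
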