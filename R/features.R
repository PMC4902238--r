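#' Median RGB pixel features on a regular grid
#'
#' For every grid position (stride `stride` in x and y, starting at pixel
#' (1, 1)) the feature vector is the per-channel median over an 11 x 11
#' neighbourhood, clipped at the image border (median over the available
#' pixels). The median makes the feature robust to speckle while preserving
#' region color.
#'
#' @param img A [raster_image()].
#' @param stride Grid stride in pixels (default 2, i.e. a 2 x 2 grid).
#' @param window Neighbourhood side length in pixels.
#' @return A `feature_set`: list with integer vectors `x`, `y` (1-based grid
#'   pixel coordinates), a numeric `n x 3` matrix `X` of median RGB values,
#'   and `image_id`. Row order follows `expand.grid(y, x)`: y varies fastest.
#' @export
extract_features <- function(img, stride = 2L, window = 11L) {
  stopifnot(stride >= 1L, window >= 1L)
  d <- dim(img)
  X <- .grid_median_cpp(unclass(img), as.integer(stride), as.integer(window))
  ys <- seq.int(1L, d[1], by = stride)
  xs <- seq.int(1L, d[2], by = stride)
  colnames(X) <- c("R", "G", "B")
  structure(list(x = rep(xs, each = length(ys)),
                 y = rep(ys, times = length(xs)),
                 X = X, stride = as.integer(stride),
                 dim = d[1:2], image_id = image_id(img)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set %s: %d grid positions (stride %d)>\n",
              x$image_id, nrow(x$X), x$stride))
  invisible(x)
}

# Label grid positions of one feature_set from annotation rows:
# point labels mark the single nearest grid position, rectangle labels mark
# every grid position inside the rectangle. Returns a character vector of
# class names (NA where unlabeled).
label_grid <- function(fs, ann) {
  cls <- rep(NA_character_, nrow(fs$X))
  if (is.null(ann) || nrow(ann) == 0L) return(cls)
  ann <- ann[ann$image_id == fs$image_id, , drop = FALSE]
  if (nrow(ann) == 0L) return(cls)
  ny <- length(unique(fs$y))
  grid_index <- function(x, y) {
    gx <- pmin(max(fs$x), pmax(1L, round((x - 1) / fs$stride) * fs$stride + 1L))
    gy <- pmin(max(fs$y), pmax(1L, round((y - 1) / fs$stride) * fs$stride + 1L))
    ((gx - 1L) %/% fs$stride) * ny + ((gy - 1L) %/% fs$stride) + 1L
  }
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    if (a$shape == "point") {
      cls[grid_index(a$x, a$y)] <- a$label
    } else {
      xs <- seq.int(a$x, a$x + a$w - 1L)
      ys <- seq.int(a$y, a$y + a$h - 1L)
      gx <- xs[(xs - 1L) %% fs$stride == 0L]
      gy <- ys[(ys - 1L) %% fs$stride == 0L]
      gx <- gx[gx <= max(fs$x)]; gy <- gy[gy <= max(fs$y)]
      if (length(gx) && length(gy)) {
        ii <- as.vector(outer(((gy - 1L) %/% fs$stride) + 1L,
                              ((gx - 1L) %/% fs$stride) * ny,
                              "+"))
        cls[ii] <- a$label
      }
    }
  }
  cls
}

#' Assemble a (sparsely labelled) training set
#'
#' Samples a fraction of the images (without replacement), extracts grid
#' features from each, subsamples grid positions, and attaches binary labels:
#' `y = 1` where the grid position carries a `live` or `stressed` annotation
#' (the two categories are fused into one positive class), `y = 0` elsewhere
#' (including `dead`/`bare` and unlabeled positions). The annotated class is
#' kept alongside for evaluation.
#'
#' @param images List of [raster_image()]s.
#' @param annotations Annotation data frame (see [emit_annotations()] for the
#'   dialect).
#' @param image_fraction Fraction of images to sample, in (0, 1].
#' @param pixel_fraction Fraction of grid positions to keep per image.
#' @param stride Feature grid stride in pixels.
#' @param seed RNG seed; the set is reproducible per seed.
#' @return A `training_set`: list with matrix `X`, integer `y`, character
#'   `class`, and a `provenance` list.
#' @export
build_training_set <- function(images, annotations = NULL,
                               image_fraction = 0.02, pixel_fraction = 0.125,
                               stride = 2L, seed = 1L) {
  stopifnot(image_fraction > 0, image_fraction <= 1,
            pixel_fraction > 0, pixel_fraction <= 1, length(images) > 0)
  set.seed(seed)
  n_img <- max(1L, round(image_fraction * length(images)))
  pick <- sort(sample.int(length(images), n_img))
  parts <- lapply(pick, function(i) {
    fs <- extract_features(images[[i]], stride = stride)
    cls <- label_grid(fs, annotations)
    keep <- seq_len(nrow(fs$X))
    if (pixel_fraction < 1) {
      keep <- sort(sample.int(nrow(fs$X), round(pixel_fraction * nrow(fs$X))))
    }
    list(X = fs$X[keep, , drop = FALSE], class = cls[keep])
  })
  X <- do.call(rbind, lapply(parts, `[[`, "X"))
  if (nrow(X) == 0L) stop("empty training selection")
  cls <- unlist(lapply(parts, `[[`, "class"))
  y <- as.integer(!is.na(cls) & cls %in% c("live", "stressed"))
  structure(list(X = X, y = y, class = cls,
                 provenance = list(image_fraction = image_fraction,
                                   pixel_fraction = pixel_fraction,
                                   stride = stride, seed = seed,
                                   images = pick)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set: %d feature vectors, %d positive labels>\n",
              nrow(x$X), sum(x$y)))
  invisible(x)
}

#' Read and write the annotation CSV dialect
#'
#' Columns: `image_id, shape(point|rect), x, y, w, h, label(live|stressed|dead|bare)`.
#'
#' @param ann Annotation data frame.
#' @param path CSV path.
#' @return `read_annotations()` returns the data frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
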