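#' Illumination-correction parameters
#'
#' Local space-average color scaling: each channel is linearized (sRGB display
#' gamma 2.2), divided by `tau` times its heavily Gaussian-blurred version
#' (`sigma = sigma_factor * max(height, width)`), and re-encoded. The blur
#' estimates the local space-average color; dividing by it flattens smooth
#' illumination gradients.
#'
#' @param sigma_factor Blur width as a fraction of the larger image dimension.
#' @param tau Scaling factor in the denominator; `tau = 2` reproduces the
#'   slight global darkening of the pipeline's reference settings, `tau = 1`
#'   leaves a uniform image unchanged.
#' @param display_gamma Display gamma used for linearization.
#' @return An `illumination_params` list.
#' @export
illumination_params <- function(sigma_factor = 0.093, tau = 2,
                                display_gamma = 2.2) {
  stopifnot(sigma_factor > 0, tau > 0, display_gamma > 0)
  structure(list(sigma_factor = sigma_factor, tau = tau,
                 display_gamma = display_gamma),
            class = "illumination_params")
}

#' Correct smooth illumination gradients
#'
#' @param img A [raster_image()].
#' @param params An [illumination_params()] object.
#' @return The corrected [raster_image()], same dimensions.
#' @export
correct_illumination <- function(img, params = illumination_params()) {
  d <- dim(img)
  g <- params$display_gamma
  sigma <- params$sigma_factor * max(d[1], d[2])
  out <- unclass(img)
  for (c in 1:3) {
    lin <- (unclass(img)[, , c] / 255)^g
    blur <- EBImage::gblur(lin, sigma = sigma, boundary = "replicate")
    if (any(blur <= 1e-8)) {
      warning("near-black region in blur denominator; flooring at epsilon")
      blur <- pmax(blur, 1e-8)
    }
    out[, , c] <- 255 * (lin / (params$tau * blur))^(1 / g)
  }
  out <- clip255(out)
  raster_image(out, image_id = image_id(img), chamber = attr(img, "chamber"),
               timepoint = attr(img, "timepoint"))
}

#' Plate layout prior for circle detection
#'
#' @param radius Expected circle radius in pixels.
#' @param spacing Expected centre-to-centre distance of neighbouring circles.
#' @param n Number of circles on the plate.
#' @return A `plate_layout` list.
#' @export
plate_layout <- function(radius, spacing, n = 6L) {
  stopifnot(radius > 0, spacing > 0, n >= 2)
  structure(list(radius = radius, spacing = spacing, n = as.integer(n)),
            class = "plate_layout")
}

#' Layout prior matching a synthetic scene spec
#' @param spec A [scene_spec()].
#' @rdname plate_layout
#' @export
plate_layout_from_spec <- function(spec) {
  plate_layout(radius = spec$plate_radius * spec$zoom_true,
               spacing = spec$plate_spacing * spec$zoom_true)
}

plate_detection <- function(circles, colors, mode, used = NULL) {
  pd <- if (nrow(circles) >= 2L) {
    sqrt(diff(circles$x)^2 + diff(circles$y)^2)
  } else numeric(0)
  structure(list(circles = circles, colors = colors, mode = mode,
                 pair_distances = pd, used = used),
            class = "plate_detection")
}

#' @export
print.plate_detection <- function(x, ...) {
  cat(sprintf("<plate_detection: %d circle(s), mode '%s'>\n",
              nrow(x$circles), x$mode))
  invisible(x)
}

circle_median_colors <- function(img, circles) {
  h <- dim(img)[1]; w <- dim(img)[2]
  t(vapply(seq_len(nrow(circles)), function(l) {
    cx <- circles$x[l]; cy <- circles$y[l]; r <- circles$r[l]
    xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
    ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
    dx <- matrix(rep(xs - cx, each = length(ys)), length(ys))
    dy <- matrix(rep(ys - cy, times = length(xs)), length(ys))
    inside <- dx^2 + dy^2 < r^2
    vapply(1:3, function(c) {
      stats::median(unclass(img)[ys, xs, c][inside])
    }, numeric(1))
  }, numeric(3)))
}

#' Detect the color reference plate
#'
#' Finds the six reference circles with a Hough circle transform: an edge map
#' (gradient-magnitude threshold) is correlated with ring templates over a
#' range of radii around the layout prior, peaks are extracted with
#' non-maximum suppression, candidates with high interior color variance are
#' discarded, and the final set is chosen as the longest near-collinear chain
#' with near-uniform spacing. Circle colors are channel-wise medians over the
#' circle interiors.
#'
#' @param img A [raster_image()].
#' @param layout A [plate_layout()] prior (radius and spacing in pixels).
#' @param manual Optional data frame with columns `x`, `y`, `r` giving the
#'   circles directly (fallback when automatic detection fails); bypasses the
#'   Hough transform and returns `mode = "manual"`.
#' @param var_threshold Maximum per-channel interior standard deviation for a
#'   candidate to count as a flat color patch.
#' @param edge_quantile Quantile of gradient magnitude used as edge threshold.
#' @param min_score Minimum fraction of matched ring perimeter for a
#'   candidate.
#' @return A `plate_detection` with circles ordered top to bottom,
#'   per-circle RGB medians, `mode` one of `auto`, `partial`, `manual`,
#'   `failed`, and the consecutive-centre `pair_distances`.
#' @export
detect_plate <- function(img, layout, manual = NULL, var_threshold = 25,
                         edge_quantile = 0.95, min_score = 0.30) {
  if (!is.null(manual)) {
    stopifnot(all(c("x", "y", "r") %in% names(manual)))
    manual <- manual[order(manual$y), , drop = FALSE]
    cols <- circle_median_colors(img, manual)
    return(plate_detection(manual, cols, "manual"))
  }
  stopifnot(inherits(layout, "plate_layout"))
  h <- dim(img)[1]; w <- dim(img)[2]
  # per-channel gradients: plate circles may share luminance with the
  # background while differing strongly in color
  mag2 <- matrix(0, h, w)
  for (c in 1:3) {
    ch <- unclass(img)[, , c]
    gx <- cbind(ch[, -1, drop = FALSE], 0) - cbind(0, ch[, -w, drop = FALSE])
    gy <- rbind(ch[-1, , drop = FALSE], 0) - rbind(0, ch[-h, , drop = FALSE])
    gx[, c(1, w)] <- 0; gy[c(1, h), ] <- 0
    mag2 <- mag2 + gx^2 + gy^2
  }
  mag <- sqrt(mag2)
  # quantile floor handles textured scenes, the max() floor noise-free ones
  thr <- max(stats::quantile(mag, edge_quantile), 0.1 * max(mag))
  if (thr <= 0) {
    return(plate_detection(data.frame(x = numeric(), y = numeric(),
                                      r = numeric()),
                           matrix(numeric(), 0, 3), "failed"))
  }
  edge <- (mag >= thr) * 1

  radii <- seq(0.7 * layout$radius, 1.3 * layout$radius,
               by = max(1, 0.1 * layout$radius))
  best_acc <- matrix(-Inf, h, w); best_r <- matrix(radii[1], h, w)
  for (r in radii) {
    half <- ceiling(r) + 1L
    sz <- 2L * half + 1L
    dx <- matrix(rep(-half:half, each = sz), sz)
    dy <- matrix(rep(-half:half, times = sz), sz)
    ring <- (abs(sqrt(dx^2 + dy^2) - r) <= 1) * 1
    ring <- ring / sum(ring)
    acc <- EBImage::filter2(edge, ring, boundary = "replicate")
    upd <- acc > best_acc
    best_acc[upd] <- acc[upd]; best_r[upd] <- r
  }

  # non-maximum suppression
  cand <- list()
  acc <- best_acc
  min_dist <- layout$spacing / 2
  for (k in 1:24) {
    j <- which.max(acc)
    if (acc[j] < min_score) break
    cy <- ((j - 1L) %% h) + 1L; cx <- ((j - 1L) %/% h) + 1L
    cand[[length(cand) + 1L]] <- c(x = cx, y = cy, r = best_r[j],
                                   score = acc[j])
    xs <- max(1L, round(cx - min_dist)):min(w, round(cx + min_dist))
    ys <- max(1L, round(cy - min_dist)):min(h, round(cy + min_dist))
    acc[ys, xs] <- -Inf
  }
  if (length(cand) == 0L)
    return(plate_detection(data.frame(x = numeric(), y = numeric(),
                                      r = numeric()),
                           matrix(numeric(), 0, 3), "failed"))
  cand <- as.data.frame(do.call(rbind, cand))

  # keep flat-colored candidates
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    cc <- cand[i, ]
    xs <- max(1L, floor(cc$x - 0.7 * cc$r)):min(w, ceiling(cc$x + 0.7 * cc$r))
    ys <- max(1L, floor(cc$y - 0.7 * cc$r)):min(h, ceiling(cc$y + 0.7 * cc$r))
    sds <- vapply(1:3, function(c) stats::sd(unclass(img)[ys, xs, c]),
                  numeric(1))
    all(sds < var_threshold)
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(plate_detection(data.frame(x = numeric(), y = numeric(),
                                      r = numeric()),
                           matrix(numeric(), 0, 3), "failed"))

  # longest vertical chain with spacing close to the prior
  cand <- cand[order(cand$y), , drop = FALSE]
  n <- nrow(cand)
  chains <- lapply(seq_len(n), function(start) {
    chain <- start
    repeat {
      cur <- chain[length(chain)]
      dy <- cand$y - cand$y[cur]
      dxa <- abs(cand$x - cand$x[cur])
      ok <- which(dy > 0.6 * layout$spacing & dy < 1.4 * layout$spacing &
                    dxa < 0.5 * layout$spacing)
      if (length(ok) == 0L) break
      nxt <- ok[which.min(abs(cand$y[ok] - cand$y[cur] - layout$spacing))]
      chain <- c(chain, nxt)
    }
    chain
  })
  chain <- chains[[which.max(lengths(chains))]]
  if (length(chain) > layout$n)
    chain <- chain[seq_len(layout$n)]
  circles <- data.frame(x = cand$x[chain], y = cand$y[chain],
                        r = cand$r[chain])
  mode <- if (nrow(circles) == layout$n) "auto" else "partial"
  cols <- circle_median_colors(img, circles)
  plate_detection(circles, cols, mode)
}

#' Pool plate detections into a color and zoom reference
#'
#' Channel-wise medians over all detections give one reference RGB triplet per
#' circle; the grand mean over all consecutive-circle centre distances gives
#' the reference plate spacing used for zoom correction.
#'
#' @param detections List of `plate_detection` objects (modes other than
#'   `failed`).
#' @return A `color_reference` with `ref_colors` (6 x 3 matrix) and
#'   `mean_pair_distance`.
#' @export
build_reference <- function(detections) {
  if (inherits(detections, "plate_detection")) detections <- list(detections)
  detections <- Filter(function(d) d$mode != "failed", detections)
  if (length(detections) == 0L) stop("no usable plate detections")
  full <- Filter(function(d) nrow(d$circles) == 6L, detections)
  if (length(full) == 0L)
    stop("no detection with all 6 circles; cannot build a reference")
  cols <- array(unlist(lapply(full, function(d) d$colors)),
                c(6, 3, length(full)))
  ref <- apply(cols, c(1, 2), stats::median)
  pds <- unlist(lapply(full, function(d) d$pair_distances))
  structure(list(ref_colors = ref, mean_pair_distance = mean(pds),
                 n_images = length(full)),
            class = "color_reference")
}

#' @export
print.color_reference <- function(x, ...) {
  cat(sprintf("<color_reference from %s image(s), mean circle spacing %.1f px>\n",
              x$n_images, x$mean_pair_distance))
  print(round(x$ref_colors, 1))
  invisible(x)
}

#' Published in-water reference plate colors
#'
#' The six RGB triplets of the color reference plate as they appear underwater
#' in the study imagery (medians over all detected plates), and the saturated
#' triplets of the physical plate. `study_reference()` wraps the in-water
#' triplets as a ready-made `color_reference` fixture (its plate spacing is
#' unknown and set to `NA`).
#'
#' @return `plate_colors_reference()` / `plate_colors_original()`: 6 x 3
#'   matrices; `study_reference()`: a `color_reference`.
#' @export
plate_colors_reference <- function() {
  matrix(c(181, 185, 100,
           147, 179, 200,
           146, 173, 106,
           173, 101, 147,
           183,  67,  80,
            69,  88, 154), ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("R", "G", "B")))
}

#' @rdname plate_colors_reference
#' @export
plate_colors_original <- function() {
  matrix(c(0, 0, 255,
           255, 0, 0,
           255, 0, 255,
           0, 255, 0,
           0, 255, 255,
           255, 255, 0), ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("R", "G", "B")))
}

#' @rdname plate_colors_reference
#' @export
study_reference <- function() {
  structure(list(ref_colors = plate_colors_reference(),
                 mean_pair_distance = NA_real_, n_images = NA_integer_),
            class = "color_reference")
}

#' Estimate a per-channel gamma correction from the plate
#'
#' For each channel the correction exponent is the median over usable circles
#' of `log(ref/255) / log(obs/255)`, so that applying it ([apply_gamma()])
#' maps the observed plate colors onto the reference. Circles whose observed
#' or reference value sits at 0 or 255 on a channel are excluded from that
#' channel's median (the logs degenerate); if no circle is usable on a
#' channel, gamma falls back to 1 with a warning.
#'
#' @param det A `plate_detection` (at least 3 circles recommended).
#' @param ref A `color_reference`.
#' @return A `gamma_correction`: numeric length-3 exponents (R, G, B).
#' @export
estimate_gamma <- function(det, ref) {
  stopifnot(inherits(det, "plate_detection"),
            inherits(ref, "color_reference"))
  if (nrow(det$circles) < 3L)
    warning("fewer than 3 circles available; gamma medians are weakly defined")
  idx <- if (nrow(det$circles) == 6L) 1:6 else match_circles(det, ref)
  g <- vapply(1:3, function(c) {
    obs <- det$colors[, c]
    rf <- ref$ref_colors[idx, c]
    usable <- obs > 0 & obs < 255 & rf > 0 & rf < 255 & !is.na(rf)
    if (!any(usable)) {
      warning(sprintf("all circles degenerate on channel %d; gamma set to 1", c))
      return(1)
    }
    stats::median(log(rf[usable] / 255) / log(obs[usable] / 255))
  }, numeric(1))
  structure(g, names = c("R", "G", "B"), class = "gamma_correction")
}

# For partial detections, match found circles to reference rows by color
# proximity (reference rows are ordered top to bottom like the plate).
match_circles <- function(det, ref) {
  vapply(seq_len(nrow(det$circles)), function(i) {
    d <- colSums((t(ref$ref_colors) - det$colors[i, ])^2)
    which.min(d)
  }, integer(1))
}

#' Apply a gamma correction
#'
#' Channel-wise `J = 255 * (I/255)^gamma_c`, clipped to \[0, 255\].
#'
#' @param img A [raster_image()].
#' @param g A `gamma_correction` (or numeric length-3).
#' @return Corrected [raster_image()].
#' @export
apply_gamma <- function(img, g) {
  stopifnot(length(g) == 3L, all(g > 0), all(is.finite(g)))
  out <- unclass(img)
  for (c in 1:3) out[, , c] <- 255 * (pmax(out[, , c], 0) / 255)^g[c]
  raster_image(clip255(out), image_id = image_id(img),
               chamber = attr(img, "chamber"),
               timepoint = attr(img, "timepoint"))
}

#' Rescale an image to the reference zoom
#'
#' The image is resampled (bilinear) by
#' `s = mean_pair_distance(reference) / mean(pair distances observed)`, after
#' which the plate spacing matches the reference within about a pixel.
#'
#' @param img A [raster_image()].
#' @param det The image's `plate_detection` (needs >= 2 circles).
#' @param ref A `color_reference` with a finite `mean_pair_distance`.
#' @return Rescaled [raster_image()] with attribute `zoom_scale`.
#' @export
correct_zoom <- function(img, det, ref) {
  stopifnot(inherits(det, "plate_detection"),
            inherits(ref, "color_reference"))
  if (length(det$pair_distances) == 0L || any(det$pair_distances <= 0))
    stop("plate detection has no usable pair distances")
  if (!is.finite(ref$mean_pair_distance) || ref$mean_pair_distance <= 0)
    stop("reference has no valid mean pair distance")
  s <- ref$mean_pair_distance / mean(det$pair_distances)
  d <- dim(img)
  if (abs(s - 1) < 1e-9) {
    out <- img
  } else {
    nh <- as.integer(round(d[1] * s)); nw <- as.integer(round(d[2] * s))
    arr <- aperm(EBImage::resize(aperm(unclass(img), c(2, 1, 3)),
                                 w = nw, h = nh), c(2, 1, 3))
    out <- raster_image(clip255(arr), image_id = image_id(img),
                        chamber = attr(img, "chamber"),
                        timepoint = attr(img, "timepoint"))
  }
  attr(out, "zoom_scale") <- s
  out
}

#' Difference image of two equally sized rasters
#'
#' Per pixel and channel `(a - b)/2 + 128`, rounded and clipped to
#' \[0, 255\] -- a mid-grey image highlighting where two processing stages
#' disagree.
#'
#' @param a,b [raster_image()]s of equal dimensions.
#' @return A [raster_image()].
#' @export
difference_image <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images must have equal dimensions")
  raster_image(clip255(round((unclass(a) - unclass(b)) / 2 + 128)),
               image_id = paste0(image_id(a), "_diff"))
}
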