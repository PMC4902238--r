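#' Specify a synthetic plate + rhodolith scene
#'
#' Builds the parameter set for rendering a synthetic photograph of one or two
#' rhodolith samples next to a six-circle color reference plate, with full
#' ground truth. The generator emulates the laboratory recording setup: samples
#' in a water-filled cylinder, reference plate as a vertical strip of circles
#' in the left part of the frame, smooth illumination gradients, per-channel
#' gamma distortion, camera zoom variation and sensor noise.
#'
#' Structural randomness (blob shapes, sediment speckles, the orientation of
#' the illumination field) is controlled by `shape_seed`; per-pixel texture
#' randomness (palette jitter, additive noise) by `seed`. With
#' `noise_sd = 0` and `palette_sd = 0` the render is therefore identical for
#' any `seed`.
#'
#' Default image size is 864 x 648 (quarter linear scale of the study's
#' 3456 x 2592 frames) to keep rendering and classification fast; pass
#' `width`/`height` for other scales. Default plate colors are the published
#' in-water reference triplets, which are far from channel saturation and so
#' usable for gamma estimation.
#'
#' @param width,height Image size in pixels.
#' @param plate_colors 6 x 3 matrix of RGB triplets for the reference circles.
#' @param plate_x,plate_y0,plate_spacing,plate_radius Plate geometry in pixels
#'   (vertical strip of circles, uniform spacing); defaults scale with the
#'   image size.
#' @param n_samples Number of rhodolith samples in the scene (1 or 2).
#' @param palettes Named list of mean RGB triplets for classes `live`, `dead`,
#'   `bare`, `background`, `sediment`.
#' @param palette_sd Per-pixel RGB jitter (standard deviation) inside sample
#'   classes; the plate and background are rendered noise-free.
#' @param min_class_distance Minimum tolerated Euclidean distance between
#'   class mean colors; closer palettes are refused.
#' @param sediment_fraction Fraction of the sample area occluded by sediment
#'   speckles, in \[0, 1\].
#' @param illum_amp Amplitude of the smooth multiplicative illumination field
#'   (0 disables it).
#' @param gamma_true Length-3 vector of per-channel gamma distortion exponents;
#'   the rendered image is `255 * (clean/255)^(1/gamma_true)` per channel.
#' @param zoom_true Positive zoom factor; the scene is resampled by this factor
#'   after all photometric distortions.
#' @param noise_sd Additive Gaussian noise standard deviation (RGB units).
#' @param live_scale Scale factor applied to the live-region blob radius (used
#'   by [render_timeseries()] to shrink the live area).
#' @param hue_shift Rotation of the live palette hue in degrees (used by
#'   [render_timeseries()]).
#' @param seed,shape_seed Integer seeds (see above).
#' @return A `scene_spec` object (list).
#' @export
scene_spec <- function(width = 864L, height = 648L,
                       plate_colors = plate_colors_reference(),
                       plate_x = round(0.09 * width),
                       plate_y0 = round(0.11 * height),
                       plate_spacing = round(0.135 * height),
                       plate_radius = round(0.034 * height),
                       n_samples = 2L,
                       palettes = list(live = c(210, 110, 115),
                                       dead = c(205, 200, 195),
                                       bare = c(115, 90, 60),
                                       background = c(100, 110, 125),
                                       sediment = c(140, 120, 95)),
                       palette_sd = 8,
                       min_class_distance = 60,
                       sediment_fraction = 0.10,
                       illum_amp = 0.15,
                       gamma_true = c(1, 1, 1),
                       zoom_true = 1,
                       noise_sd = 3,
                       live_scale = 1,
                       hue_shift = 0,
                       seed = 1L, shape_seed = 7L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               plate_colors = as.matrix(plate_colors),
               plate_x = plate_x, plate_y0 = plate_y0,
               plate_spacing = plate_spacing, plate_radius = plate_radius,
               n_samples = as.integer(n_samples), palettes = palettes,
               palette_sd = palette_sd,
               min_class_distance = min_class_distance,
               sediment_fraction = sediment_fraction,
               illum_amp = illum_amp, gamma_true = gamma_true,
               zoom_true = zoom_true, noise_sd = noise_sd,
               live_scale = live_scale, hue_shift = hue_shift,
               seed = as.integer(seed), shape_seed = as.integer(shape_seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(spec$width > 0, spec$height > 0,
            nrow(spec$plate_colors) == 6L, ncol(spec$plate_colors) == 3L,
            spec$n_samples %in% 1:2, spec$zoom_true > 0,
            all(spec$gamma_true > 0), spec$sediment_fraction >= 0,
            spec$sediment_fraction <= 1)
  ys <- spec$plate_y0 + (0:5) * spec$plate_spacing
  if (spec$plate_spacing < 2 * spec$plate_radius + 2)
    stop("plate circles overlap: spacing must exceed the circle diameter")
  if (spec$plate_x - spec$plate_radius < 1 ||
      spec$plate_x + spec$plate_radius > spec$width ||
      min(ys) - spec$plate_radius < 1 ||
      max(ys) + spec$plate_radius > spec$height)
    stop("plate circles fall outside the image")
  cls <- c("live", "dead", "bare", "background")
  mu <- do.call(rbind, spec$palettes[cls])
  dd <- as.matrix(stats::dist(mu))
  diag(dd) <- Inf
  if (min(dd) < spec$min_class_distance) {
    bad <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("class palettes '%s' and '%s' are only %.1f RGB units",
                        " apart (minimum %g); choose separable palettes"),
                 cls[bad[1]], cls[bad[2]], min(dd), spec$min_class_distance))
  }
  invisible(spec)
}

# Irregular blob membership: pixels within a Fourier-perturbed radius of a
# centre. dx, dy are coordinate matrices relative to the centre.
blob_mask <- function(dx, dy, radius, coef) {
  th <- atan2(dy, dx)
  r <- sqrt(dx^2 + dy^2)
  pert <- 1
  for (k in seq_along(coef$a))
    pert <- pert + coef$a[k] * cos((k + 1) * th + coef$phi[k])
  r <= radius * pert
}

scene_geometry <- function(spec) {
  w <- spec$width; h <- spec$height
  set.seed(spec$shape_seed)
  centres <- if (spec$n_samples == 1L) {
    cbind(x = 0.55 * w, y = 0.50 * h)
  } else {
    cbind(x = c(0.55, 0.58) * w, y = c(0.29, 0.72) * h)
  }
  rs <- 0.20 * min(w, h)
  samples <- lapply(seq_len(spec$n_samples), function(i) {
    list(cx = centres[i, 1], cy = centres[i, 2], r = rs,
         coef_sample = list(a = stats::rnorm(3, 0, 0.05),
                            phi = stats::runif(3, 0, 2 * pi)),
         coef_dead = list(a = stats::rnorm(3, 0, 0.07),
                          phi = stats::runif(3, 0, 2 * pi)),
         coef_live = list(a = stats::rnorm(3, 0, 0.07),
                          phi = stats::runif(3, 0, 2 * pi)),
         dead_off = stats::runif(2, -0.08, 0.08) * rs,
         live_off = stats::runif(2, -0.06, 0.06) * rs)
  })
  gain_dir <- stats::runif(1, 0, 2 * pi)
  bump <- c(stats::runif(1, 0.3, 0.7) * w, stats::runif(1, 0.3, 0.7) * h)
  # sediment deposits as a moderate number of drifts, not confetti
  n_speck <- 80
  speck <- list(u = stats::runif(n_speck), v = stats::runif(n_speck),
                th = stats::runif(n_speck, 0, 2 * pi),
                r = stats::runif(n_speck, 6, 18))
  list(samples = samples, gain_dir = gain_dir, bump = bump, speck = speck)
}

#' Render a synthetic scene with ground truth
#'
#' Draws the clean scene (background, reference plate, samples with live /
#' dead / bare regions and sediment speckles), then applies the distortion
#' chain in a fixed, documented order: per-channel gamma, multiplicative
#' illumination gain, additive noise, zoom resampling, clipping to \[0, 255\].
#' Ground-truth masks describe the *visible* class regions (sediment-occluded
#' pixels are not counted) and are resampled to the emitted image size.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `image` (a [raster_image()]) and `truth`, the
#'   latter holding binary masks `mask_live`, `mask_dead`, `mask_bare`, the
#'   true plate geometry (`plate`: data frame with `x`, `y`, `r`),
#'   `gamma_true`, `zoom_true`, the illumination `gain` field (pre-zoom) and
#'   `live_area` (pixels of visible live algae in the emitted image).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_scene_spec(spec)
  w <- spec$width; h <- spec$height
  geom <- scene_geometry(spec)
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)

  img <- array(0, c(h, w, 3))
  for (c in 1:3) img[, , c] <- spec$palettes$background[c]

  # class regions per sample
  live <- matrix(FALSE, h, w); dead <- matrix(FALSE, h, w)
  bare <- matrix(FALSE, h, w); samp <- matrix(FALSE, h, w)
  for (s in geom$samples) {
    ms <- blob_mask(X - s$cx, Y - s$cy, s$r, s$coef_sample)
    md <- blob_mask(X - (s$cx + s$dead_off[1]), Y - (s$cy + s$dead_off[2]),
                    0.85 * s$r, s$coef_dead) & ms
    ml <- blob_mask(X - (s$cx + s$live_off[1]), Y - (s$cy + s$live_off[2]),
                    0.70 * s$r * spec$live_scale, s$coef_live) & ms
    samp <- samp | ms
    live <- live | ml
    dead <- dead | (md & !ml)
    bare <- bare | (ms & !md & !ml)
  }
  dead <- dead & !live
  bare <- bare & !live & !dead

  # sediment speckles occlude sample pixels
  sed <- matrix(FALSE, h, w)
  if (spec$sediment_fraction > 0) {
    target <- spec$sediment_fraction * sum(samp)
    sp <- geom$speck
    for (k in seq_along(sp$u)) {
      if (sum(sed & samp) >= target) break
      s <- geom$samples[[1 + (k %% length(geom$samples))]]
      cx <- s$cx + (sp$u[k] - 0.5) * 2 * s$r * cos(sp$th[k])
      cy <- s$cy + (sp$v[k] - 0.5) * 2 * s$r * sin(sp$th[k])
      sed <- sed | ((X - cx)^2 + (Y - cy)^2 <= sp$r[k]^2)
    }
    sed <- sed & samp
  }

  # paint classes (seeded texture jitter), sediment on top
  set.seed(spec$seed)
  live_col <- spec$palettes$live
  if (spec$hue_shift != 0) {
    hsv <- rgb_to_hsv_deg(matrix(live_col, 1))
    live_col <- as.numeric(hsv_to_rgb255(hsv$h + spec$hue_shift, hsv$s, hsv$v))
  }
  paint <- function(img, mask, col) {
    n <- sum(mask)
    if (n == 0L) return(img)
    for (c in 1:3) {
      ch <- img[, , c]
      jit <- if (spec$palette_sd > 0) stats::rnorm(n, 0, spec$palette_sd) else 0
      ch[mask] <- col[c] + jit
      img[, , c] <- ch
    }
    img
  }
  img <- paint(img, bare, spec$palettes$bare)
  img <- paint(img, dead, spec$palettes$dead)
  img <- paint(img, live, live_col)
  img <- paint(img, sed, spec$palettes$sediment)

  # reference plate: exact colors, no jitter
  ys <- spec$plate_y0 + (0:5) * spec$plate_spacing
  for (l in 1:6) {
    m <- (X - spec$plate_x)^2 + (Y - ys[l])^2 < spec$plate_radius^2
    for (c in 1:3) {
      ch <- img[, , c]; ch[m] <- spec$plate_colors[l, c]; img[, , c] <- ch
    }
  }

  # visible-class ground truth
  live <- live & !sed; dead <- dead & !sed; bare <- bare & !sed

  # distortion chain: gamma -> gain -> noise -> zoom -> clip
  for (c in 1:3)
    img[, , c] <- 255 * (pmax(img[, , c], 0) / 255)^(1 / spec$gamma_true[c])
  gain <- matrix(1, h, w)
  if (spec$illum_amp > 0) {
    u <- (X / w - 0.5) * cos(geom$gain_dir) + (Y / h - 0.5) * sin(geom$gain_dir)
    bump <- exp(-((X - geom$bump[1])^2 + (Y - geom$bump[2])^2) /
                  (2 * (0.4 * min(w, h))^2))
    gain <- 1 + spec$illum_amp * u + 0.5 * spec$illum_amp * (bump - mean(bump))
    for (c in 1:3) img[, , c] <- img[, , c] * gain
  }
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  plate <- data.frame(x = rep(spec$plate_x, 6), y = ys,
                      r = rep(spec$plate_radius, 6))
  if (spec$zoom_true != 1) {
    nh <- as.integer(round(h * spec$zoom_true))
    nw <- as.integer(round(w * spec$zoom_true))
    img <- aperm(EBImage::resize(aperm(img, c(2, 1, 3)), w = nw, h = nh),
                 c(2, 1, 3))
    live <- resize_nearest(live * 1, nh, nw) > 0.5
    dead <- resize_nearest(dead * 1, nh, nw) > 0.5
    bare <- resize_nearest(bare * 1, nh, nw) > 0.5
    plate$x <- plate$x * spec$zoom_true
    plate$y <- plate$y * spec$zoom_true
    plate$r <- plate$r * spec$zoom_true
  }
  img <- clip255(img)

  truth <- list(mask_live = live * 1, mask_dead = dead * 1,
                mask_bare = bare * 1, plate = plate,
                gamma_true = spec$gamma_true, zoom_true = spec$zoom_true,
                gain = gain, live_area = sum(live))
  list(image = raster_image(img, image_id = sprintf("scene_s%d", spec$seed)),
       truth = truth)
}

#' Render a shrinking, hue-drifting time series of scenes
#'
#' Re-renders the same scene geometry at successive time points, scaling the
#' live-region blob so its area follows `area * (1 - shrink_rate)^t` and
#' rotating the live palette hue by `hue_drift` degrees per time point.
#' Texture noise differs between frames (seed offset by `t`); geometry is
#' shared via `shape_seed`.
#'
#' @param spec A [scene_spec()]; its `live_scale`/`hue_shift` are overridden.
#' @param n_timepoints Number of frames (>= 2).
#' @param shrink_rate Per-step fractional loss of live area, in \[0, 1\].
#' @param hue_drift Hue rotation per time point, degrees.
#' @return List of `n_timepoints` render results (as from [render_scene()]),
#'   each image carrying its `timepoint` attribute (0-based time index).
#' @export
render_timeseries <- function(spec, n_timepoints, shrink_rate = 0,
                              hue_drift = 0) {
  stopifnot(n_timepoints >= 2, shrink_rate >= 0, shrink_rate < 1)
  lapply(seq_len(n_timepoints) - 1L, function(t) {
    sp <- spec
    sp$live_scale <- spec$live_scale * sqrt((1 - shrink_rate)^t)
    sp$hue_shift <- spec$hue_shift + t * hue_drift
    sp$seed <- spec$seed + t
    out <- render_scene(sp)
    attr(out$image, "timepoint") <- t
    attr(out$image, "image_id") <- sprintf("scene_s%d_t%d", spec$seed, t)
    out
  })
}

#' Sample sparse annotations from ground truth
#'
#' Emulates expert point and rectangle labels: points are sampled uniformly
#' inside class masks, rectangles are axis-aligned boxes lying entirely inside
#' one class mask. Classes `live` and `stressed` are both drawn from
#' `mask_live` (the downstream classifier fuses them into one positive class);
#' `dead` and `bare` come from their masks. Default class proportions follow
#' the study's label counts (2404 / 2834 / 4358 / 43).
#'
#' @param truth Ground truth from [render_scene()].
#' @param n_points,n_frames Number of point and rectangle labels.
#' @param seed RNG seed.
#' @param image_id Image id written into the annotation rows.
#' @param class_probs Named sampling probabilities over
#'   `live`, `stressed`, `dead`, `bare`.
#' @param frame_half Range of rectangle half-sizes in pixels.
#' @return Data frame with columns `image_id`, `shape` (`point`/`rect`), `x`,
#'   `y`, `w`, `h`, `label`. For points `w = h = 0`; for rectangles `(x, y)`
#'   is the top-left pixel and `w`, `h` the box size in pixels.
#' @export
emit_annotations <- function(truth, n_points, n_frames, seed = 1L,
                             image_id = "img",
                             class_probs = c(live = 2404, stressed = 2834,
                                             dead = 4358, bare = 43),
                             frame_half = c(5L, 12L)) {
  set.seed(seed)
  empty <- data.frame(image_id = character(), shape = character(),
                      x = integer(), y = integer(), w = integer(),
                      h = integer(), label = character(),
                      stringsAsFactors = FALSE)
  if (n_points + n_frames == 0L) return(empty)
  class_probs <- class_probs / sum(class_probs)
  mask_of <- function(cls)
    switch(cls, live = , stressed = truth$mask_live,
           dead = truth$mask_dead, bare = truth$mask_bare)
  pick_classes <- function(n) {
    cls <- sample(names(class_probs), n, replace = TRUE, prob = class_probs)
    ok <- vapply(cls, function(cc) sum(mask_of(cc)) > 0, logical(1))
    avail <- names(class_probs)[vapply(names(class_probs),
                                       function(cc) sum(mask_of(cc)) > 0,
                                       logical(1))]
    if (length(avail) == 0L) stop("all class masks are empty")
    cls[!ok] <- sample(avail, sum(!ok), replace = TRUE)
    cls
  }
  rows <- list()
  if (n_points > 0L) {
    cls <- pick_classes(n_points)
    for (i in seq_len(n_points)) {
      m <- mask_of(cls[i])
      idx <- which(m > 0)
      j <- idx[sample.int(length(idx), 1L)]
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = image_id, shape = "point",
        x = ((j - 1L) %/% nrow(m)) + 1L, y = ((j - 1L) %% nrow(m)) + 1L,
        w = 0L, h = 0L, label = cls[i], stringsAsFactors = FALSE)
    }
  }
  if (n_frames > 0L) {
    cls <- pick_classes(n_frames)
    for (i in seq_len(n_frames)) {
      m <- mask_of(cls[i])
      placed <- FALSE
      for (half in rev(seq.int(frame_half[1], frame_half[2]))) {
        size <- 2L * half + 1L
        er <- erode_box(m, size)
        # erode_box anchors the element at its top-left: er[y, x] == 1 means
        # the box with top-left (x, y) fits inside the mask
        idx <- which(er > 0)
        if (length(idx) == 0L) next
        j <- idx[sample.int(length(idx), 1L)]
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = image_id, shape = "rect",
          x = ((j - 1L) %/% nrow(m)) + 1L, y = ((j - 1L) %% nrow(m)) + 1L,
          w = size, h = size, label = cls[i], stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed)
        warning(sprintf("no %s rectangle of requested size fits; skipped",
                        cls[i]))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}
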