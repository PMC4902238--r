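# Shared fixtures, memoised across test files. Heavy objects (rendered
# scenes, the trained segmentation model) are built once on first use.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- builder()
  .fx_env[[name]]
}

# scene with all stochastic and photometric distortions disabled
clean_spec <- function(...) {
  scene_spec(noise_sd = 0, palette_sd = 0, illum_amp = 0,
             sediment_fraction = 0, ...)
}

small_clean_spec <- function(...) clean_spec(width = 432L, height = 324L, ...)

fx_clean_scene <- function() fx("clean_scene", function() {
  render_scene(clean_spec())
})

fx_clean_det <- function() fx("clean_det", function() {
  detect_plate(fx_clean_scene()$image, plate_layout_from_spec(clean_spec()))
})

fx_clean_ref <- function() fx("clean_ref", function() {
  build_reference(fx_clean_det())
})

# reference built from a scene with sensor noise but flat illumination,
# used by the gamma-recovery tests
fx_noisy_ref <- function() fx("noisy_ref", function() {
  sp <- scene_spec(illum_amp = 0)
  build_reference(detect_plate(render_scene(sp)$image,
                               plate_layout_from_spec(sp)))
})

# Segmentation fixture: 20 seeded synthetic scenes at default generator
# settings, illumination-corrected. Mirroring the study design, the H2SOM and
# the prototype label mapping are built from a small image subset (6 of the
# 20 scenes, every second grid position: ~4e5 median-RGB features), and the
# classifier is then applied to all 20 scenes; masks are post-processed with
# the 10x10 opening and scored against ground truth.
fx_seg <- function() fx("seg", function() {
  n <- 20L
  train_scenes <- 1:6
  scenes <- lapply(seq_len(n), function(i) {
    render_scene(scene_spec(seed = 100L + i, shape_seed = i))
  })
  imgs <- lapply(seq_len(n), function(i) {
    img <- correct_illumination(scenes[[i]]$image)
    attr(img, "image_id") <- sprintf("img%02d", i)
    img
  })
  anns <- do.call(rbind, lapply(seq_len(n), function(i) {
    emit_annotations(scenes[[i]]$truth, n_points = 160L, n_frames = 4L,
                     seed = i, image_id = sprintf("img%02d", i),
                     frame_half = c(3L, 6L))
  }))
  ts_map <- build_training_set(
    imgs[train_scenes],
    anns[anns$image_id %in% sprintf("img%02d", train_scenes), ],
    image_fraction = 1, pixel_fraction = 0.5, stride = 2L, seed = 3L)
  model <- h2som(ts_map$X, iter_mult = 30, seed = 5L)
  lmod <- fit_label_model(model, ts_map)
  masks <- lapply(imgs, function(img) {
    open_mask(classify_image(img, model, lmod, stride = 2L), 10L)
  })
  stats <- do.call(rbind, lapply(seq_len(n), function(i) {
    gt <- scenes[[i]]$truth
    neg <- (gt$mask_dead + gt$mask_bare) > 0
    data.frame(
      recall = sum(masks[[i]] > 0 & gt$mask_live > 0) / sum(gt$mask_live),
      fpr = sum(masks[[i]] > 0 & neg) / sum(neg))
  }))
  list(scenes = scenes, imgs = imgs, anns = anns, training = ts_map,
       model = model, lmod = lmod, masks = masks, stats = stats)
})

# Naive reference implementation of binary opening with a k x k box
# (definition: erosion then dilation over the same offset set), used as the
# morphological oracle on small masks.
naive_open <- function(mask, k) {
  h <- nrow(mask); w <- ncol(mask)
  er <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    ys <- y:(y + k - 1L); xs <- x:(x + k - 1L)
    if (max(ys) <= h && max(xs) <= w && all(mask[ys, xs] > 0)) er[y, x] <- 1
  }
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    ys <- max(1L, y - k + 1L):y; xs <- max(1L, x - k + 1L):x
    if (any(er[ys, xs] > 0)) out[y, x] <- 1
  }
  out
}

# R oracle for the grid median features (direct neighbourhood medians)
naive_grid_median <- function(img, stride, window = 11L) {
  d <- dim(img); half <- window %/% 2L
  ys <- seq.int(1L, d[1], by = stride); xs <- seq.int(1L, d[2], by = stride)
  out <- matrix(NA_real_, length(ys) * length(xs), 3L)
  k <- 1L
  for (x in xs) for (y in ys) {
    yy <- max(1L, y - half):min(d[1], y + half)
    xx <- max(1L, x - half):min(d[2], x + half)
    out[k, ] <- vapply(1:3, function(c) stats::median(img[yy, xx, c]),
                       numeric(1))
    k <- k + 1L
  }
  out
}
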