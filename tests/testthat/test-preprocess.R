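test_that("illumination correction flattens gradients and fixes flat fields", {
  # flat field: output is 255 * (1/tau)^(1/2.2) whatever the input level
  img <- raster_image(array(120, c(60, 80, 3)))
  out <- correct_illumination(img)
  expect_equal(mean(out), 255 * 0.5^(1 / 2.2), tolerance = 1e-2)
  expect_lt(max(out) - min(out), 1e-6)
  img2 <- raster_image(array(40, c(60, 80, 3)))
  expect_equal(mean(correct_illumination(img2)), 255 * 0.5^(1 / 2.2),
               tolerance = 1e-2)
  expect_equal(mean(correct_illumination(img, illumination_params(tau = 1))),
               255, tolerance = 1e-2)

  # multiplicative ramp on a flat scene: strong reduction in variation
  h <- 120L; w <- 160L
  ramp <- matrix(rep(seq(0.5, 1.5, length.out = w), each = h), h)
  arr <- array(0, c(h, w, 3))
  for (c in 1:3) arr[, , c] <- 140 * ramp
  corrected <- correct_illumination(raster_image(arr))
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(unclass(corrected)[, , 1]), 0.1 * cv(arr[, , 1]))
})

test_that("plate detection recovers circles, degrades gracefully, and fails loudly", {
  sp <- clean_spec()
  sc <- fx_clean_scene()
  det <- fx_clean_det()
  expect_identical(det$mode, "auto")
  err <- sqrt((det$circles$x - sc$truth$plate$x)^2 +
                (det$circles$y - sc$truth$plate$y)^2)
  expect_true(all(err < 2))
  expect_equal(det$colors, unname(sp$plate_colors), tolerance = 1e-8)
  expect_length(det$pair_distances, 5L)

  # specular highlight painted over two circles -> partial detection
  img <- unclass(sc$image)
  ys <- sp$plate_y0 + (0:5) * sp$plate_spacing
  X <- matrix(rep(seq_len(sp$width), each = sp$height), sp$height)
  Y <- matrix(rep(seq_len(sp$height), sp$width), sp$height)
  for (l in 5:6) {
    hl <- (X - sp$plate_x)^2 + (Y - ys[l])^2 < (1.6 * sp$plate_radius)^2
    for (c in 1:3) {
      ch <- img[, , c]
      ch[hl] <- 255 * runif(sum(hl), 0.6, 1)  # glare destroys flat interior
      img[, , c] <- ch
    }
  }
  det_p <- detect_plate(raster_image(img), plate_layout_from_spec(sp))
  expect_identical(det_p$mode, "partial")
  expect_equal(nrow(det_p$circles), 4L)

  blank <- raster_image(array(128, c(200, 150, 3)))
  expect_identical(detect_plate(blank, plate_layout(20, 50))$mode, "failed")

  # manual fallback bypasses the Hough transform
  man <- detect_plate(sc$image, manual = sc$truth$plate)
  expect_identical(man$mode, "manual")
  expect_equal(man$colors, unname(sp$plate_colors), tolerance = 1e-8)
})

test_that("reference pooling is an identity for one detection and median-robust for several", {
  det <- fx_clean_det()
  ref1 <- build_reference(list(det))
  expect_equal(ref1$ref_colors, det$colors)
  expect_equal(ref1$mean_pair_distance, mean(det$pair_distances))

  # hand-computable median over 3 detections with one outlier
  mk <- function(cols) {
    d <- det; d$colors <- cols; d
  }
  a <- det$colors
  b <- det$colors + 2
  c_out <- det$colors; c_out[1, ] <- c(250, 5, 5)
  ref3 <- build_reference(list(mk(a), mk(b), mk(c_out)))
  expected <- apply(simplify2array(list(a, b, c_out)), c(1, 2), median)
  expect_equal(ref3$ref_colors, expected)
  # the outlier never dominates: pooled colors stay within the honest pair
  expect_true(all(ref3$ref_colors >= pmin(a, b) & ref3$ref_colors <= pmax(a, b)))
  expect_error(build_reference(list()), "usable")
})

test_that("gamma estimation inverts per-channel distortions (round trip on the plate)", {
  ref <- fx_clean_ref()
  det <- fx_clean_det()
  # identity: observed equals reference
  expect_equal(unclass(estimate_gamma(det, ref)), c(R = 1, G = 1, B = 1))

  # single-circle direct evaluation: obs 128, ref 64 on one channel
  d1 <- det
  d1$circles <- det$circles[1, , drop = FALSE]
  d1$colors <- matrix(c(128, 128, 128), 1)
  r1 <- ref
  r1$ref_colors <- matrix(c(64, 64, 64), 1)
  g1 <- suppressWarnings(estimate_gamma(d1, r1))
  expect_equal(unname(g1[1]), log(64 / 255) / log(128 / 255), tolerance = 1e-9)

  # apply then estimate against the original recovers the inverse exponent
  img <- fx_clean_scene()$image
  gset <- c(0.8, 1.0, 1.25)
  out <- apply_gamma(img, gset)
  det2 <- detect_plate(out, plate_layout_from_spec(clean_spec()))
  g2 <- estimate_gamma(det2, ref)
  expect_equal(unclass(g2), c(R = 1, G = 1, B = 1) / gset, tolerance = 0.01)

  # synthetic distortion round trip: estimate + apply restores plate colors
  sp <- clean_spec(gamma_true = c(0.8, 1.0, 1.25))
  sc <- render_scene(sp)
  d3 <- detect_plate(sc$image, plate_layout_from_spec(sp))
  g3 <- estimate_gamma(d3, ref)
  expect_equal(unclass(g3), c(R = 0.8, G = 1, B = 1.25), tolerance = 0.05)
  d4 <- detect_plate(apply_gamma(sc$image, g3), plate_layout_from_spec(sp))
  expect_lt(max(abs(d4$colors - ref$ref_colors)), 3)
})

test_that("apply_gamma matches direct evaluation and ignores identity", {
  img <- raster_image(array(128, c(10, 10, 3)))
  expect_equal(unclass(apply_gamma(img, c(1, 1, 1)))[, , ],
               unclass(img)[, , ])
  out <- apply_gamma(img, c(2, 2, 2))
  expect_equal(out[1, 1, 1], 255 * (128 / 255)^2, tolerance = 1e-9)
  expect_error(apply_gamma(img, c(-1, 1, 1)))
})

test_that("zoom correction rescales to the reference plate spacing", {
  ref <- fx_clean_ref()
  det <- fx_clean_det()
  same <- correct_zoom(fx_clean_scene()$image, det, ref)
  expect_equal(attr(same, "zoom_scale"), 1, tolerance = 1e-9)
  expect_equal(dim(same), dim(fx_clean_scene()$image))

  sp <- clean_spec(zoom_true = 1.25)
  sc <- render_scene(sp)
  dz <- detect_plate(sc$image, plate_layout_from_spec(sp))
  corr <- correct_zoom(sc$image, dz, ref)
  expect_equal(attr(corr, "zoom_scale"), 0.8, tolerance = 0.02)
  dc <- detect_plate(corr, plate_layout_from_spec(clean_spec()))
  expect_true(all(abs(dc$pair_distances - ref$mean_pair_distance) <= 1))
})

test_that("difference image centres at mid-grey with the documented rounding", {
  a <- raster_image(array(90, c(5, 6, 3)))
  expect_true(all(difference_image(a, a) == 128))
  hi <- raster_image(array(255, c(5, 6, 3)))
  lo <- raster_image(array(0, c(5, 6, 3)))
  expect_true(all(difference_image(hi, lo) == 255))
  expect_true(all(difference_image(lo, hi) == 0))
  expect_error(difference_image(a, raster_image(array(0, c(6, 6, 3)))),
               "dimensions")
})
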