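#' Measure size and HSV color of segmented live algae
#'
#' The size is the segmented pixel count weighted by the ratio of the
#' reference plate spacing to this image's observed plate spacing
#' (`A = size * d_ref / d_n`), compensating residual zoom differences.
#' Colors are measured in HSV over the segmented pixels: hue as a circular
#' mean (degrees), saturation and value as arithmetic means in \[0, 1\].
#' An empty mask yields `A = 0` and missing color fields, which later flags
#' the observation for the outlier rule.
#'
#' @param img The (corrected) [raster_image()].
#' @param mask Binary segmentation mask of equal size.
#' @param det The image's `plate_detection`.
#' @param ref A `color_reference` with finite `mean_pair_distance`.
#' @return One-row data frame: `image_id`, `chamber`, `timepoint`, `A`,
#'   `h_bar`, `s_bar`, `v_bar`.
#' @export
measure_sample <- function(img, mask, det, ref) {
  stopifnot(all(dim(mask) == dim(img)[1:2]))
  dn <- mean(det$pair_distances)
  wgt <- if (is.finite(ref$mean_pair_distance) && is.finite(dn) && dn > 0)
    ref$mean_pair_distance / dn else 1
  n <- sum(mask > 0)
  if (n == 0L) {
    return(data.frame(image_id = image_id(img),
                      chamber = attr(img, "chamber") %||% NA_integer_,
                      timepoint = attr(img, "timepoint") %||% NA_integer_,
                      A = 0, h_bar = NA_real_, s_bar = NA_real_,
                      v_bar = NA_real_))
  }
  sel <- which(mask > 0)
  rgb <- cbind(unclass(img)[, , 1][sel], unclass(img)[, , 2][sel],
               unclass(img)[, , 3][sel])
  hsv <- rgb_to_hsv_deg(rgb)
  data.frame(image_id = image_id(img),
             chamber = attr(img, "chamber") %||% NA_integer_,
             timepoint = attr(img, "timepoint") %||% NA_integer_,
             A = n * wgt,
             h_bar = circular_mean(hsv$h),
             s_bar = mean(hsv$s), v_bar = mean(hsv$v))
}

#' Relative size within a measurement series
#'
#' Divides each chamber's weighted sizes by its baseline `A_0`, the earliest
#' retained time point with nonzero size, so the baseline relative size is 1.
#' (In the study the first two time points were excluded for plate
#' reflections, so "first measurement" means the first *retained* one.)
#'
#' @param records Data frame of [measure_sample()] rows.
#' @return The records with an `A_hat` column, ordered by chamber and
#'   timepoint. All-zero series get `A_hat = NA`.
#' @export
relative_size <- function(records) {
  records <- records[order(records$chamber, records$timepoint), , drop = FALSE]
  parts <- split(records, records$chamber)
  out <- lapply(parts, function(df) {
    base <- df$A[df$A > 0][1]
    df$A_hat <- if (is.na(base)) NA_real_ else df$A / base
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average measurements per chamber and time point
#'
#' All samples in a chamber share the same treatment, and each photo holds two
#' samples that are not co-located across time, so measurements are averaged
#' chamber-wise: arithmetic means for `A_hat`, `s_bar`, `v_bar`, a circular
#' mean for hue. The result is joined with the chamber design factors (L, F,
#' S) and, when given, external responses (e.g. photosynthetic efficiency `P`
#' and sediment coverage `SC` per chamber and time point).
#'
#' @param records Measurement rows (with `A_hat`, see [relative_size()]).
#' @param design Chamber design table with columns `chamber`, `L`, `F`, `S`.
#' @param responses Optional data frame keyed by `chamber` and `timepoint`
#'   with extra response columns.
#' @return A chamber-series data frame, one row per chamber x timepoint.
#' @export
aggregate_chambers <- function(records, design, responses = NULL) {
  if (!all(records$chamber %in% design$chamber))
    stop("records reference chamber ids missing from the design table")
  key <- interaction(records$chamber, records$timepoint, drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(df) {
    data.frame(chamber = df$chamber[1], timepoint = df$timepoint[1],
               A_hat = mean(df$A_hat), h_bar = circular_mean(df$h_bar),
               s_bar = mean(df$s_bar), v_bar = mean(df$v_bar))
  }))
  out <- merge(agg, design[, c("chamber", "L", "F", "S")], by = "chamber")
  if (!is.null(responses))
    out <- merge(out, responses, by = c("chamber", "timepoint"),
                 all.x = TRUE)
  out <- out[order(out$chamber, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}
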