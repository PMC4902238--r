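#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()]:
#' stage toggles, per-module parameters and seeds. The configuration
#' round-trips through YAML ([write_config()]/[read_config()]).
#'
#' @param out_dir Output directory for images, models, tables and the
#'   manifest.
#' @param stages Named logical list enabling pipeline stages.
#' @param simulate,preprocess,features,h2som,labelmap,segment,pls Named lists
#'   of stage parameters (see Details in the package vignette); partial lists
#'   are merged over the defaults.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("rhodoscan_run_"),
                       stages = list(), simulate = list(),
                       preprocess = list(), features = list(),
                       h2som = list(), labelmap = list(), segment = list(),
                       pls = list(), seed = 1L) {
  # like modifyList, but a NULL user value sets the entry to NULL instead of
  # deleting it, so configurations round-trip through YAML unchanged
  merge_over <- function(defaults, user) {
    stopifnot(all(names(user) %in% names(defaults)))
    for (nm in names(user)) defaults[nm] <- list(user[[nm]])
    defaults
  }
  cfg <- list(
    out_dir = out_dir,
    stages = merge_over(list(simulate = TRUE, preprocess = TRUE,
                             train = TRUE, labelmap = TRUE, segment = TRUE,
                             quantify = TRUE, regress = TRUE), stages),
    simulate = merge_over(list(n_chambers = 2L, n_timepoints = 3L,
                               width = 432L, height = 324L,
                               shrink_rate = 0.08, hue_drift = -1,
                               n_points = 40L, n_frames = 8L,
                               sediment_fraction = 0.1, illum_amp = 0.1,
                               noise_sd = 2), simulate),
    preprocess = merge_over(list(sigma_factor = 0.093, tau = 2,
                                 detect = TRUE, manual_circles = NULL,
                                 var_threshold = 25, illumination = TRUE),
                            preprocess),
    features = merge_over(list(stride = 2L, image_fraction = 1,
                               pixel_fraction = 0.25), features),
    h2som = merge_over(list(rings = 3L, branching = 8L, iter_mult = 10),
                       h2som),
    labelmap = merge_over(list(coverage_target = 0.8), labelmap),
    segment = merge_over(list(opening = 10L), segment),
    pls = merge_over(list(ncomp = 2L, cv = "chamber",
                          responses = c("A_hat", "h_bar", "s_bar", "v_bar"),
                          add_square = "S"), pls),
    seed = as.integer(seed))
  stopifnot(cfg$simulate$n_chambers >= 1, cfg$simulate$n_timepoints >= 2,
            cfg$h2som$rings >= 1, cfg$h2som$branching >= 7,
            cfg$labelmap$coverage_target > 0,
            cfg$labelmap$coverage_target <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw)
  cfg
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(as.vector(h), basename(paths))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order -- simulate scenes, preprocess
#' (illumination, plate detection, gamma and zoom correction), train the
#' H2SOM, map prototype labels, segment, quantify size and color, and fit the
#' PLS regression -- writing all artifacts under `cfg$out_dir` and returning
#' a manifest (per-stage parameters, output file hashes, warnings, wall
#' time). Identical configurations and seeds produce identical output hashes.
#' Images whose reference plate cannot be detected (and that have no manual
#' circles) are excluded from color/zoom correction and listed in the
#' manifest with a reason.
#'
#' @param cfg A [run_config()].
#' @return A `run_manifest` list (also written to
#'   `file.path(cfg$out_dir, "manifest.json")`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(cfg), stages = list())
  note <- function(stage, t0, outputs = character(), warnings = character(),
                   extra = list()) {
    manifest$stages[[stage]] <<- c(list(
      elapsed_s = round(as.numeric(Sys.time()) - t0, 2),
      outputs = as.list(hash_files(outputs)),
      warnings = warnings), extra)
  }
  design <- study_design()
  # spread the chamber subset across the design so no factor is constant
  design <- design[unique(round(seq(1, nrow(design),
                                    length.out = cfg$simulate$n_chambers))), ,
                   drop = FALSE]

  scenes <- list(); annotations <- NULL
  if (cfg$stages$simulate) {
    t0 <- as.numeric(Sys.time())
    sim_dir <- file.path(cfg$out_dir, "images")
    dir.create(sim_dir, showWarnings = FALSE)
    paths <- character(0)
    for (ch in design$chamber) {
      spec <- scene_spec(width = cfg$simulate$width,
                         height = cfg$simulate$height,
                         sediment_fraction = cfg$simulate$sediment_fraction,
                         illum_amp = cfg$simulate$illum_amp,
                         noise_sd = cfg$simulate$noise_sd,
                         seed = cfg$seed + 100L * ch,
                         shape_seed = cfg$seed + ch)
      frames <- render_timeseries(spec, cfg$simulate$n_timepoints,
                                  shrink_rate = cfg$simulate$shrink_rate,
                                  hue_drift = cfg$simulate$hue_drift)
      for (t in seq_along(frames)) {
        fr <- frames[[t]]
        id <- sprintf("ch%02d_t%d", ch, t - 1L)
        attr(fr$image, "image_id") <- id
        attr(fr$image, "chamber") <- ch
        attr(fr$image, "timepoint") <- t - 1L
        p <- file.path(sim_dir, paste0(id, ".png"))
        write_image(fr$image, p)
        paths <- c(paths, p)
        ann <- emit_annotations(fr$truth, cfg$simulate$n_points,
                                cfg$simulate$n_frames,
                                seed = cfg$seed + 7L * ch + t,
                                image_id = id)
        annotations <- rbind(annotations, ann)
        scenes[[id]] <- fr
      }
    }
    ann_path <- file.path(cfg$out_dir, "annotations.csv")
    write_annotations(annotations, ann_path)
    note("simulate", t0, c(paths, ann_path))
  }
  images <- lapply(scenes, `[[`, "image")

  detections <- list(); ref <- NULL
  excluded <- character(0)
  if (cfg$stages$preprocess) {
    t0 <- as.numeric(Sys.time())
    warns <- character(0)
    if (cfg$preprocess$illumination) {
      ip <- illumination_params(cfg$preprocess$sigma_factor,
                                cfg$preprocess$tau)
      images <- lapply(images, correct_illumination, params = ip)
    }
    if (cfg$preprocess$detect) {
      spec0 <- scene_spec(width = cfg$simulate$width,
                          height = cfg$simulate$height)
      layout <- plate_layout_from_spec(spec0)
      for (id in names(images)) {
        det <- detect_plate(images[[id]], layout,
                            var_threshold = cfg$preprocess$var_threshold)
        if (det$mode == "failed" &&
            !is.null(cfg$preprocess$manual_circles)) {
          mc <- cfg$preprocess$manual_circles
          mc <- mc[mc$image_id == id, c("x", "y", "r"), drop = FALSE]
          if (nrow(mc) > 0L)
            det <- detect_plate(images[[id]], layout, manual = mc)
        }
        if (det$mode == "failed") {
          excluded <- c(excluded, id)
          warns <- c(warns, sprintf("%s: plate detection failed; excluded",
                                    id))
          next
        }
        detections[[id]] <- det
      }
      images <- images[setdiff(names(images), excluded)]
      if (length(detections) > 0L) {
        ref <- build_reference(detections)
        for (id in names(images)) {
          g <- estimate_gamma(detections[[id]], ref)
          images[[id]] <- apply_gamma(images[[id]], g)
          img2 <- correct_zoom(images[[id]], detections[[id]], ref)
          s <- attr(img2, "zoom_scale")
          d2 <- detections[[id]]
          d2$circles[, c("x", "y", "r")] <- d2$circles[, c("x", "y", "r")] * s
          d2$pair_distances <- d2$pair_distances * s
          detections[[id]] <- d2
          images[[id]] <- img2
        }
      }
    } else {
      warns <- c(warns, paste("plate detection disabled and no manual",
                              "circles: color and zoom correction skipped"))
      warning(warns[length(warns)])
    }
    pre_dir <- file.path(cfg$out_dir, "corrected")
    dir.create(pre_dir, showWarnings = FALSE)
    paths <- vapply(names(images), function(id) {
      write_image(images[[id]], file.path(pre_dir, paste0(id, ".png")))
    }, character(1))
    note("preprocess", t0, paths, warns,
         list(excluded = as.list(excluded)))
  }

  model <- NULL
  if (cfg$stages$train) {
    t0 <- as.numeric(Sys.time())
    ts <- build_training_set(images, annotations,
                             image_fraction = cfg$features$image_fraction,
                             pixel_fraction = cfg$features$pixel_fraction,
                             stride = cfg$features$stride,
                             seed = cfg$seed + 1L)
    model <- h2som(ts$X, rings = cfg$h2som$rings,
                   branching = cfg$h2som$branching,
                   iter_mult = cfg$h2som$iter_mult, seed = cfg$seed + 2L)
    mp <- file.path(cfg$out_dir, "h2som.json")
    write_h2som(model, mp)
    note("train", t0, mp, extra = list(n_features = nrow(ts$X)))
  }

  lm_fit <- NULL
  if (cfg$stages$labelmap) {
    t0 <- as.numeric(Sys.time())
    ts_all <- build_training_set(images, annotations, image_fraction = 1,
                                 pixel_fraction = cfg$features$pixel_fraction,
                                 stride = cfg$features$stride,
                                 seed = cfg$seed + 3L)
    lm_fit <- fit_label_model(model, ts_all,
                              coverage_target = cfg$labelmap$coverage_target)
    lp <- file.path(cfg$out_dir, "labelmodel.json")
    jsonlite::write_json(list(selected = lm_fit$selected, L = lm_fit$L,
                              s = lm_fit$s, coverage = lm_fit$coverage),
                         lp, auto_unbox = TRUE, digits = NA)
    note("labelmap", t0, lp, extra = list(L = lm_fit$L))
  }

  masks <- list()
  if (cfg$stages$segment) {
    t0 <- as.numeric(Sys.time())
    mask_dir <- file.path(cfg$out_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    paths <- character(0)
    metrics <- NULL
    for (id in names(images)) {
      mk <- classify_image(images[[id]], model, lm_fit,
                           stride = cfg$features$stride)
      mk <- open_mask(mk, cfg$segment$opening)
      masks[[id]] <- mk
      p <- file.path(mask_dir, paste0(id, ".png"))
      png::writePNG(mk, p)
      paths <- c(paths, p)
      metrics <- rbind(metrics,
                       cbind(image_id = id,
                             evaluate_segmentation(mk, annotations, id)))
    }
    met_path <- file.path(cfg$out_dir, "segmentation_metrics.csv")
    utils::write.csv(metrics, met_path, row.names = FALSE)
    note("segment", t0, c(paths, met_path))
  }

  series <- NULL
  if (cfg$stages$quantify) {
    t0 <- as.numeric(Sys.time())
    recs <- do.call(rbind, lapply(names(images), function(id) {
      det <- detections[[id]]
      rf <- ref
      if (is.null(det)) {
        det <- structure(list(pair_distances = NA_real_),
                         class = "plate_detection")
        rf <- structure(list(mean_pair_distance = NA_real_),
                        class = "color_reference")
      }
      measure_sample(images[[id]], masks[[id]], det, rf)
    }))
    recs <- relative_size(recs)
    mp <- file.path(cfg$out_dir, "measurements.csv")
    utils::write.csv(recs, mp, row.names = FALSE)
    series <- aggregate_chambers(recs, design)
    sp <- file.path(cfg$out_dir, "chamber_series.csv")
    utils::write.csv(series, sp, row.names = FALSE)
    note("quantify", t0, c(mp, sp))
  }

  if (cfg$stages$regress) {
    t0 <- as.numeric(Sys.time())
    responses <- intersect(cfg$pls$responses, names(series))
    dm <- assemble_design_matrix(series, responses = responses,
                                 add_square = cfg$pls$add_square)
    dm <- remove_outliers(dm)
    fit <- fit_pls(dm, ncomp = cfg$pls$ncomp, cv = cfg$pls$cv)
    r2_path <- file.path(cfg$out_dir, "pls_r2.csv")
    utils::write.csv(data.frame(response = names(fit$R2_fit),
                                fit = fit$R2_fit, pred = fit$R2_pred),
                     r2_path, row.names = FALSE)
    cl_path <- file.path(cfg$out_dir, "correlation_loadings.csv")
    utils::write.csv(data.frame(variable = rownames(fit$correlation_loadings),
                                fit$correlation_loadings),
                     cl_path, row.names = FALSE)
    note("regress", t0, c(r2_path, cl_path),
         extra = list(dropped = length(dm$dropped)))
  }

  manifest$excluded <- excluded
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest: %d stage(s), %d image(s) excluded>\n",
              length(x$stages), length(x$excluded)))
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %6.2fs  %d output(s)\n", nm,
                x$stages[[nm]]$elapsed_s, length(x$stages[[nm]]$outputs)))
  invisible(x)
}
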