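#' Face-centred central composite (CCF) design with replicates
#'
#' Generates the 15 distinct points of a 3-factor face-centred central
#' composite design -- 8 factorial corners, 6 face centres and 1 centre point
#' -- at the given low/mid/high levels, then expands named points into
#' technical replicates. The default levels and replicate pattern reproduce
#' the 21-chamber exposure study layout: light 3/6.6/10 umol m-2 s-1, flow
#' 0.04/0.07/0.09 m s-1, sediment 600/900/1200 g; the low-light face centre
#' and the centre point duplicated, the low-flow and high-flow face centres
#' triplicated.
#'
#' @param levels Named list of three numeric `c(low, mid, high)` vectors (in
#'   order: the factor columns of the output).
#' @param replicates Named integer vector: number of runs for specific design
#'   points (by point name); points not named run once. `NULL` gives the 15
#'   distinct points.
#' @return Data frame with `chamber`, one column per factor, and `point` (the
#'   design-point name, e.g. `"c+-+"` or `"f1-"` for the low face of factor
#'   1, `"0"` for the centre).
#' @export
make_ccf_design <- function(levels = list(L = c(3, 6.6, 10),
                                          F = c(0.04, 0.07, 0.09),
                                          S = c(600, 900, 1200)),
                            replicates = c("f1-" = 2, "f2-" = 3,
                                           "f2+" = 3, "0" = 2)) {
  stopifnot(length(levels) == 3L,
            all(vapply(levels, function(l)
              length(l) == 3 && l[1] < l[2] && l[2] < l[3], logical(1))))
  fn <- names(levels)
  lo <- vapply(levels, `[`, numeric(1), 1)
  mid <- vapply(levels, `[`, numeric(1), 2)
  hi <- vapply(levels, `[`, numeric(1), 3)
  lev <- function(code) ifelse(code < 0, lo, ifelse(code > 0, hi, mid))
  # corners in the study's chamber order, then face centres, then the centre
  corners <- rbind(c(-1, -1, -1), c(1, 1, -1), c(-1, 1, -1), c(1, -1, -1),
                   c(-1, -1, 1), c(1, -1, 1), c(-1, 1, 1), c(1, 1, 1))
  faces <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                 c(0, 0, -1), c(0, 0, 1))
  codes <- rbind(corners, faces, c(0, 0, 0))
  name_of <- function(cd) {
    if (all(cd == 0)) return("0")
    if (all(cd != 0))
      return(paste0("c", paste(ifelse(cd > 0, "+", "-"), collapse = "")))
    k <- which(cd != 0)
    paste0("f", k, if (cd[k] > 0) "+" else "-")
  }
  pts <- data.frame(point = apply(codes, 1, name_of))
  for (j in 1:3) pts[[fn[j]]] <- vapply(seq_len(nrow(codes)), function(i)
    lev(codes[i, ])[j], numeric(1))
  # study ordering: corners, then faces of factor 1, factor 2, factor 3,
  # centre; replicates expand in place
  order_names <- c(pts$point[1:8], "f1-", "f1+", "f2-", "f2+", "f3-", "f3+",
                   "0")
  reps <- if (is.null(replicates)) integer(0) else replicates
  rows <- list()
  for (nm in order_names) {
    k <- if (nm %in% names(reps)) reps[[nm]] else 1L
    p <- pts[pts$point == nm, , drop = FALSE]
    for (i in seq_len(k)) rows[[length(rows) + 1L]] <- p
  }
  out <- do.call(rbind, rows)
  out <- cbind(chamber = seq_len(nrow(out)), out[, c(fn, "point")])
  rownames(out) <- NULL
  out
}

#' The 21-chamber study design
#'
#' [make_ccf_design()] at the study's levels and replicate pattern.
#'
#' @return Data frame with 21 rows: `chamber`, `L`, `F`, `S`, `point`.
#' @export
study_design <- function() make_ccf_design()

#' Simulate chamber-series measurements with the study's correlation structure
#'
#' Generates per-chamber, per-timepoint responses in which sediment amount S
#' drives sediment coverage (up), photosynthetic efficiency (down) and the
#' HSV color variables, while time T drives relative size down; light and
#' flow are inert. This is the minimal data-generating process consistent
#' with the observed loading geometry (S/SC/P/HSV on one latent direction,
#' T/A_hat on an orthogonal one) and is used to exercise the PLS machinery
#' without rendering images.
#'
#' @param design Chamber design table ([study_design()]).
#' @param timepoints Integer vector of retained time points (default 2..9).
#' @param seed RNG seed.
#' @param noise_sd Named noise levels for the six responses (0 gives exact
#'   linear responses).
#' @param n_fail Number of chamber x timepoint cells simulated as failed
#'   segmentations (zero live area: `A_hat` and colors set `NA`).
#' @return Chamber-series data frame: `chamber`, `timepoint`, `L`, `F`, `S`,
#'   `A_hat`, `h_bar`, `s_bar`, `v_bar`, `P`, `SC`.
#' @export
simulate_chamber_series <- function(design, timepoints = 2:9, seed = 1L,
                                    noise_sd = c(A_hat = 0.08, h_bar = 1.2,
                                                 s_bar = 0.03, v_bar = 0.04,
                                                 P = 0.05, SC = 0.08),
                                    n_fail = 0L) {
  set.seed(seed)
  grid <- expand.grid(timepoint = timepoints, chamber = design$chamber)
  df <- merge(grid, design[, c("chamber", "L", "F", "S")], by = "chamber")
  df <- df[order(df$chamber, df$timepoint), ]
  sn <- (df$S - 900) / 300                       # -1, 0, 1
  tn <- (df$timepoint - min(timepoints)) /
    max(1, diff(range(timepoints)))              # 0..1
  n <- nrow(df)
  e <- function(nm) stats::rnorm(n, 0, noise_sd[[nm]])
  df$A_hat <- pmax(0.05, 1 - 0.35 * tn + e("A_hat"))
  df$h_bar <- 6 - 3.5 * sn + e("h_bar")          # hue near 0..10 degrees,
                                                 # kept unwrapped for PLS
  df$s_bar <- pmin(1, pmax(0, 0.45 - 0.12 * sn + e("s_bar")))
  df$v_bar <- pmin(1, pmax(0, 0.55 + 0.15 * sn + e("v_bar")))
  df$P <- pmin(1, pmax(0, 0.55 - 0.22 * sn + e("P")))
  df$SC <- pmin(1, pmax(0, 0.5 + 0.4 * sn + e("SC")))
  if (n_fail > 0L) {
    fail <- sample.int(n, n_fail)
    df$A_hat[fail] <- NA_real_
    df$h_bar[fail] <- NA_real_
    df$s_bar[fail] <- NA_real_
    df$v_bar[fail] <- NA_real_
  }
  rownames(df) <- NULL
  df[, c("chamber", "timepoint", "L", "F", "S", "A_hat", "h_bar", "s_bar",
         "v_bar", "P", "SC")]
}
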