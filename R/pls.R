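#' Assemble the predictor/response matrices for PLS
#'
#' Builds X from the design factors plus time (and an optional squared term,
#' by default S^2, supporting the quadratic response-surface structure of the
#' CCF design) and Y from the measured responses, then mean-centres and
#' scales every column to unit variance, recording the scaling for
#' back-transformation.
#'
#' @param series Chamber-series data frame ([aggregate_chambers()] or
#'   [simulate_chamber_series()]).
#' @param predictors Predictor column names (default L, F, S, T where T is
#'   the `timepoint` column).
#' @param responses Response column names present in `series`.
#' @param add_square Name of one predictor to expand with a squared term, or
#'   `NULL`.
#' @return A `design_matrix`: raw and scaled X and Y, the centring/scaling
#'   vectors, and the `chamber` ids per row.
#' @export
assemble_design_matrix <- function(series,
                                   predictors = c("L", "F", "S", "T"),
                                   responses = c("A_hat", "h_bar", "s_bar",
                                                 "v_bar", "P", "SC"),
                                   add_square = "S") {
  df <- series
  if (!"T" %in% names(df) && "timepoint" %in% names(df)) df$T <- df$timepoint
  missing_cols <- setdiff(c(predictors, responses), names(df))
  if (length(missing_cols))
    stop("series lacks columns: ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(df[, predictors, drop = FALSE])
  if (!is.null(add_square)) {
    if (!add_square %in% predictors) stop("add_square must be a predictor")
    X <- cbind(X, stats::setNames(data.frame(X[, add_square]^2),
                                  paste0(add_square, "2"))[[1]])
    colnames(X)[ncol(X)] <- paste0(add_square, "2")
  }
  Y <- as.matrix(df[, responses, drop = FALSE])
  dm <- list(X = X, Y = Y,
             chamber = df$chamber %||% rep(1L, nrow(X)),
             timepoint = df$timepoint %||% seq_len(nrow(X)))
  dm <- rescale_dm(dm)
  class(dm) <- "design_matrix"
  dm
}

rescale_dm <- function(dm) {
  # scaling tolerates missing cells (failed segmentations); they are dropped
  # by remove_outliers() before any model is fitted
  sc <- function(M) {
    mu <- colMeans(M, na.rm = TRUE)
    sd <- apply(M, 2, stats::sd, na.rm = TRUE)
    if (any(!is.finite(sd)) || any(sd == 0)) {
      bad <- colnames(M)[!is.finite(sd) | sd == 0]
      stop("constant or degenerate column(s): ", paste(bad, collapse = ", "))
    }
    list(Z = sweep(sweep(M, 2, mu), 2, sd, "/"), mu = mu, sd = sd)
  }
  x <- sc(dm$X); y <- sc(dm$Y)
  dm$Xs <- x$Z; dm$Ys <- y$Z
  dm$x_center <- x$mu; dm$x_scale <- x$sd
  dm$y_center <- y$mu; dm$y_scale <- y$sd
  dm
}

#' Drop observations with failed segmentations
#'
#' Removes rows whose underlying segmentation produced no live pixels (zero
#' size: missing `A_hat` or color fields) or that carry any missing response,
#' then re-centres and re-scales the remaining rows. This is the study's
#' outlier rule: a cell where no live algae were detected is a segmentation
#' failure, not a measurement of zero.
#'
#' @param dm A `design_matrix`.
#' @return The reduced, re-scaled `design_matrix`; the dropped row indices
#'   are recorded in `$dropped`.
#' @export
remove_outliers <- function(dm) {
  stopifnot(inherits(dm, "design_matrix"))
  bad <- which(!stats::complete.cases(dm$Y) | !stats::complete.cases(dm$X))
  if (length(bad) == 0L) { dm$dropped <- integer(0); return(dm) }
  dm$X <- dm$X[-bad, , drop = FALSE]
  dm$Y <- dm$Y[-bad, , drop = FALSE]
  dm$chamber <- dm$chamber[-bad]
  dm$timepoint <- dm$timepoint[-bad]
  dm <- rescale_dm(dm)
  dm$dropped <- bad
  class(dm) <- "design_matrix"
  dm
}

# NIPALS PLS2 on already-scaled matrices. Returns weights W, X-loadings P,
# Y-loadings Q, scores Tm, and the coefficient matrix B for scaled data.
nipals_pls <- function(Xs, Ys, ncomp, tol = 1e-10, max_iter = 500L) {
  n <- nrow(Xs); px <- ncol(Xs); py <- ncol(Ys)
  W <- matrix(0, px, ncomp); P <- matrix(0, px, ncomp)
  Q <- matrix(0, py, ncomp); Tm <- matrix(0, n, ncomp)
  Xd <- Xs; Yd <- Ys
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt)[, 1] / sum(tt^2)
      u <- (Yd %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      if (it == max_iter)
        stop(sprintf("NIPALS failed to converge for component %d", a))
      t_old <- tt
    }
    p <- crossprod(Xd, tt)[, 1] / sum(tt^2)
    W[, a] <- w; P[, a] <- p; Q[, a] <- q; Tm[, a] <- tt
    Xd <- Xd - tcrossprod(tt, p)
    Yd <- Yd - tcrossprod(tt, q)
  }
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)
  list(W = W, P = P, Q = Q, T = Tm, B = B)
}

#' Fit a cross-validated PLS2 regression
#'
#' Iterative (NIPALS) partial least squares with deflation, on mean-centred,
#' unit-variance data. Goodness of fit `R2_fit` is computed per response from
#' the fitted values with all `ncomp` components; goodness of prediction
#' `R2_pred` from out-of-fold predictions under the chosen cross-validation
#' scheme (default: leave one chamber out, so technical replicates never
#' straddle folds; each training fold is re-centred and re-scaled).
#' Correlation loadings are the Pearson correlations of every scaled X and Y
#' variable with each component's scores.
#'
#' @param dm A `design_matrix`.
#' @param ncomp Number of latent components (default 2).
#' @param cv `"chamber"`, `"kfold"` or `"none"`.
#' @param k Number of folds for `cv = "kfold"`.
#' @param seed Seed for random fold assignment.
#' @return A `pls_fit` with scores, loadings, weights, per-response `R2_fit`
#'   and `R2_pred`, `correlation_loadings`, and the explained X-variance per
#'   component.
#' @export
fit_pls <- function(dm, ncomp = 2L, cv = c("chamber", "kfold", "none"),
                    k = 7L, seed = 1L) {
  stopifnot(inherits(dm, "design_matrix"))
  cv <- match.arg(cv)
  n <- nrow(dm$Xs)
  if (n <= ncomp) stop("need more rows than components")
  if (anyNA(dm$Xs) || anyNA(dm$Ys))
    stop("design matrix contains missing cells; run remove_outliers() first")
  fit <- nipals_pls(dm$Xs, dm$Ys, ncomp)
  Yhat <- fit$T %*% t(fit$Q)
  ss_tot <- colSums(dm$Ys^2)
  r2_fit <- 1 - colSums((dm$Ys - Yhat)^2) / ss_tot
  xvar <- vapply(seq_len(ncomp), function(a)
    sum(tcrossprod(fit$T[, a], fit$P[, a])^2), numeric(1)) / sum(dm$Xs^2)

  r2_pred <- rep(NA_real_, ncol(dm$Ys))
  if (cv != "none") {
    folds <- if (cv == "chamber") {
      split(seq_len(n), dm$chamber)
    } else {
      set.seed(seed)
      split(seq_len(n), sample(rep_len(seq_len(k), n)))
    }
    press <- rep(0, ncol(dm$Y))
    sstot <- rep(0, ncol(dm$Y))
    ybar_all <- colMeans(dm$Y)
    for (f in folds) {
      Xtr <- dm$X[-f, , drop = FALSE]; Ytr <- dm$Y[-f, , drop = FALSE]
      mu_x <- colMeans(Xtr); sd_x <- apply(Xtr, 2, stats::sd)
      mu_y <- colMeans(Ytr); sd_y <- apply(Ytr, 2, stats::sd)
      if (any(sd_x == 0) || any(sd_y == 0)) next
      Zx <- sweep(sweep(Xtr, 2, mu_x), 2, sd_x, "/")
      Zy <- sweep(sweep(Ytr, 2, mu_y), 2, sd_y, "/")
      fold_fit <- nipals_pls(Zx, Zy, ncomp)
      Zt <- sweep(sweep(dm$X[f, , drop = FALSE], 2, mu_x), 2, sd_x, "/")
      pred <- sweep(sweep(Zt %*% fold_fit$B, 2, sd_y, "*"), 2, mu_y, "+")
      press <- press + colSums((dm$Y[f, , drop = FALSE] - pred)^2)
      sstot <- sstot +
        colSums(sweep(dm$Y[f, , drop = FALSE], 2, ybar_all)^2)
    }
    r2_pred <- 1 - press / sstot
  }

  cl <- rbind(stats::cor(dm$Xs, fit$T), stats::cor(dm$Ys, fit$T))
  rownames(cl) <- c(colnames(dm$X), colnames(dm$Y))
  colnames(cl) <- paste0("comp", seq_len(ncomp))
  structure(list(ncomp = ncomp, weights = fit$W, x_loadings = fit$P,
                 y_loadings = fit$Q, scores = fit$T, coefficients = fit$B,
                 R2_fit = stats::setNames(r2_fit, colnames(dm$Y)),
                 R2_pred = stats::setNames(r2_pred, colnames(dm$Y)),
                 x_variance = xvar,
                 correlation_loadings = cl,
                 dm = dm, cv = cv),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit: %d component(s), %d obs, CV = %s>\n",
              x$ncomp, nrow(x$scores), x$cv))
  tab <- rbind(fit = round(x$R2_fit, 2), pred = round(x$R2_pred, 2))
  print(tab)
  invisible(x)
}

#' @export
summary.pls_fit <- function(object, ...) {
  cat(sprintf("PLS2 regression, %d components, %d observations\n",
              object$ncomp, nrow(object$scores)))
  cat(sprintf("X variance explained per component: %s\n",
              paste(sprintf("%.1f%%", 100 * object$x_variance),
                    collapse = ", ")))
  cat("\nGoodness of fit / prediction (R2):\n")
  print(round(rbind(fit = object$R2_fit, pred = object$R2_pred), 3))
  invisible(object)
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  dm <- object$dm
  X <- as.matrix(newdata)[, colnames(dm$X), drop = FALSE]
  Z <- sweep(sweep(X, 2, dm$x_center), 2, dm$x_scale, "/")
  sweep(sweep(Z %*% object$coefficients, 2, dm$y_scale, "*"),
        2, dm$y_center, "+")
}

#' Correlation loading plot
#'
#' Plots every predictor (circles) and response (filled dots) at its Pearson
#' correlation with the first two latent components, with circles at 50% and
#' 100% explained variance: a variable on the outer circle is fully described
#' by the two components.
#'
#' @param x A `pls_fit`.
#' @param comps Which two components to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pls_fit <- function(x, comps = c(1L, 2L), ...) {
  cl <- x$correlation_loadings[, comps, drop = FALSE]
  px <- ncol(x$dm$X)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 xlab = sprintf("Component %d", comps[1]),
                 ylab = sprintf("Component %d", comps[2]), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey50")
  graphics::lines(sqrt(0.5) * cos(th), sqrt(0.5) * sin(th), col = "grey75",
                  lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey85")
  graphics::points(cl[seq_len(px), 1], cl[seq_len(px), 2], pch = 1,
                   col = "blue")
  graphics::points(cl[-seq_len(px), 1], cl[-seq_len(px), 2], pch = 16,
                   col = "red")
  graphics::text(cl[, 1], cl[, 2], rownames(cl), pos = 3, cex = 0.8)
  invisible(x)
}

#' PLS of photosynthetic efficiency on HSV color
#'
#' Alternative regression predicting P from the three measured color
#' variables only (linear terms, no square expansion).
#'
#' @param series Chamber-series data frame with `h_bar`, `s_bar`, `v_bar`,
#'   `P`.
#' @param ncomp Components (default 2).
#' @param cv Cross-validation scheme, as in [fit_pls()].
#' @return A `pls_fit`.
#' @export
fit_hsv_to_p <- function(series, ncomp = 2L, cv = "chamber") {
  keep <- stats::complete.cases(series[, c("h_bar", "s_bar", "v_bar", "P")])
  df <- series[keep, , drop = FALSE]
  X <- as.matrix(df[, c("h_bar", "s_bar", "v_bar")])
  Y <- as.matrix(df[, "P", drop = FALSE])
  dm <- list(X = X, Y = Y, chamber = df$chamber %||% seq_len(nrow(X)),
             timepoint = df$timepoint %||% seq_len(nrow(X)))
  dm <- rescale_dm(dm)
  class(dm) <- "design_matrix"
  fit_pls(dm, ncomp = ncomp, cv = cv)
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()], reporting slope,
#' intercept and R2 (the squared Pearson correlation).
#'
#' @param y,x Numeric vectors (>= 3 finite pairs).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
fit_linear <- function(y, x) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  m <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(m)[2]),
       intercept = unname(stats::coef(m)[1]),
       r_squared = summary(m)$r.squared)
}
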