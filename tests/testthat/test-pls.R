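test_that("design matrices are scaled to zero mean, unit variance, with the square term", {
  ser <- simulate_chamber_series(study_design(), 2:9, seed = 3L)
  dm <- assemble_design_matrix(ser)
  expect_equal(nrow(dm$X), 168L)
  expect_equal(colnames(dm$X), c("L", "F", "S", "T", "S2"))
  expect_equal(dm$X[, "S2"], dm$X[, "S"]^2)
  expect_lt(max(abs(colMeans(dm$Xs))), 1e-9)
  expect_lt(max(abs(colMeans(dm$Ys))), 1e-9)
  expect_equal(unname(apply(dm$Xs, 2, sd)), rep(1, 5))
  expect_equal(unname(apply(dm$Ys, 2, sd)), rep(1, 6))

  const <- ser; const$P <- 1
  expect_error(assemble_design_matrix(const), "P")
})

test_that("the outlier rule drops exactly the failed-segmentation rows", {
  ser <- simulate_chamber_series(study_design(), 2:9, seed = 4L)
  dm <- remove_outliers(assemble_design_matrix(ser))
  expect_equal(nrow(dm$X), 168L)
  expect_length(dm$dropped, 0L)

  ser1 <- simulate_chamber_series(study_design(), 2:9, seed = 4L, n_fail = 1L)
  dm1 <- remove_outliers(assemble_design_matrix(ser1))
  expect_equal(nrow(dm1$X), 167L)
  expect_lt(max(abs(colMeans(dm1$Ys))), 1e-9)

  ser3 <- simulate_chamber_series(study_design(), 2:9, seed = 4L, n_fail = 3L)
  expect_equal(nrow(remove_outliers(assemble_design_matrix(ser3))$X), 165L)
})

test_that("noiseless linear responses are fit exactly with enough components", {
  ser <- simulate_chamber_series(study_design(), 2:9, seed = 6L,
                                 noise_sd = c(A_hat = 0, h_bar = 0,
                                              s_bar = 0, v_bar = 0,
                                              P = 0, SC = 0))
  dm <- assemble_design_matrix(ser, add_square = NULL)
  fit <- fit_pls(dm, ncomp = 4L, cv = "none")
  expect_true(all(fit$R2_fit >= 0.999))
})

test_that("PLS scores are orthogonal and correlation loadings live in the unit disk", {
  ser <- simulate_chamber_series(study_design(), 2:9, seed = 7L)
  fit <- fit_pls(assemble_design_matrix(ser), ncomp = 2L)
  g <- crossprod(fit$scores)
  expect_lt(abs(g[1, 2]) / sqrt(g[1, 1] * g[2, 2]), 1e-8)
  expect_true(all(abs(fit$correlation_loadings) <= 1 + 1e-9))
  expect_true(all(fit$x_variance >= 0) && sum(fit$x_variance) <= 1 + 1e-9)
  expect_true(all(fit$R2_fit >= fit$R2_pred - 0.05))
  # a response fully explained by two components sits on the outer circle
  r2c <- rowSums(fit$correlation_loadings^2)
  expect_true(all(r2c <= 1 + 1e-9))
})

test_that("the fitted loading geometry separates the sediment and time directions", {
  ser <- simulate_chamber_series(study_design(), 2:9, seed = 8L)
  fit <- fit_pls(assemble_design_matrix(ser), ncomp = 2L)
  cl <- fit$correlation_loadings
  grp1 <- c("S", "S2", "h_bar", "s_bar", "v_bar", "P", "SC")
  grp2 <- c("T", "A_hat")
  expect_true(all(abs(cl[grp1, 1]) > 0.7))
  expect_true(all(abs(cl[grp1, 2]) < 0.3))
  expect_true(all(abs(cl[grp2, 2]) > 0.7))
  expect_true(all(abs(cl[grp2, 1]) < 0.3))
  expect_true(all(abs(cl[c("L", "F"), 1:2]) < 0.3))
})

test_that("cross-validated R2 stays near zero for unrelated responses", {
  set.seed(15)
  r2p <- replicate(50, {
    ser <- simulate_chamber_series(study_design(), 2:9,
                                   seed = sample.int(1e6, 1))
    ser$P <- rnorm(nrow(ser))   # response unrelated to the predictors
    fit <- fit_pls(assemble_design_matrix(ser, responses = "P"), ncomp = 2L)
    fit$R2_pred[["P"]]
  })
  expect_lte(mean(r2p), 0.1)
})

test_that("HSV-to-photosynthesis regression recovers known signal strengths", {
  des <- study_design()
  # noiseless linear combination: essentially perfect fit
  ser <- simulate_chamber_series(des, 2:9, seed = 9L)
  ser$P <- 0.2 + 0.01 * ser$h_bar + 0.5 * ser$s_bar - 0.3 * ser$v_bar
  f0 <- fit_hsv_to_p(ser, ncomp = 3L)
  expect_gte(f0$R2_fit[["P"]], 0.999)

  # SNR set so the population R2 is 0.8: mean fitted R2 within 0.05
  set.seed(16)
  r2 <- replicate(100, {
    s <- simulate_chamber_series(des, 2:9, seed = sample.int(1e6, 1))
    z <- scale(0.01 * s$h_bar + 0.5 * s$s_bar - 0.3 * s$v_bar)[, 1]
    s$P <- z + rnorm(nrow(s), 0, sqrt(1 / 0.8 - 1))
    fit_hsv_to_p(s, ncomp = 3L, cv = "none")$R2_fit[["P"]]
  })
  expect_lt(abs(mean(r2) - 0.8), 0.05)

  # P independent of HSV: predictive R2 near zero
  set.seed(17)
  r2p <- replicate(50, {
    s <- simulate_chamber_series(des, 2:9, seed = sample.int(1e6, 1))
    s$P <- rnorm(nrow(s))
    fit_hsv_to_p(s, ncomp = 2L)$R2_pred[["P"]]
  })
  expect_lte(mean(r2p), 0.1)
})

test_that("simple linear regression matches closed forms and simulated SNR", {
  x <- seq_len(20)
  # lm warns about an "essentially perfect fit" on exact data; that is the point
  f <- suppressWarnings(fit_linear(2 * x + 1, x))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  set.seed(12)
  y_orth <- stats::residuals(lm(rnorm(20) ~ x))  # orthogonal to x by construction
  expect_lt(fit_linear(y_orth, x)$r_squared, 1e-20)

  expect_error(fit_linear(1:10, rep(1, 10)), "variance")
  expect_error(fit_linear(1:2, 1:2), "3 points")

  # population R2 = 0.4 at n = 168: the fitted R2 lands in [0.3, 0.5] with
  # probability 0.912 (40k-rep oracle; Fisher-z gives the same value), so a
  # 200-rep draw should sit within 3 binomial SE of that
  set.seed(18)
  hits <- replicate(200, {
    x <- rnorm(168)
    y <- x + rnorm(168, 0, sqrt(1 / 0.4 - 1))
    r2 <- fit_linear(y, x)$r_squared
    r2 >= 0.3 && r2 <= 0.5
  })
  expect_lt(abs(mean(hits) - 0.912), 0.06)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  ser <- simulate_chamber_series(study_design(), 2:9, seed = 19L)
  dm <- assemble_design_matrix(ser)
  fit <- fit_pls(dm, ncomp = 2L, cv = "none")
  mo <- mixOmics::pls(dm$X, dm$Y, ncomp = 2, mode = "regression",
                      scale = TRUE)
  for (a in 1:2) {
    expect_gt(abs(cor(fit$scores[, a], mo$variates$X[, a])), 0.999)
  }
  # fitted-variance agreement per response
  pred_mo <- predict(mo, dm$X)$predict[, , 2]
  r2_mo <- 1 - colSums((dm$Y - pred_mo)^2) /
    colSums(sweep(dm$Y, 2, colMeans(dm$Y))^2)
  expect_equal(unname(fit$R2_fit), unname(r2_mo), tolerance = 1e-6)
})
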