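# A fake trained model whose prototypes are chosen directly lets the label
# mapping be exercised against hand-countable feature->prototype assignments.
fake_model <- function(P) structure(list(prototypes = P, trained = TRUE),
                                    class = "h2som")

test_that("label mapping selects the minimal prototype prefix for the coverage rule", {
  P <- matrix(c(0, 0, 0,
                100, 0, 0,
                0, 100, 0,
                0, 0, 100), 4, byrow = TRUE)
  m <- fake_model(P)

  # all positives on one prototype
  X <- P[c(1, 2, 2, 2), ]
  y <- c(0, 1, 1, 1)
  lm1 <- fit_label_model(m, X, y)
  expect_equal(lm1$selected, 2L)
  expect_equal(lm1$L, 1L)

  # positives split 60/25/15 across three prototypes, target 0.8 -> L = 2
  X <- P[c(rep(2, 60), rep(3, 25), rep(4, 15)), ]
  y <- rep(1, 100)
  lm2 <- fit_label_model(m, X, y, coverage_target = 0.8)
  expect_equal(lm2$L, 2L)
  expect_setequal(lm2$selected, c(2L, 3L))

  expect_error(fit_label_model(m, P, c(0, 0, 0, 0)), "positive")
})

test_that("selected prefixes are minimal over random count distributions (exhaustive check)", {
  set.seed(101)
  for (rep in 1:30) {
    k <- sample(5:30, 1)
    P <- matrix(runif(k * 3, 0, 255), k)
    while (min(dist(P)) < 5) P <- matrix(runif(k * 3, 0, 255), k)
    m <- fake_model(P)
    q <- sample(1:40, k, replace = TRUE)
    qp <- vapply(q, function(n) sample(0:n, 1), integer(1))
    if (sum(qp) == 0L) qp[1] <- 1L
    X <- P[rep(seq_len(k), q), , drop = FALSE]
    y <- unlist(lapply(seq_len(k), function(j) {
      c(rep(1L, qp[j]), rep(0L, q[j] - qp[j]))
    }))
    lmod <- fit_label_model(m, X, y, coverage_target = 0.8)
    covered <- sum(qp[lmod$selected])
    expect_gte(covered, 0.8 * sum(qp))
    if (lmod$L > 1L) {
      expect_lt(sum(qp[lmod$selected[-lmod$L]]), 0.8 * sum(qp))
    }
    # ranking respects s with the documented tie-breaks
    s <- ifelse(q > 0, qp / q, 0)
    expect_true(all(diff(s[lmod$ranking]) <= 1e-12))
  }
})

test_that("classification follows the selected prototype set", {
  P <- matrix(c(200, 40, 40,
                40, 200, 40,
                40, 40, 200), 3, byrow = TRUE)
  m <- fake_model(P)
  lmod <- fit_label_model(m, P[c(1, 1, 2), ], c(1, 1, 0))
  expect_equal(lmod$selected, 1L)

  img_pos <- raster_image(array(rep(c(200, 40, 40), each = 400), c(20, 20, 3)))
  mk <- classify_image(img_pos, m, lmod, stride = 2L)
  expect_true(all(mk == 1))
  expect_equal(dim(mk), c(20L, 20L))

  img_neg <- raster_image(array(rep(c(40, 40, 200), each = 400), c(20, 20, 3)))
  expect_true(all(classify_image(img_neg, m, lmod, stride = 2L) == 0))
})

test_that("opening matches the definition oracle and removes sub-element structure", {
  # isolated 5x5 blob is erased by a 10x10 element
  mk <- matrix(0, 40, 40); mk[10:14, 10:14] <- 1
  expect_equal(sum(open_mask(mk, 10L)), 0)

  # solid 50x50 square is untouched
  big <- matrix(0, 70, 70); big[11:60, 11:60] <- 1
  expect_equal(open_mask(big, 10L)[11:60, 11:60], big[11:60, 11:60])
  expect_equal(sum(open_mask(big, 10L)), 2500)

  # two 20x20 squares joined by a 3 px bridge: bridge removed, squares kept
  bridged <- matrix(0, 50, 60)
  bridged[16:35, 6:25] <- 1
  bridged[16:35, 36:55] <- 1
  bridged[25:27, 26:35] <- 1
  opened <- open_mask(bridged, 10L)
  expect_equal(opened, naive_open(bridged, 10L), ignore_attr = TRUE)
  expect_equal(sum(opened), 800)           # both squares, no bridge
  expect_true(all(opened[25:27, 30] == 0)) # bridge centre gone

  # random masks: oracle equality, anti-extensivity, idempotence
  set.seed(61)
  for (rep in 1:5) {
    m0 <- matrix(rbinom(45 * 35, 1, 0.55), 45, 35)
    for (k in c(3L, 4L)) {
      op <- open_mask(m0, k)
      expect_equal(op, naive_open(m0, k), ignore_attr = TRUE)
      expect_true(all(op <= m0))
      expect_equal(open_mask(op, k), op, ignore_attr = TRUE)
    }
  }
})

test_that("segmentation metrics count labelled pixels with missing-safe denominators", {
  mk <- matrix(0, 30, 30)
  ann <- data.frame(image_id = "z",
                    shape = c("rect", "rect"),
                    x = c(2L, 20L), y = c(2L, 20L),
                    w = c(5L, 10L), h = c(2L, 10L),
                    label = c("live", "dead"))
  attr(mk, "image_id") <- "z"

  # mask identical to the positive labels: recall 1, FPR 0
  mk1 <- mk; mk1[2:3, 2:6] <- 1
  r <- evaluate_segmentation(mk1, ann, "z")
  expect_equal(r$recall, 1)
  expect_equal(r$fpr_all, 0)
  expect_equal(r$fpr_dead, 0)
  expect_true(is.na(r$fpr_bare))  # no bare labels -> undefined, not 0

  # empty mask: recall 0, precision undefined
  r0 <- evaluate_segmentation(mk, ann, "z")
  expect_equal(r0$recall, 0)
  expect_true(is.na(r0$precision))

  # 10 positive px, 9 segmented; 100 negative px, 2 segmented
  mk2 <- mk; mk2[2:3, 2:6] <- 1; mk2[2, 2] <- 0
  mk2[20, 20:21] <- 1
  r2 <- evaluate_segmentation(mk2, ann, "z")
  expect_equal(r2$recall, 0.9)
  expect_equal(r2$fpr_all, 0.02)
})

test_that("the trained fixture segments live algae with high recall and low FPR", {
  seg <- fx_seg()
  # label-based metrics on one scene agree in direction with ground truth
  ev <- evaluate_segmentation(seg$masks[[1]], seg$anns, "img01")
  expect_gt(ev$recall, 0.8)
  expect_lt(ev$fpr_all, 0.05)
  # opening never added pixels
  raw <- classify_image(seg$imgs[[1]], seg$model, seg$lmod, stride = 2L)
  expect_true(all(seg$masks[[1]] <= raw))
})
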