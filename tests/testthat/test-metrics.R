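test_that("dice and iou match set arithmetic exhaustively on a 2x2x1 grid", {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  masks <- lapply(seq_len(nrow(combos)),
                  function(i) seg_mask(array(unlist(combos[i, ]), c(2, 2, 1)),
                                       c(1, 1, 1)))
  for (a in masks) for (b in masks) {
    expect_identical(dice(a, b), oracle_dice(a, b))
    expect_identical(iou(a, b), oracle_iou(a, b))
    expect_lte(iou(a, b), dice(a, b))
  }
})

test_that("dice/iou basics and the algebraic identity", {
  a <- rand_mask(c(8, 8, 8), seed = 1)
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  d <- array(FALSE, c(2, 2, 2)); d[1] <- TRUE
  e <- array(FALSE, c(2, 2, 2)); e[8] <- TRUE
  expect_equal(dice(seg_mask(d, c(1, 1, 1)), seg_mask(e, c(1, 1, 1))), 0)
  # |A| = |B| = 8 with overlap 4
  A <- array(FALSE, c(4, 4, 1)); A[1:8] <- TRUE
  B <- array(FALSE, c(4, 4, 1)); B[5:12] <- TRUE
  expect_equal(dice(seg_mask(A, c(1, 1, 1)), seg_mask(B, c(1, 1, 1))), 0.5)
  expect_equal(iou(seg_mask(A, c(1, 1, 1)), seg_mask(B, c(1, 1, 1))), 4 / 12)
  set.seed(2)
  for (i in 1:200) {
    a <- rand_mask(c(8, 8, 8), p = runif(1, 0.1, 0.9))
    b <- rand_mask(c(8, 8, 8), p = runif(1, 0.1, 0.9))
    dc <- dice(a, b)
    expect_equal(iou(a, b), dc / (2 - dc), tolerance = 1e-12)
    expect_equal(dc, dice(b, a))
  }
})

test_that("surface distances follow hand geometry on two-voxel fixtures", {
  a <- array(FALSE, c(8, 4, 4)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, c(8, 4, 4)); b[4, 1, 1] <- TRUE
  sd1 <- surface_distances(seg_mask(a, c(1, 1, 1)), seg_mask(b, c(1, 1, 1)))
  expect_equal(sd1$a_to_b, 3)
  expect_equal(sd1$b_to_a, 3)
  expect_equal(asd(seg_mask(a, c(1, 1, 1)), seg_mask(b, c(1, 1, 1))), 3)
  expect_equal(rhd95(seg_mask(a, c(1, 1, 1)), seg_mask(b, c(1, 1, 1))), 3)
  # anisotropic spacing scales the same geometry
  sd2 <- surface_distances(seg_mask(a, c(2, 1, 1)), seg_mask(b, c(2, 1, 1)))
  expect_equal(sd2$a_to_b, 6)
  expect_equal(asd(seg_mask(a, c(2, 1, 1)), seg_mask(b, c(2, 1, 1))), 6)
  # identical masks
  m <- rand_mask(c(6, 6, 6), seed = 3)
  expect_equal(asd(m, m), 0)
  expect_equal(rhd95(m, m), 0)
  expect_error(surface_distances(seg_mask(array(FALSE, c(6, 6, 6)), c(1, 1, 1)),
                                 m), "surface undefined")
})

test_that("the 95th percentile is robust to a single outlier voxel", {
  d <- c(110, 60, 1)
  a <- array(FALSE, d); a[1:100, 1, 1] <- TRUE
  b <- a
  b[1, 51, 1] <- TRUE   # one stray voxel 50 mm off the line
  am <- seg_mask(a, c(1, 1, 1)); bm <- seg_mask(b, c(1, 1, 1))
  sd_ <- surface_distances(bm, am)
  expect_equal(max(sd_$a_to_b), 50)          # exact Hausdorff sees 50 mm
  expect_equal(rhd95(am, bm), 0)             # the robust distance does not
  expect_lt(asd(am, bm), 1)
})

test_that("surface metrics are symmetric, spacing-linear, and rhd95 <= HD", {
  set.seed(4)
  for (i in 1:10) {
    a <- rand_mask(c(7, 7, 7), p = 0.3)
    b <- rand_mask(c(7, 7, 7), p = 0.3)
    if (sum(a$voxels) == 0 || sum(b$voxels) == 0) next
    expect_equal(asd(a, b), asd(b, a), tolerance = 1e-12)
    expect_equal(rhd95(a, b), rhd95(b, a), tolerance = 1e-12)
    expect_equal(asd(a, b, c(2, 2, 2)), 2 * asd(a, b), tolerance = 1e-12)
    sd_ <- surface_distances(a, b)
    hd <- max(max(sd_$a_to_b), max(sd_$b_to_a))
    expect_lte(rhd95(a, b), hd + 1e-12)
    expect_lte(asd(a, b), hd + 1e-12)
  }
})

test_that("one-vs-rest classification scores match hand-computed counts", {
  labs <- rep(c(0L, 1L, 2L), each = 4)
  expect_equal(classification_scores(labs, labs)$balanced_accuracy, rep(1, 3))
  expect_equal(classification_scores(labs, labs)$f1, rep(1, 3))
  # all-wrong binary case
  aw <- classification_scores(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L),
                              classes = 0:1)
  expect_equal(aw$balanced_accuracy, c(0, 0))
  # TP=8 FP=2 FN=2 TN=8 for class 0
  labels <- c(rep(0L, 10), rep(1L, 10))
  preds <- c(rep(0L, 8), rep(1L, 2), rep(0L, 2), rep(1L, 8))
  cs <- classification_scores(preds, labels, classes = 0:1)
  expect_equal(cs$precision[1], 0.8)
  expect_equal(cs$f1[1], 0.8)
  expect_equal(cs$balanced_accuracy[1], 0.8)
  expect_warning(classification_scores(labs, labs, classes = 0:3),
                 "absent")
})

test_that("wilcoxon effect sizes follow |z|/sqrt(N) with inclusive boundaries", {
  x <- c(1, 2, 3, 4, 5, 6)
  r0 <- paired_wilcoxon_effect(x, x)
  expect_equal(r0$r, 0)
  expect_equal(r0$category, "small")
  # category thresholds on the printed scale
  expect_equal(plaseg:::effect_category(2.5 / sqrt(25)), "strong")
  expect_equal(plaseg:::effect_category(1.2 / sqrt(16)), "small")
  expect_equal(plaseg:::effect_category(0.42), "moderate")
  # all-positive differences: W = n(n+1)/2, z = (W - mu)/sigma
  set.seed(5)
  a <- runif(8) + 1
  b <- a - runif(8, 0.1, 0.5)
  ef <- paired_wilcoxon_effect(a, b)
  n <- 8
  z_expect <- (n * (n + 1) / 2 - n * (n + 1) / 4) /
    sqrt(n * (n + 1) * (2 * n + 1) / 24)
  expect_equal(ef$z, z_expect, tolerance = 1e-12)
  expect_equal(ef$r, abs(z_expect) / sqrt(n), tolerance = 1e-12)
  # p-value agrees with the normal-approximation wilcox.test
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                     correct = FALSE))
  expect_equal(ef$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("relative change helper reproduces simple percentages", {
  expect_equal(pct_change(0.5, 0.75), 50)
  expect_equal(pct_change(10, 5, lower_is_better = TRUE), 50)
})
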