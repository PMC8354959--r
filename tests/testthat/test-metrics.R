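test_that("dice matches the set formula and its conventions", {
  a <- array(0, c(4, 4))
  b <- array(0, c(4, 4))
  a[1:2, 1] <- 1
  b[1:3, 1] <- 1
  expect_equal(dice(a, b), 0.8)  # 2*2 / (2+3)
  expect_equal(dice(a, a), 1)
  d <- array(0, c(4, 4))
  d[4, 4] <- 1
  expect_equal(dice(a, d), 0)
  # both-empty convention
  z <- array(0, c(4, 4))
  expect_equal(dice(z, z), 1)
  # symmetry
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, array(0.5, c(4, 4))), "binary")
  expect_error(dice(a, array(0, c(2, 2))), "shape")
})

test_that("data-set Dice pools voxels rather than averaging subjects", {
  # hand-built example: subject 1 perfect (|X|=|Y|=2), subject 2 disjoint
  # (|X|=|Y|=2): pooled = 2*2 / (4+4)
  p1 <- array(0, c(3, 3)); t1 <- array(0, c(3, 3))
  p1[1:2, 1] <- 1; t1[1:2, 1] <- 1
  p2 <- array(0, c(3, 3)); t2 <- array(0, c(3, 3))
  p2[1:2, 2] <- 1; t2[1:2, 3] <- 1
  expect_equal(dice_dataset(list(p1, p2), list(t1, t2)), 100 * 4 / 8)
  # unequal sizes make pooled and mean disagree
  p3 <- array(0, c(3, 3)); t3 <- array(0, c(3, 3))
  p3[, 1:2] <- 1; t3[, 1:2] <- 1   # 6 voxels, perfect
  pooled <- dice_dataset(list(p2, p3), list(t2, t3))
  subj <- dice_subjects(list(p2, p3), list(t2, t3))
  expect_equal(pooled, 100 * 2 * (0 + 6) / ((2 + 6) + (2 + 6)))
  expect_equal(subj$mean, 50)
  expect_false(isTRUE(all.equal(pooled, subj$mean)))
  # singleton reduction and permutation invariance
  expect_equal(dice_dataset(list(p1), list(t1)), 100 * dice(p1, t1))
  expect_equal(dice_dataset(list(p3, p2), list(t3, t2)), pooled)
  expect_error(dice_dataset(list(), list()), "empty")
})

test_that("subject-wise Dice reports mean and population deviation", {
  p <- array(1, c(2, 2))
  z <- array(0, c(2, 2))
  o <- array(c(1, 0, 0, 0), c(2, 2))
  res <- dice_subjects(list(p, o), list(p, z))
  expect_equal(res$per_subject, c(100, 0))
  expect_equal(res$mean, 50)
  expect_equal(res$std, 50)  # population, not sample
  same <- dice_subjects(list(p, p), list(p, p))
  expect_equal(same$std, 0)
  expect_equal(mean(res$per_subject), res$mean, tolerance = 1e-9)
})

test_that("dice agrees with an index-set oracle on random instances", {
  set.seed(1)
  for (i in 1:100) {
    n <- sample(20:500, 1)
    d <- c(n, 1)
    p <- array(rbinom(n, 1, runif(1, 0.1, 0.6)), d)
    t <- array(rbinom(n, 1, runif(1, 0.1, 0.6)), d)
    expect_identical(dice(p, t), dice_oracle(p, t))
  }
})

test_that("precision-recall curve and area match a brute-force oracle", {
  # perfect separation
  expect_equal(auprc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 100)
  # constant scores collapse to a single point at the prevalence
  expect_equal(auprc(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 30)
  set.seed(2)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.3)
  expect_equal(auprc(scores, labels), auprc_oracle(scores, labels),
               tolerance = 1e-9)
  # tied scores
  scores_t <- sample(seq(0, 1, 0.1), 200, replace = TRUE)
  expect_equal(auprc(scores_t, labels), auprc_oracle(scores_t, labels),
               tolerance = 1e-9)
  curve <- pr_curve(scores, labels)
  expect_true(all(diff(curve$recall) >= 0))
  expect_true(all(curve$precision >= 0 & curve$precision <= 1))
  expect_error(pr_curve(scores, rep(0, 200)), "positive")
})

test_that("slice labelling flags exactly the annotated axial slices", {
  ann <- array(0, c(8, 8, 8))
  expect_equal(label_slices(ann), rep(0L, 8))
  ann[3, 4, 5] <- 1
  lab <- label_slices(ann)
  expect_equal(sum(lab), 1)
  expect_equal(which(lab == 1), 5)
  expect_length(label_slices(array(0, c(4, 4, 16))), 16)
})

test_that("slice scores are in-mask mean residuals and scale linearly", {
  x <- array(0, c(8, 8, 8))
  mask <- array(1, c(8, 8, 8))
  x_hat <- x
  expect_equal(score_slices(x, x_hat, mask), rep(0, 8))
  x_hat[, , 3] <- 0.5
  s <- score_slices(x, x_hat, mask)
  expect_equal(which(s > 0), 3)
  expect_equal(s[3], 0.5)
  expect_equal(score_slices(x, 2 * x_hat, mask), 2 * s)
  # mask-free slices score zero
  mask[, , 3] <- 0
  expect_equal(score_slices(x, x_hat, mask)[3], 0)
})

test_that("relative improvement reproduces printed worked examples", {
  expect_equal(relative_improvement(26.80, 30.10), 12.31)
  expect_equal(relative_improvement(24.72, 32.68), 32.20)
  expect_equal(relative_improvement(10, 10), 0)
  expect_error(relative_improvement(0, 5), "baseline")
})

test_that("evaluation report carries all metric fields on percent scales", {
  s1 <- tiny_lesioned(seed = 21, grid = 32)
  s2 <- tiny_lesioned(seed = 22, grid = 32)
  # imperfect synthetic "residuals": annotation plus noise
  set.seed(5)
  res <- lapply(list(s1, s2), function(s) {
    s$annotation * 0.6 + array(runif(length(s$mask), 0, 0.3), dim(s$mask)) *
      s$mask
  })
  preds <- lapply(res, binarize, threshold = 0.5)
  rep <- evaluate_segmentation(preds, list(s1$annotation, s2$annotation),
                               residuals = res)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$n_subjects, 2)
  expect_true(rep$dice_dataset > 0 && rep$dice_dataset <= 100)
  expect_true(rep$auprc_voxel > 0 && rep$auprc_voxel <= 100)
  expect_true(rep$dice_subject_std >= 0)
  expect_equal(nrow(tidy(rep)), 2)
  expect_equal(glance(rep)$dice_dataset, rep$dice_dataset)
})
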