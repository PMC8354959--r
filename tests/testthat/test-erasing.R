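test_that("single-region erasing respects budget, borders and the target", {
  set.seed(1)
  img <- array(runif(24^3), c(24, 24, 24))
  cfg <- erasing_config("single", "zero", apply_prob = 1)
  n <- length(img)
  for (i in 1:200) {
    es <- erase_single(img, cfg)
    frac <- es$nominal_size / n
    expect_gte(frac, 0.01)
    expect_lte(frac, 0.25)
    expect_identical(es$target, img)
    expect_true(all(es$input[es$erase_mask] == 0))
    expect_identical(es$input[!es$erase_mask], img[!es$erase_mask])
    expect_gt(sum(es$erase_mask), 0)
  }
})

test_that("multi-region erasing bounds region count and total budget", {
  set.seed(2)
  img <- array(runif(24^3), c(24, 24, 24))
  cfg <- erasing_config("multi", "zero", apply_prob = 1)
  n <- length(img)
  counts <- integer(200)
  for (i in 1:200) {
    es <- erase_multi(img, cfg)
    frac <- es$nominal_size / n
    expect_gte(frac, 0.01)
    expect_lte(frac, 0.25)
    expect_lte(es$n_regions, 10)
    expect_gte(es$n_regions, 1)
    counts[i] <- es$n_regions
    expect_identical(es$target, img)
  }
  expect_gt(length(unique(counts)), 3)
})

test_that("half erasing removes exactly one lateral half of a slice or slab", {
  cfg <- erasing_config("half")
  s2 <- array(runif(64^2), c(64, 64))
  set.seed(3)
  es2 <- erase_half(s2, cfg)
  expect_equal(sum(es2$erase_mask), 64 * 32)
  # erased columns are one contiguous lateral block
  lr <- apply(es2$erase_mask, 1, any)
  expect_true(identical(lr, c(rep(TRUE, 32), rep(FALSE, 32))) ||
                identical(lr, c(rep(FALSE, 32), rep(TRUE, 32))))
  v <- array(runif(64^3), c(64, 64, 64))
  set.seed(4)
  for (i in 1:100) {
    es <- erase_half(v, cfg)
    zs <- which(apply(es$erase_mask, 3, any))
    k <- length(zs)
    expect_gte(k, 1)
    expect_lte(k, 32)
    expect_equal(zs, seq(min(zs), max(zs)))
    expect_equal(sum(es$erase_mask), 32 * 64 * k)
  }
  expect_error(
    erase_half(array(0, c(16, 16, 16)), erasing_config("half")),
    "slab_range")
})

test_that("fill modes write zeros or draws from the image's own distribution", {
  set.seed(5)
  img <- array(runif(32^2, 0.2, 0.8), c(32, 32))
  mask <- array(FALSE, c(32, 32))
  mask[5:20, 5:20] <- TRUE
  z <- fill_region(img, mask, "zero")
  expect_equal(sum(z[mask]), 0)
  expect_identical(z[!mask], img[!mask])
  # degenerate distribution: constant image stays constant
  cimg <- array(0.7, c(16, 16))
  expect_true(all(fill_region(cimg, mask[1:16, 1:16], "noise") == 0.7))
  # mean of noise-filled values close to the image mean (3 standard errors)
  nf <- fill_region(img, mask, "noise")
  se <- sd(as.vector(img)) / sqrt(sum(mask))
  expect_lt(abs(mean(nf[mask]) - mean(img)), 3 * se)
})

test_that("noise fill matches the source intensity distribution (KS check)", {
  set.seed(6)
  img <- array(c(runif(2000), rep(0, 32^3 - 2000)), c(32, 32, 32))
  cfg <- erasing_config("single", "noise", apply_prob = 1)
  es <- erase_single(img, cfg)
  n1 <- sum(es$erase_mask)
  # calibrate the KS bound on known-identical samples of the same size
  cal <- replicate(50, {
    s <- sample(as.vector(img), n1, replace = TRUE)
    suppressWarnings(stats::ks.test(s, as.vector(img))$statistic)
  })
  bound <- max(cal) * 1.5
  d <- suppressWarnings(
    stats::ks.test(es$input[es$erase_mask], as.vector(img))$statistic)
  expect_lt(d, bound)
})

test_that("erasing is applied with the configured probability", {
  set.seed(7)
  img <- array(runif(8^2), c(8, 8))
  cfg <- erasing_config("single", apply_prob = 0.5)
  hits <- vapply(1:10000, function(i) {
    sum(apply_erasing(img, cfg)$erase_mask) > 0
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.5), 0.02)
  # degenerate probabilities
  cfg0 <- erasing_config("single", apply_prob = 0)
  es <- apply_erasing(img, cfg0)
  expect_identical(es$input, img)
  expect_equal(sum(es$erase_mask), 0)
  cfg_none <- erasing_config("none", apply_prob = 1)
  expect_identical(apply_erasing(img, cfg_none)$input, img)
})

test_that("erasing draws are reproducible under a fixed seed", {
  img <- array(runif(16^3), c(16, 16, 16))
  for (strat in c("single", "multi", "half")) {
    cfg <- erasing_config(strat, "noise", apply_prob = 1,
                          slab_range = c(1L, 8L))
    set.seed(99)
    a <- apply_erasing(img, cfg)
    set.seed(99)
    b <- apply_erasing(img, cfg)
    expect_identical(a, b)
  }
})

test_that("2D and 3D half erasing agree on through-slab volumes", {
  # a volume constant along the axial axis, erased across the full slab,
  # must reduce to the 2D result applied slice by slice
  sl <- array(runif(64^2), c(64, 64))
  v <- array(rep(sl, 64), c(64, 64, 64))
  cfg3 <- erasing_config("half", "zero", apply_prob = 1,
                         slab_range = c(64, 64))
  set.seed(8)
  es3 <- erase_half(v, cfg3)
  m2 <- es3$erase_mask[, , 1]
  for (k in c(2, 33, 64)) {
    expect_identical(es3$erase_mask[, , k], m2)
    expect_identical(es3$input[, , k], ifelse(m2, 0, sl))
  }
})

test_that("erasing configuration is validated", {
  expect_error(erasing_config("single", budget_range = c(0, 0.25)),
               "budget_range")
  expect_error(erasing_config("single", apply_prob = 1.5), "apply_prob")
  expect_error(erasing_config("multi", max_regions = 0), "max_regions")
  expect_error(erasing_config("half", slab_range = c(3, 2)), "slab_range")
  expect_error(apply_erasing(array(0, c(4, 4)), list()), "erasing_config")
})
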