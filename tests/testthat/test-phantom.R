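test_that("noise-free, jitter-free phantoms are exact mirror fixed points", {
  ph <- tiny_phantom(seed = 3, grid = 32, noise = 0, jitter = 0)
  mirrored <- ph$volume[rev(seq_len(32)), , ]
  expect_equal(max(abs(ph$volume - mirrored)), 0, tolerance = 1e-12)
  expect_true(all(ph$volume >= 0 & ph$volume <= 1))
  expect_true(all(ph$volume[ph$mask == 0] == 0))
})

test_that("phantom generation is seed-deterministic", {
  a <- tiny_phantom(seed = 7, grid = 16)
  b <- tiny_phantom(seed = 7, grid = 16)
  expect_identical(a, b)
  c <- tiny_phantom(seed = 8, grid = 16)
  expect_false(identical(a$volume, c$volume))
})

test_that("default 64^3 brain mask fills between 10% and 70% of the grid", {
  ph <- generate_healthy(phantom_spec(seed = 1))
  frac <- mean(ph$mask)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.7)
  # frozen value for the default semi-axes, computed from the ellipsoid
  expect_equal(frac, 0.2273, tolerance = 1e-3)
})

test_that("noisy phantoms stay mirror-symmetric up to the noise level", {
  sigma <- 0.04
  ph <- generate_healthy(phantom_spec(grid_size = 32, noise_sigma = sigma,
                                      symmetry_jitter = 0, seed = 11))
  asym <- abs(ph$volume - ph$volume[rev(seq_len(32)), , ])
  expect_lte(mean(asym[ph$mask == 1]), 2 * sigma)
})

test_that("phantom spec validation rejects bad parameters", {
  expect_error(phantom_spec(grid_size = 8), "grid_size")
  expect_error(phantom_spec(noise_sigma = 0.7), "noise_sigma")
  expect_error(phantom_spec(brain_axes = c(40, 20, 20), grid_size = 64),
               "fit inside")
  expect_error(generate_healthy(list()), "phantom_spec")
})

test_that("zero-contrast lesions annotate without modifying the volume", {
  ph <- tiny_phantom(seed = 2, grid = 32)
  les <- insert_lesions(ph$volume, ph$mask,
                        lesion_spec(n_lesions = 1, radius_range = c(2, 4),
                                    intensity_shift = 0, seed = 4))
  expect_gt(sum(les$annotation), 0)
  expect_identical(les$volume, ph$volume)
})

test_that("lesions form disjoint components inside the brain mask", {
  s <- tiny_lesioned(seed = 6, grid = 32, n_lesions = 2)
  expect_true(all(s$annotation <= s$mask))
  expect_equal(count_components_oracle(s$annotation), 2)
})

test_that("lesion insertion is deterministic and leaves healthy voxels intact", {
  ph <- tiny_phantom(seed = 9, grid = 32)
  lspec <- lesion_spec(n_lesions = 2, radius_range = c(2, 4), seed = 13)
  a <- insert_lesions(ph$volume, ph$mask, lspec)
  b <- insert_lesions(ph$volume, ph$mask, lspec)
  expect_identical(a, b)
  expect_identical(a$volume[a$annotation == 0], ph$volume[a$annotation == 0])
  expect_true(all(a$volume >= 0 & a$volume <= 1))
})

test_that("impossible lesion placement raises a placement error", {
  ph <- tiny_phantom(seed = 1, grid = 32)
  # radius almost as large as the brain: cannot fit strictly inside
  expect_error(
    insert_lesions(ph$volume, ph$mask,
                   lesion_spec(n_lesions = 1, radius_range = c(14, 15),
                               seed = 1), max_tries = 5),
    class = "erasevae_placement_error")
})

test_that("cohort generation writes a complete, reproducible manifest", {
  spec <- phantom_spec(grid_size = 16, seed = 1)
  lspec <- lesion_spec(n_lesions = 1, radius_range = c(1.5, 2.5), seed = 1)
  d1 <- withr::local_tempdir()
  m1 <- generate_cohort(d1, n_healthy = 5, n_lesioned = 4, spec, lspec,
                        seed = 42)
  expect_equal(nrow(m1), 9)
  expect_equal(sum(m1$role == "train"), 4)
  expect_equal(sum(m1$role == "val-healthy"), 1)
  expect_equal(sum(m1$role == "val-anom"), 2)
  expect_equal(sum(m1$role == "test"), 2)
  expect_true(all(file.exists(m1$path)))
  expect_true(all(file.exists(m1$mask_path)))
  expect_true(all(is.na(m1$annotation_path[m1$role %in%
                                             c("train", "val-healthy")])))
  # round-trip through the manifest reader
  m1b <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(m1b$role, m1$role)

  d2 <- withr::local_tempdir()
  m2 <- generate_cohort(d2, n_healthy = 5, n_lesioned = 4, spec, lspec,
                        seed = 42)
  expect_identical(m1$seed, m2$seed)
  v1 <- load_volume(m1$path[6])$data
  v2 <- load_volume(m2$path[6])$data
  expect_identical(v1, v2)
})

test_that("cohorts without healthy subjects contain only lesioned roles", {
  d <- withr::local_tempdir()
  m <- generate_cohort(d, n_healthy = 0, n_lesioned = 2,
                       phantom_spec(grid_size = 16, seed = 1),
                       lesion_spec(n_lesions = 1, radius_range = c(1.5, 2.5)),
                       seed = 3)
  expect_equal(nrow(m), 2)
  expect_true(all(m$role %in% c("val-anom", "test")))
})
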