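test_that("encoder produces posterior vectors of the configured latent size", {
  cfg3 <- network_config(rank = 3, input_extent = 64)
  expect_equal(cfg3$latent_dim, 512)
  model3 <- vae_init(cfg3)
  set.seed(1)
  batch <- list(array(runif(64^3), c(64, 64, 64)),
                array(runif(64^3), c(64, 64, 64)))
  code <- encode(model3, batch)
  expect_equal(dim(code$mu), c(2, 512))
  expect_equal(dim(code$logvar), c(2, 512))
  expect_true(all(is.finite(code$mu)))

  cfg2 <- network_config(rank = 2, input_extent = 64)
  expect_equal(cfg2$latent_dim, 128)
  model2 <- vae_init(cfg2)
  code2 <- encode(model2, array(runif(64^2), c(64, 64)))
  expect_equal(dim(code2$mu), c(1, 128))

  expect_error(encode(model3, array(0, c(32, 32, 32))), "extent")
  expect_error(encode(model3, array(0, c(64, 64))), "rank")
})

test_that("the first convolution halves the spatial extent", {
  cfg <- network_config(rank = 3, input_extent = 64)
  shapes <- layer_shapes(vae_init(cfg))
  first <- shapes[shapes$part == "encoder" & shapes$stage == 1, ]
  expect_equal(first$extent, 32)
  # every stage halves again
  enc <- shapes[shapes$part == "encoder", ]
  expect_equal(enc$extent, 64 / 2^(1:4))
})

test_that("2D and 3D networks share one structure differing only in rank", {
  m2 <- vae_init(network_config(rank = 2, input_extent = 64, seed = 1))
  m3 <- vae_init(network_config(rank = 3, input_extent = 64, seed = 1))
  expect_equal(length(m2$enc), length(m3$enc))
  expect_equal(length(m2$dec), length(m3$dec))
  expect_equal(m2$cfg$stage_channels, m3$cfg$stage_channels)
  s2 <- layer_shapes(m2)
  s3 <- layer_shapes(m3)
  expect_equal(s2$extent, s3$extent)
  expect_equal(s2$channels, s3$channels)
  # weight tensors differ by the kernel rank only
  expect_equal(nrow(m3$enc[[1]]$W) / nrow(m2$enc[[1]]$W), 3)  # 27/9 taps
})

test_that("reparameterization follows mu + exp(logvar/2) * eps", {
  code <- structure(list(mu = matrix(c(1, -2), 1, 2),
                         logvar = matrix(c(-60, -60), 1, 2)),
                    class = "latent_code")
  # variance -> 0 limit collapses to the mean
  set.seed(1)
  z <- reparameterize(code)
  expect_equal(as.vector(z), c(1, -2), tolerance = 1e-10)
  # fixed seed reproducibility
  code2 <- structure(list(mu = matrix(0, 1, 4), logvar = matrix(0, 1, 4)),
                     class = "latent_code")
  set.seed(7)
  a <- reparameterize(code2)
  set.seed(7)
  b <- reparameterize(code2)
  expect_identical(a, b)
  # evaluation mode returns the mean
  expect_identical(reparameterize(code2, sample = FALSE), code2$mu)
  # CLT: sample mean of 10^4 standard-normal draws within 3/sqrt(n)
  big <- structure(list(mu = matrix(0, 10000, 3),
                        logvar = matrix(0, 10000, 3)),
                   class = "latent_code")
  set.seed(8)
  zs <- reparameterize(big)
  expect_true(all(abs(colMeans(zs)) <= 3 / sqrt(10000)))
})

test_that("decoder output matches the input shape and is bounded to [0,1]", {
  cfg <- tiny_net(extent = 16, latent = 6, channels = c(4, 8), rank = 3)
  model <- vae_init(cfg)
  set.seed(2)
  x_hat <- decode(model, rnorm(6) * 5)
  expect_equal(dim(x_hat), c(16, 16, 16))
  expect_true(all(x_hat >= 0 & x_hat <= 1))
  cfg2 <- tiny_net(extent = 16, latent = 6, channels = c(4, 8), rank = 2)
  x_hat2 <- decode(vae_init(cfg2), rnorm(6))
  expect_equal(dim(x_hat2), c(16, 16))
  expect_error(decode(model, rnorm(5)), "latent")
})

test_that("l1 reconstruction loss equals the brute-force mean absolute error", {
  a <- array(0, c(8, 8))
  b <- array(1, c(8, 8))
  expect_equal(recon_l1(a, a), 0)
  expect_equal(recon_l1(a, b), 1)
  set.seed(3)
  x <- array(runif(6^3), c(6, 6, 6))
  y <- array(runif(6^3), c(6, 6, 6))
  acc <- 0
  for (i in seq_along(x)) acc <- acc + abs(x[i] - y[i])
  expect_equal(recon_l1(x, y), acc / length(x), tolerance = 1e-7)
  expect_error(recon_l1(a, array(0, c(4, 4))), "shape")
})

test_that("KL closed form matches hand values and the Monte-Carlo oracle", {
  lc <- function(mu, lv) {
    structure(list(mu = matrix(mu, 1), logvar = matrix(lv, 1)),
              class = "latent_code")
  }
  expect_equal(kl_term(lc(c(0, 0), c(0, 0))), 0)
  expect_equal(kl_term(lc(1, 0)), 0.5)
  set.seed(4)
  for (i in 1:5) {
    mu <- rnorm(4)
    lv <- rnorm(4, sd = 0.5)
    mc <- kl_mc_oracle(mu, lv, n = 1e5)
    expect_lt(abs(kl_term(lc(mu, lv)) - mc$est), 3 * mc$se)
  }
})

test_that("loss components sum to the total", {
  cfg <- tiny_net(extent = 8, latent = 4, channels = c(4, 4), rank = 2)
  model <- vae_init(cfg)
  set.seed(5)
  x <- array(runif(64), c(8, 8))
  code <- encode(model, x)
  x_hat <- decode(model, reparameterize(code, sample = FALSE))[[1]]
  l <- vae_loss(x, x_hat, code, kl_weight = 0.3)
  expect_equal(l$loss, l$recon + 0.3 * l$kl, tolerance = 1e-7)
  l0 <- vae_loss(x, x_hat, code, kl_weight = 0)
  expect_equal(l0$loss, l0$recon)
  # perfect reconstruction with a standard-normal code scores zero
  zero_code <- structure(list(mu = matrix(0, 1, 4), logvar = matrix(0, 1, 4)),
                         class = "latent_code")
  expect_equal(vae_loss(x, x, zero_code)$loss, 0)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_net(extent = 8, latent = 5, channels = c(4, 6), rank = 2,
                  seed = 2)
  model <- vae_init(cfg)
  set.seed(9)
  x <- array(runif(64), c(8, 8))
  eps <- rnorm(5)
  klw <- 0.7
  loss_fn <- function(m) {
    fw <- erasevae:::vae_forward_sample(m, x, sample = TRUE, eps = eps)
    mean(abs(fw$x_hat - x)) +
      klw * 0.5 * sum(fw$mu^2 + exp(fw$logvar) - 1 - fw$logvar)
  }
  fw <- erasevae:::vae_forward_sample(model, x, sample = TRUE, eps = eps,
                                      keep_cache = TRUE)
  g <- erasevae:::vae_backward_sample(
    model, fw, sign(fw$x_hat - x) / length(x),
    d_mu_extra = klw * fw$mu,
    d_lv_extra = klw * 0.5 * (exp(fw$logvar) - 1))
  flat <- erasevae:::flatten_params(model)
  h <- 1e-6
  set.seed(42)
  for (nm in names(flat)) {
    idx <- sample(length(flat[[nm]]), min(3, length(flat[[nm]])))
    for (i in idx) {
      f2 <- flat
      f2[[nm]][i] <- f2[[nm]][i] + h
      up <- loss_fn(erasevae:::unflatten_params(model, f2))
      f2[[nm]][i] <- f2[[nm]][i] - 2 * h
      dn <- loss_fn(erasevae:::unflatten_params(model, f2))
      num <- (up - dn) / (2 * h)
      expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                   label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip weights and configuration", {
  cfg <- tiny_net(extent = 8, latent = 4, channels = c(4, 4), rank = 2)
  model <- vae_init(cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f, train_seed = 33)
  back <- load_checkpoint(f)
  expect_equal(erasevae:::flatten_params(back),
               erasevae:::flatten_params(model))
  expect_equal(back$cfg, model$cfg)
  expect_equal(attr(back, "train_seed"), 33)
})

test_that("network configuration is validated", {
  expect_error(network_config(rank = 4), "rank")
  expect_error(network_config(input_extent = 60), "divisible")
  expect_error(network_config(latent_dim = 0), "latent_dim")
  expect_error(network_config(kernel_size = 4), "odd")
})
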