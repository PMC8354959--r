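#' Network configuration for the 2D/3D variational autoencoder
#'
#' One architecture specification instantiated at rank 2 (slices) or rank 3
#' (volumes): a stack of stride-2 convolutions (the first convolution already
#' downsamples, 64 -> 32), a dense map to the Gaussian posterior parameters
#' (mu, log-variance), and a mirrored decoder of transposed convolutions with
#' a logistic-sigmoid output bounded to the normalized intensity range
#' \[0, 1\]. Layer count and feature-map widths are identical across ranks;
#' only the operator rank and the latent size differ.
#'
#' @param rank 2 for slice models, 3 for volume models.
#' @param input_extent Spatial extent per axis (default 64); must be
#'   divisible by `2^length(stage_channels)`.
#' @param latent_dim Latent size n_z; defaults to 128 for rank 2 and 512 for
#'   rank 3.
#' @param stage_channels Feature maps per downsampling stage.
#' @param kernel_size Odd encoder kernel size (default 3). Decoder transposed
#'   convolutions use kernel 4, stride 2, pad 1 for exact doubling.
#' @param activation Hidden activation; `"leaky_relu"` (slope 0.2).
#' @param seed Seed for weight initialization.
#' @return An object of class `network_config`.
#' @export
network_config <- function(rank = 3, input_extent = 64L, latent_dim = NULL,
                           stage_channels = c(32, 64, 128, 256),
                           kernel_size = 3L, activation = "leaky_relu",
                           seed = 1L) {
  assert_that(rank %in% c(2, 3), "rank must be 2 or 3")
  if (is.null(latent_dim)) latent_dim <- if (rank == 2) 128L else 512L
  n_stages <- length(stage_channels)
  assert_that(input_extent %% (2^n_stages) == 0,
              "input_extent must be divisible by 2^(number of stages)")
  assert_that(latent_dim >= 1, "latent_dim must be >= 1")
  assert_that(kernel_size %% 2 == 1, "kernel_size must be odd")
  structure(list(rank = as.integer(rank),
                 input_extent = as.integer(input_extent),
                 latent_dim = as.integer(latent_dim),
                 stage_channels = as.integer(stage_channels),
                 kernel_size = as.integer(kernel_size),
                 activation = activation, seed = as.integer(seed)),
            class = "network_config")
}

leaky_relu <- function(a, alpha = 0.2) pmax(a, 0) + alpha * pmin(a, 0)
leaky_relu_grad <- function(a, alpha = 0.2) ifelse(a > 0, 1, alpha)
sigmoid <- function(a) 1 / (1 + exp(-a))

add_bias <- function(A, b) A + rep(b, each = nrow(A))

#' Initialize a VAE model
#'
#' He-style initialization of all convolution, transposed-convolution and
#' dense weights under the configuration seed.
#'
#' @param cfg A [network_config()].
#' @return An object of class `vae_model` holding the parameter list and the
#'   configuration.
#' @export
vae_init <- function(cfg) {
  assert_that(inherits(cfg, "network_config"), "cfg must be a network_config")
  r <- cfg$rank
  k <- cfg$kernel_size
  K <- k^r
  K4 <- 4^r
  ch <- c(1L, cfg$stage_channels)
  S <- length(cfg$stage_channels)
  e_last <- cfg$input_extent / 2^S
  flat <- cfg$stage_channels[S] * e_last^r
  he <- function(nr, nc, fan_in) {
    matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  with_seed(cfg$seed, {
    enc <- lapply(seq_len(S), function(i) {
      list(W = he(ch[i] * K, ch[i + 1], ch[i] * K), b = numeric(ch[i + 1]))
    })
    fc_mu <- list(W = he(flat, cfg$latent_dim, flat),
                  b = numeric(cfg$latent_dim))
    fc_lv <- list(W = he(flat, cfg$latent_dim, flat),
                  b = numeric(cfg$latent_dim))
    fc_dec <- list(W = he(cfg$latent_dim, flat, cfg$latent_dim),
                   b = numeric(flat))
    # decoder stage j maps channels ch[S+2-j] -> ch[S+1-j] while doubling the
    # spatial extent; weights are stored for the adjoint convolution
    dec <- lapply(seq_len(S), function(j) {
      c_in <- ch[S + 2 - j]
      c_out <- ch[S + 1 - j]
      list(W = he(c_out * K4, c_in, c_in * K4), b = numeric(c_out))
    })
    structure(list(cfg = cfg, enc = enc, fc_mu = fc_mu, fc_lv = fc_lv,
                   fc_dec = fc_dec, dec = dec),
              class = "vae_model")
  })
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf(
    "<vae_model> rank %d, input %d^%d, latent %d, stages (%s), %d parameters\n",
    x$cfg$rank, x$cfg$input_extent, x$cfg$rank, x$cfg$latent_dim,
    paste(x$cfg$stage_channels, collapse = ", "), count_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A `vae_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(flatten_params(model), length, numeric(1)))
}

# Flatten the parameter tree into a named list of numeric objects.
flatten_params <- function(model) {
  out <- list()
  for (i in seq_along(model$enc)) {
    out[[paste0("enc", i, ".W")]] <- model$enc[[i]]$W
    out[[paste0("enc", i, ".b")]] <- model$enc[[i]]$b
  }
  out[["fc_mu.W"]] <- model$fc_mu$W
  out[["fc_mu.b"]] <- model$fc_mu$b
  out[["fc_lv.W"]] <- model$fc_lv$W
  out[["fc_lv.b"]] <- model$fc_lv$b
  out[["fc_dec.W"]] <- model$fc_dec$W
  out[["fc_dec.b"]] <- model$fc_dec$b
  for (j in seq_along(model$dec)) {
    out[[paste0("dec", j, ".W")]] <- model$dec[[j]]$W
    out[[paste0("dec", j, ".b")]] <- model$dec[[j]]$b
  }
  out
}

unflatten_params <- function(model, flat) {
  for (i in seq_along(model$enc)) {
    model$enc[[i]]$W <- flat[[paste0("enc", i, ".W")]]
    model$enc[[i]]$b <- flat[[paste0("enc", i, ".b")]]
  }
  model$fc_mu$W <- flat[["fc_mu.W"]]; model$fc_mu$b <- flat[["fc_mu.b"]]
  model$fc_lv$W <- flat[["fc_lv.W"]]; model$fc_lv$b <- flat[["fc_lv.b"]]
  model$fc_dec$W <- flat[["fc_dec.W"]]; model$fc_dec$b <- flat[["fc_dec.b"]]
  for (j in seq_along(model$dec)) {
    model$dec[[j]]$W <- flat[[paste0("dec", j, ".W")]]
    model$dec[[j]]$b <- flat[[paste0("dec", j, ".b")]]
  }
  model
}

check_input_shape <- function(model, x) {
  d <- dim(x)
  cfg <- model$cfg
  assert_that(length(d) == cfg$rank,
              sprintf("input rank %d does not match network rank %d",
                      length(d), cfg$rank))
  assert_that(all(d == cfg$input_extent),
              sprintf("input extent (%s) does not match configured %d",
                      paste(d, collapse = "x"), cfg$input_extent))
}

# Forward pass for one sample. Returns activations needed for backprop.
vae_forward_sample <- function(model, x, sample = FALSE, eps = NULL,
                               keep_cache = FALSE) {
  cfg <- model$cfg
  check_input_shape(model, x)
  r <- cfg$rank
  k <- cfg$kernel_size
  pad <- (k - 1L) %/% 2L
  S <- length(cfg$stage_channels)
  ch <- c(1L, cfg$stage_channels)
  sp <- rep(cfg$input_extent, r)
  H <- matrix(as.vector(x), ncol = 1)
  enc_cache <- vector("list", S)
  for (i in seq_len(S)) {
    P <- nd_im2col(as.vector(H), as.integer(sp), ch[i], k, 2L, pad)
    A <- add_bias(P %*% model$enc[[i]]$W, model$enc[[i]]$b)
    Hn <- leaky_relu(A)
    enc_cache[[i]] <- list(P = P, A = A, sp = sp)
    sp <- sp %/% 2L
    H <- Hn
  }
  flat <- as.vector(H)
  mu <- as.vector(flat %*% model$fc_mu$W) + model$fc_mu$b
  logvar <- as.vector(flat %*% model$fc_lv$W) + model$fc_lv$b
  if (sample) {
    if (is.null(eps)) eps <- rnorm(length(mu))
    z <- mu + exp(logvar / 2) * eps
  } else {
    eps <- numeric(length(mu))
    z <- mu
  }
  d0 <- as.vector(z %*% model$fc_dec$W) + model$fc_dec$b
  D0 <- leaky_relu(d0)
  e_small <- cfg$input_extent / 2^S
  Hd <- matrix(D0, nrow = e_small^r, ncol = ch[S + 1])
  dec_cache <- vector("list", S)
  spd <- rep(e_small, r)
  for (j in seq_len(S)) {
    sp_large <- spd * 2L
    c_out <- ch[S + 1 - j]
    dP <- Hd %*% t(model$dec[[j]]$W)
    Y <- nd_col2im(dP, as.integer(sp_large), c_out, 4L, 2L, 1L)
    Ym <- matrix(Y, nrow = prod(sp_large), ncol = c_out)
    Am <- add_bias(Ym, model$dec[[j]]$b)
    dec_cache[[j]] <- list(Hin = Hd, A = Am, sp_large = sp_large)
    Hd <- if (j < S) leaky_relu(Am) else sigmoid(Am)
    spd <- sp_large
  }
  x_hat <- array(Hd[, 1], dim = rep(cfg$input_extent, r))
  out <- list(x_hat = x_hat, mu = mu, logvar = logvar, z = z, eps = eps)
  if (keep_cache) {
    out$enc_cache <- enc_cache
    out$dec_cache <- dec_cache
    out$flat <- flat
    out$d0 <- d0
    out$D0 <- D0
  }
  out
}

# Backward pass for one sample; `fw` must come from vae_forward_sample with
# keep_cache = TRUE. d_xhat is dLoss/dx_hat (same shape as x_hat);
# d_mu_extra / d_lv_extra carry the KL contributions.
vae_backward_sample <- function(model, fw, d_xhat, d_mu_extra, d_lv_extra) {
  cfg <- model$cfg
  r <- cfg$rank
  k <- cfg$kernel_size
  pad <- (k - 1L) %/% 2L
  S <- length(cfg$stage_channels)
  ch <- c(1L, cfg$stage_channels)
  grads <- list()
  # decoder, last stage first
  dH <- matrix(as.vector(d_xhat), ncol = 1)
  for (j in rev(seq_len(S))) {
    cc <- fw$dec_cache[[j]]
    c_out <- ch[S + 1 - j]
    act_grad <- if (j < S) {
      leaky_relu_grad(cc$A)
    } else {
      y <- sigmoid(cc$A)
      y * (1 - y)
    }
    dA <- dH * act_grad
    grads[[paste0("dec", j, ".b")]] <- colSums(dA)
    G <- nd_im2col(as.vector(dA), as.integer(cc$sp_large), c_out, 4L, 2L, 1L)
    grads[[paste0("dec", j, ".W")]] <- t(G) %*% cc$Hin
    dH <- G %*% model$dec[[j]]$W
  }
  dD0 <- as.vector(dH)
  dd0 <- dD0 * leaky_relu_grad(fw$d0)
  grads[["fc_dec.W"]] <- outer(fw$z, dd0)
  grads[["fc_dec.b"]] <- dd0
  dz <- as.vector(model$fc_dec$W %*% dd0)
  d_mu <- dz + d_mu_extra
  d_lv <- dz * fw$eps * 0.5 * exp(fw$logvar / 2) + d_lv_extra
  grads[["fc_mu.W"]] <- outer(fw$flat, d_mu)
  grads[["fc_mu.b"]] <- d_mu
  grads[["fc_lv.W"]] <- outer(fw$flat, d_lv)
  grads[["fc_lv.b"]] <- d_lv
  dflat <- as.vector(model$fc_mu$W %*% d_mu) +
    as.vector(model$fc_lv$W %*% d_lv)
  # encoder, last stage first
  e_last <- cfg$input_extent / 2^S
  dH <- matrix(dflat, nrow = e_last^r, ncol = ch[S + 1])
  for (i in rev(seq_len(S))) {
    cc <- fw$enc_cache[[i]]
    dA <- dH * leaky_relu_grad(cc$A)
    grads[[paste0("enc", i, ".b")]] <- colSums(dA)
    grads[[paste0("enc", i, ".W")]] <- t(cc$P) %*% dA
    if (i > 1) {
      dP <- dA %*% t(model$enc[[i]]$W)
      dX <- nd_col2im(dP, as.integer(cc$sp), ch[i], k, 2L, pad)
      dH <- matrix(dX, nrow = prod(cc$sp), ncol = ch[i])
    }
  }
  grads
}

#' Encode images to the variational posterior
#'
#' @param model A `vae_model`.
#' @param x A single array (matching the configured rank and extent) or a
#'   list of such arrays.
#' @return A `latent_code`: list with matrices `mu` and `logvar`
#'   (samples x latent_dim).
#' @export
encode <- function(model, x) {
  if (!is.list(x)) x <- list(x)
  n <- length(x)
  mu <- matrix(0, n, model$cfg$latent_dim)
  lv <- matrix(0, n, model$cfg$latent_dim)
  for (i in seq_len(n)) {
    fw <- vae_forward_sample(model, x[[i]], sample = FALSE)
    mu[i, ] <- fw$mu
    lv[i, ] <- fw$logvar
  }
  structure(list(mu = mu, logvar = lv), class = "latent_code")
}

#' Sample latent codes with the reparameterization trick
#'
#' `z = mu + exp(logvar / 2) * eps` with `eps ~ N(0, I)`; with
#' `sample = FALSE` (evaluation mode) returns the posterior mean.
#'
#' @param code A `latent_code`.
#' @param sample Draw noise (`TRUE`) or return `mu` (`FALSE`).
#' @return Matrix of latent samples (samples x latent_dim).
#' @export
reparameterize <- function(code, sample = TRUE) {
  assert_that(inherits(code, "latent_code"), "code must be a latent_code")
  assert_that(all(is.finite(code$mu)) && all(is.finite(code$logvar)),
              "latent code must be finite")
  if (!sample) return(code$mu)
  eps <- matrix(rnorm(length(code$mu)), nrow(code$mu), ncol(code$mu))
  code$mu + exp(code$logvar / 2) * eps
}

#' Decode latent vectors to reconstructions
#'
#' @param model A `vae_model`.
#' @param z A latent vector of length `latent_dim` or a matrix of rows.
#' @return A reconstruction array in \[0, 1\] (or a list for matrix input).
#' @export
decode <- function(model, z) {
  cfg <- model$cfg
  single <- is.null(dim(z))
  if (single) z <- matrix(z, nrow = 1)
  assert_that(ncol(z) == cfg$latent_dim,
              sprintf("latent length %d does not match latent_dim %d",
                      ncol(z), cfg$latent_dim))
  r <- cfg$rank
  S <- length(cfg$stage_channels)
  ch <- c(1L, cfg$stage_channels)
  e_small <- cfg$input_extent / 2^S
  out <- vector("list", nrow(z))
  for (n in seq_len(nrow(z))) {
    d0 <- as.vector(z[n, ] %*% model$fc_dec$W) + model$fc_dec$b
    Hd <- matrix(leaky_relu(d0), nrow = e_small^r, ncol = ch[S + 1])
    spd <- rep(e_small, r)
    for (j in seq_len(S)) {
      sp_large <- spd * 2L
      c_out <- ch[S + 1 - j]
      dP <- Hd %*% t(model$dec[[j]]$W)
      Y <- nd_col2im(dP, as.integer(sp_large), c_out, 4L, 2L, 1L)
      Am <- add_bias(matrix(Y, nrow = prod(sp_large), ncol = c_out),
                     model$dec[[j]]$b)
      Hd <- if (j < S) leaky_relu(Am) else sigmoid(Am)
      spd <- sp_large
    }
    out[[n]] <- array(Hd[, 1], dim = rep(cfg$input_extent, r))
  }
  if (single) out[[1]] else out
}

#' Reconstruct an input through the posterior mean
#'
#' Deterministic evaluation-mode reconstruction (`z = mu`), used for residual
#' maps.
#'
#' @param model A `vae_model`.
#' @param x Input array matching the configured rank.
#' @return Reconstruction array of the same shape.
#' @export
reconstruct <- function(model, x) {
  vae_forward_sample(model, x, sample = FALSE)$x_hat
}

#' Mean absolute (l1) reconstruction error
#'
#' @param x_target Target image (array, or list of arrays).
#' @param x_hat Reconstruction of identical shape.
#' @return Mean absolute difference over all elements (and samples).
#' @export
recon_l1 <- function(x_target, x_hat) {
  if (is.list(x_target)) {
    assert_that(is.list(x_hat) && length(x_hat) == length(x_target),
                "target/reconstruction batch mismatch")
    return(mean(vapply(seq_along(x_target),
                       function(i) recon_l1(x_target[[i]], x_hat[[i]]),
                       numeric(1))))
  }
  assert_that(identical(dim(x_target), dim(x_hat)),
              "target/reconstruction shape mismatch")
  mean(abs(x_target - x_hat))
}

#' Kullback-Leibler divergence of the posterior from the standard normal
#'
#' Closed form for a diagonal Gaussian:
#' `0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)`, averaged over the batch.
#'
#' @param code A `latent_code`.
#' @return Non-negative scalar; 0 iff `mu = 0, logvar = 0`.
#' @export
kl_term <- function(code) {
  assert_that(inherits(code, "latent_code"), "code must be a latent_code")
  per_sample <- 0.5 * rowSums(code$mu^2 + exp(code$logvar) - 1 - code$logvar)
  mean(per_sample)
}

#' Total VAE loss
#'
#' `recon_l1 + kl_weight * kl_term`, with the components returned separately
#' for logging.
#'
#' @param x_target,x_hat Target and reconstruction (arrays or lists).
#' @param code A `latent_code`.
#' @param kl_weight KL weight (default 1).
#' @return List with `loss`, `recon`, `kl`.
#' @export
vae_loss <- function(x_target, x_hat, code, kl_weight = 1) {
  recon <- recon_l1(x_target, x_hat)
  kl <- kl_term(code)
  list(loss = recon + kl_weight * kl, recon = recon, kl = kl)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the weights, the full network configuration and the
#' training seed.
#'
#' @param model A `vae_model`.
#' @param path Destination file.
#' @param train_seed Optional training seed stored alongside.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   a `vae_model` (with attribute `train_seed`).
#' @export
save_checkpoint <- function(model, path, train_seed = NULL) {
  saveRDS(list(model = model, train_seed = train_seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- obj$model
  attr(model, "train_seed") <- obj$train_seed
  model
}

#' Per-stage output shapes of a model
#'
#' @param model A `vae_model`.
#' @return Tibble with stage, part (encoder/decoder), spatial extent and
#'   channels; useful for structural checks and logging.
#' @export
layer_shapes <- function(model) {
  cfg <- model$cfg
  S <- length(cfg$stage_channels)
  ch <- c(1L, cfg$stage_channels)
  enc <- tibble::tibble(part = "encoder", stage = seq_len(S),
                        extent = cfg$input_extent / 2^seq_len(S),
                        channels = cfg$stage_channels)
  dec <- tibble::tibble(part = "decoder", stage = seq_len(S),
                        extent = cfg$input_extent / 2^(S - seq_len(S)),
                        channels = ch[S + 1 - seq_len(S)])
  dplyr::bind_rows(enc, dec)
}
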