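# Fixtures are generated in code; independent brute-force oracles live here
# and never call the implementation paths they check.

tiny_phantom <- function(seed = 1, grid = 16, noise = 0.02, jitter = 0) {
  generate_healthy(phantom_spec(grid_size = grid, noise_sigma = noise,
                                symmetry_jitter = jitter, seed = seed))
}

tiny_lesioned <- function(seed = 1, grid = 32, n_lesions = 2,
                          radius = c(2.5, 5), shift = 0.35) {
  ph <- generate_healthy(phantom_spec(grid_size = grid, seed = seed))
  les <- insert_lesions(ph$volume, ph$mask,
                        lesion_spec(n_lesions = n_lesions,
                                    radius_range = radius,
                                    intensity_shift = shift,
                                    seed = seed + 5000L))
  list(volume = les$volume, mask = ph$mask, annotation = les$annotation)
}

tiny_net <- function(extent = 8, latent = 5, channels = c(4, 6), rank = 2,
                     seed = 1) {
  network_config(rank = rank, input_extent = extent, latent_dim = latent,
                 stage_channels = channels, seed = seed)
}

# Connected components by breadth-first search over the 6-neighbourhood;
# returns the component count.
count_components_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  strides <- c(1L, d[1], d[1] * d[2])
  for (start in which(mask == 1)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      co <- arrayInd(v, d)
      for (ax in 1:3) {
        for (s in c(-1L, 1L)) {
          if (co[ax] + s < 1L || co[ax] + s > d[ax]) next
          ni <- v + s * strides[ax]
          if (mask[ni] == 1 && lab[ni] == 0L) {
            lab[ni] <- cur
            queue <- c(queue, ni)
          }
        }
      }
    }
  }
  cur
}

# Dice via explicit index sets.
dice_oracle <- function(pred, truth) {
  X <- which(pred == 1)
  Y <- which(truth == 1)
  if (length(X) + length(Y) == 0) return(1)
  2 * length(intersect(X, Y)) / (length(X) + length(Y))
}

# Average precision by re-counting from scratch at every unique threshold.
auprc_oracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  area <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    r <- tp / sum(labels == 1)
    area <- area + (r - prev_r) * (tp / (tp + fp))
    prev_r <- r
  }
  100 * area
}

# Monte-Carlo estimate of KL(N(mu, diag exp(logvar)) || N(0, I)).
kl_mc_oracle <- function(mu, logvar, n = 1e5) {
  nz <- length(mu)
  eps <- matrix(rnorm(n * nz), n, nz)
  sdv <- exp(logvar / 2)
  z <- sweep(eps, 2, sdv, `*`)
  z <- sweep(z, 2, mu, `+`)
  logq <- -0.5 * rowSums(sweep(eps^2, 2, logvar, `+`))
  logp <- -0.5 * rowSums(z^2)
  vals <- logq - logp
  list(est = mean(vals), se = stats::sd(vals) / sqrt(n))
}

# Residual/annotation sets whose pooled Dice-vs-threshold profile has a
# single near-symmetric peak at `c0`: annotated voxels score U(c0, 1),
# healthy voxels U(0, c0).
threshold_fixture <- function(seed, c0 = 0.44, d = c(20, 20, 20)) {
  set.seed(seed)
  n <- prod(d)
  annot <- array(0, d)
  annot[, , seq_len(d[3] / 2)] <- 1
  res <- array(0, d)
  res[annot == 0] <- runif(n / 2, 0, c0)
  res[annot == 1] <- runif(n / 2, c0, 1)
  list(res = res, annot = annot)
}
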