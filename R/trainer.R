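#' Training configuration
#'
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param optimizer Only `"adam"` is implemented.
#' @param max_epochs Number of training epochs to run; the returned model is
#'   the checkpoint of the epoch with the best healthy-validation
#'   reconstruction error.
#' @param kl_weight Weight of the KL term in the loss (default 1).
#' @param erasing An [erasing_config()] applied to network inputs only.
#' @param seed Training seed (shuffling, erasing draws, latent noise).
#' @param subset_fraction Train on a seed-deterministic nested subset of the
#'   training set (1 = all data); subsets for increasing fractions are
#'   nested, supporting data-set-size ablations.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 0.001,
                         optimizer = "adam", max_epochs = 10L,
                         kl_weight = 1, erasing = erasing_config("none"),
                         seed = 1L, subset_fraction = 1) {
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  assert_that(learning_rate > 0, "learning_rate must be > 0")
  assert_that(identical(optimizer, "adam"), "only adam is implemented")
  assert_that(max_epochs >= 1, "max_epochs must be >= 1")
  assert_that(subset_fraction > 0 && subset_fraction <= 1,
              "subset_fraction must be in (0, 1]")
  assert_that(inherits(erasing, "erasing_config"),
              "erasing must be an erasing_config")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 max_epochs = as.integer(max_epochs), kl_weight = kl_weight,
                 erasing = erasing, seed = as.integer(seed),
                 subset_fraction = subset_fraction),
            class = "train_config")
}

#' Seed-deterministic nested training subset
#'
#' Indices of the first `ceiling(fraction * n)` elements of a seeded
#' permutation, so subsets for increasing fractions are nested
#' (10% of the data is contained in the 20% subset, and so on), supporting
#' data-set-size ablations.
#'
#' @param n Training-set size.
#' @param fraction Fraction in (0, 1].
#' @param seed Training seed.
#' @return Integer index vector.
#' @export
training_subset <- function(n, fraction, seed) {
  assert_that(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  sel <- with_seed(derive_seed(seed, 11L), sample(n))
  sel[seq_len(ceiling(fraction * n))]
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

#' Slice stream for 2D training
#'
#' Yields all axial slices (axis 3) of the given volumes, shuffled with the
#' seed; the slice count equals the summed axial extents.
#'
#' @param volumes List of 3D arrays.
#' @param seed Shuffle seed.
#' @return List of 2D arrays.
#' @export
make_2d_training_stream <- function(volumes, seed = 1L) {
  slices <- unlist(lapply(volumes, extract_slices, axis = 3),
                   recursive = FALSE)
  with_seed(seed, slices[sample(length(slices))])
}

#' Train a VAE on healthy data with input erasing
#'
#' Each epoch erases every training sample's network input per the erasing
#' configuration, computes the l1 + KL loss against the unmodified target,
#' and takes Adam steps. After every epoch the un-erased reconstruction l1
#' on the healthy validation set is evaluated; the returned model is the
#' weight snapshot of the epoch minimizing that validation error.
#'
#' @param train_set List of healthy arrays matching the network rank
#'   (volumes for rank 3, slices for rank 2).
#' @param val_set Healthy validation arrays (disjoint from `train_set`).
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch log lines to stderr.
#' @return An object of class `vae_train`: `model` (best epoch), `log`
#'   (tibble: epoch, train_recon, train_kl, train_loss, val_recon),
#'   `selected_epoch`, and the configurations.
#' @export
train_vae <- function(train_set, val_set, net_cfg = network_config(),
                      train_cfg = train_config(), verbose = FALSE) {
  assert_that(length(train_set) > 0, "training set is empty")
  assert_that(length(val_set) > 0, "validation set is empty")
  train_set <- train_set[training_subset(length(train_set),
                                         train_cfg$subset_fraction,
                                         train_cfg$seed)]
  model <- vae_init(net_cfg)
  flat <- flatten_params(model)
  state <- adam_init(flat)
  n <- length(train_set)
  log_rows <- vector("list", train_cfg$max_epochs)
  best_val <- Inf
  best_flat <- flat
  selected <- 1L
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- with_seed(derive_seed(train_cfg$seed, 100L + epoch), sample(n))
    with_seed(derive_seed(train_cfg$seed, 10000L + epoch), {
      ep_recon <- 0
      ep_kl <- 0
      n_batches <- 0L
      starts <- seq(1, n, by = train_cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + train_cfg$batch_size - 1L, n)]
        B <- length(idx)
        grads_sum <- NULL
        b_recon <- 0
        b_kl <- 0
        for (ii in idx) {
          x <- train_set[[ii]]
          er <- apply_erasing(x, train_cfg$erasing)
          fw <- vae_forward_sample(model, er$input, sample = TRUE,
                                   keep_cache = TRUE)
          n_el <- length(x)
          resid <- fw$x_hat - er$target
          recon <- mean(abs(resid))
          kl <- 0.5 * sum(fw$mu^2 + exp(fw$logvar) - 1 - fw$logvar)
          if (!is.finite(recon) || !is.finite(kl)) {
            rlang::abort(sprintf(
              "non-finite loss at epoch %d (recon=%g, kl=%g); training aborted",
              epoch, recon, kl),
              class = c("erasevae_divergence_error", "erasevae_error"))
          }
          d_xhat <- sign(resid) / (n_el * B)
          kw <- train_cfg$kl_weight / B
          g <- vae_backward_sample(model, fw, d_xhat,
                                   d_mu_extra = kw * fw$mu,
                                   d_lv_extra = kw * 0.5 *
                                     (exp(fw$logvar) - 1))
          grads_sum <- if (is.null(grads_sum)) {
            g
          } else {
            mapply(`+`, grads_sum, g, SIMPLIFY = FALSE)
          }
          b_recon <- b_recon + recon / B
          b_kl <- b_kl + kl / B
        }
        upd <- adam_step(flat, grads_sum, state, train_cfg$learning_rate)
        flat <- upd$flat
        state <- upd$state
        model <- unflatten_params(model, flat)
        ep_recon <- ep_recon + b_recon
        ep_kl <- ep_kl + b_kl
        n_batches <- n_batches + 1L
      }
      ep_recon <- ep_recon / n_batches
      ep_kl <- ep_kl / n_batches
    })
    val_recon <- mean(vapply(val_set, function(v) {
      recon_l1(v, reconstruct(model, v))
    }, numeric(1)))
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, train_recon = ep_recon, train_kl = ep_kl,
      train_loss = ep_recon + train_cfg$kl_weight * ep_kl,
      val_recon = val_recon)
    if (verbose) {
      message(sprintf(
        "epoch %3d | train l1 %.5f | train KL %.3f | val l1 %.5f",
        epoch, ep_recon, ep_kl, val_recon))
    }
    if (val_recon < best_val) {
      best_val <- val_recon
      best_flat <- flat
      selected <- epoch
    }
  }
  structure(list(model = unflatten_params(model, best_flat),
                 log = dplyr::bind_rows(log_rows),
                 selected_epoch = selected, net_cfg = net_cfg,
                 train_cfg = train_cfg),
            class = "vae_train")
}

#' @export
print.vae_train <- function(x, ...) {
  cat(sprintf(
    "<vae_train> %d epochs, selected epoch %d (val l1 %.5f)\n",
    nrow(x$log), x$selected_epoch, x$log$val_recon[x$selected_epoch]))
  invisible(x)
}

#' @export
tidy.vae_train <- function(x, ...) {
  tidyr::pivot_longer(x$log, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' @export
glance.vae_train <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), selected_epoch = x$selected_epoch,
                 best_val_recon = min(x$log$val_recon),
                 final_train_loss = x$log$train_loss[nrow(x$log)],
                 n_params = count_params(x$model))
}

#' @export
autoplot.vae_train <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_epoch,
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "VAE training curves (dashed: selected epoch)") +
    ggplot2::theme_minimal()
}
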