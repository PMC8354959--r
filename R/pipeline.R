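# Workflow glue: manifest handling, cohort loading, the end-to-end pipeline
# used by the command-line interface, and the in-memory synthetic recovery
# experiment.

#' Synthetic lesion-recovery experiment
#'
#' Runs the whole method at a reduced problem size, in memory: trains a 3D
#' VAE on healthy phantoms with input erasing, calibrates the binarization
#' threshold on annotated lesioned phantoms by greedy search, segments a
#' held-out lesioned set, and compares against two reference baselines — the
#' all-brain-positive segmentation and a permutation baseline that shuffles
#' each residual map within the eroded brain mask before thresholding.
#'
#' @param seed Master seed for phantoms, training and baselines.
#' @param n_train,n_val Healthy training/validation phantom counts.
#' @param n_calib,n_test Lesioned calibration/held-out counts.
#' @param grid Phantom grid size (default 32).
#' @param latent_dim,stage_channels Reduced VAE size (defaults 64 and
#'   16/32/64/128).
#' @param epochs,batch_size,learning_rate Training budget.
#' @param erasing Erasing configuration (default: single cube, noise fill,
#'   probability 0.5).
#' @param verbose Log training progress.
#' @return List with `report` (`metrics_report`), `search`
#'   (`threshold_search`), `fit` (`vae_train`), `baseline_allpos_dice`,
#'   `baseline_permuted_dice`, `residual_lesion_mean`,
#'   `residual_healthy_mean` and cohort sizes.
#' @export
recovery_experiment <- function(seed = 1L, n_train = 180, n_val = 20,
                                n_calib = 20, n_test = 20, grid = 32,
                                latent_dim = 64,
                                stage_channels = c(16, 32, 64, 128),
                                epochs = 6, batch_size = 8,
                                learning_rate = 0.001,
                                erasing = erasing_config("single", "noise"),
                                verbose = FALSE) {
  spec <- phantom_spec(grid_size = grid, seed = seed)
  lspec <- lesion_spec(n_lesions = 2, radius_range = c(2.5, 5),
                       intensity_shift = 0.35, seed = seed)
  healthy <- lapply(seq_len(n_train + n_val), function(i) {
    s <- spec
    s$seed <- derive_seed(seed, i)
    generate_healthy(s)$volume
  })
  lesioned <- lapply(seq_len(n_calib + n_test), function(i) {
    s <- spec
    s$seed <- derive_seed(seed, 100000L + i)
    ph <- generate_healthy(s)
    ls <- lspec
    ls$seed <- derive_seed(seed, 200000L + i)
    les <- insert_lesions(ph$volume, ph$mask, ls)
    list(volume = les$volume, mask = ph$mask, annotation = les$annotation)
  })
  net_cfg <- network_config(rank = 3, input_extent = grid,
                            latent_dim = latent_dim,
                            stage_channels = stage_channels,
                            seed = derive_seed(seed, 31L))
  train_cfg <- train_config(batch_size = batch_size,
                            learning_rate = learning_rate,
                            max_epochs = epochs, erasing = erasing,
                            seed = derive_seed(seed, 32L))
  fit <- train_vae(healthy[seq_len(n_train)],
                   healthy[n_train + seq_len(n_val)],
                   net_cfg, train_cfg, verbose = verbose)
  resid_of <- function(s) {
    x_hat <- reconstruct_volume(fit$model, s$volume)
    postprocess_residual(residual_map(s$volume, x_hat), s$mask, 1, 3)
  }
  calib <- lesioned[seq_len(n_calib)]
  test <- lesioned[n_calib + seq_len(n_test)]
  calib_res <- lapply(calib, resid_of)
  search <- greedy_threshold_search(calib_res,
                                    lapply(calib, `[[`, "annotation"))
  test_recon <- lapply(test, function(s) reconstruct_volume(fit$model,
                                                            s$volume))
  test_res <- lapply(seq_along(test), function(i) {
    postprocess_residual(residual_map(test[[i]]$volume, test_recon[[i]]),
                         test[[i]]$mask, 1, 3)
  })
  annots <- lapply(test, `[[`, "annotation")
  preds <- lapply(test_res, binarize, threshold = search$best_threshold)
  report <- evaluate_segmentation(preds, annots, residuals = test_res,
                                  volumes = lapply(test, `[[`, "volume"),
                                  reconstructions = test_recon,
                                  masks = lapply(test, `[[`, "mask"))
  eroded <- lapply(test, function(s) erode_mask(s$mask, 1))
  allpos <- dice_subjects(eroded, annots)$mean
  permuted <- with_seed(derive_seed(seed, 33L), {
    perm_preds <- lapply(seq_along(test), function(i) {
      r <- test_res[[i]]
      inside <- eroded[[i]] == 1
      r[inside] <- sample(r[inside])
      binarize(r, search$best_threshold)
    })
    dice_subjects(perm_preds, annots)$mean
  })
  lesion_vals <- unlist(lapply(seq_along(test), function(i) {
    test_res[[i]][annots[[i]] == 1 & eroded[[i]] == 1]
  }))
  healthy_vals <- unlist(lapply(seq_along(test), function(i) {
    test_res[[i]][annots[[i]] == 0 & eroded[[i]] == 1]
  }))
  list(report = report, search = search, fit = fit,
       baseline_allpos_dice = allpos, baseline_permuted_dice = permuted,
       residual_lesion_mean = mean(lesion_vals),
       residual_healthy_mean = mean(healthy_vals),
       n_train = n_train, n_val = n_val, n_calib = n_calib, n_test = n_test,
       grid = grid)
}

#' Read a cohort manifest
#'
#' @param path Path to a `manifest.csv` written by [generate_cohort()].
#' @return Tibble with columns `path`, `mask_path`, `annotation_path`,
#'   `role`, `seed`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf(
      "manifest '%s' not found; run generate_cohort() (CLI: make-phantoms) first",
      path), class = c("erasevae_io_error", "erasevae_error"))
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Load cohort volumes for a role
#'
#' @param manifest Manifest tibble from [read_manifest()].
#' @param role Role to select (`train`, `val-healthy`, `val-anom`, `test`).
#' @return List with `volumes`, `masks` and `annotations` (lists of arrays;
#'   annotations `NULL` where absent).
#' @export
load_cohort <- function(manifest, role) {
  rows <- dplyr::filter(manifest, .data$role == !!role)
  assert_that(nrow(rows) > 0, sprintf("no subjects with role '%s'", role))
  vols <- lapply(rows$path, function(p) load_volume(p)$data)
  masks <- lapply(rows$mask_path, function(p) {
    (load_volume(p)$data > 0.5) * 1
  })
  annots <- lapply(rows$annotation_path, function(p) {
    if (is.na(p)) NULL else (load_volume(p)$data > 0.5) * 1
  })
  list(volumes = vols, masks = masks, annotations = annots)
}

#' Run the full anomaly-segmentation pipeline on a phantom cohort
#'
#' Generates (or reuses) a phantom cohort, trains the configured VAE on
#' healthy volumes with input erasing, selects the epoch on the healthy
#' validation reconstruction, calibrates the binarization threshold on the
#' annotated calibration split by greedy search, segments the test split and
#' evaluates voxel-wise and slice-wise metrics.
#'
#' @param work_dir Run directory; the cohort goes to `work_dir/cohort`,
#'   outputs next to it.
#' @param n_healthy,n_lesioned Cohort sizes.
#' @param spec,lspec Phantom and lesion specifications.
#' @param net_cfg,train_cfg Network and training configurations.
#' @param erosion_radius,median_size Residual post-processing parameters.
#' @param iterations Greedy-search iterations.
#' @param seed Master seed.
#' @param verbose Log per-epoch progress.
#' @return List with `fit` (`vae_train`), `search` (`threshold_search`),
#'   `report` (`metrics_report`) and `manifest`.
#' @export
run_pipeline <- function(work_dir, n_healthy = 60, n_lesioned = 20,
                         spec = phantom_spec(), lspec = lesion_spec(),
                         net_cfg = network_config(), train_cfg = train_config(),
                         erosion_radius = 1, median_size = 3,
                         iterations = 10, seed = 1L, verbose = FALSE) {
  cohort_dir <- file.path(work_dir, "cohort")
  manifest_path <- file.path(cohort_dir, "manifest.csv")
  manifest <- if (file.exists(manifest_path)) {
    read_manifest(manifest_path)
  } else {
    generate_cohort(cohort_dir, n_healthy, n_lesioned, spec, lspec,
                    seed = seed)
  }
  train <- load_cohort(manifest, "train")
  val_h <- load_cohort(manifest, "val-healthy")
  calib <- load_cohort(manifest, "val-anom")
  test <- load_cohort(manifest, "test")

  train_in <- train$volumes
  val_in <- val_h$volumes
  if (net_cfg$rank == 2) {
    train_in <- make_2d_training_stream(train$volumes,
                                        seed = derive_seed(seed, 21L))
    val_in <- make_2d_training_stream(val_h$volumes,
                                      seed = derive_seed(seed, 22L))
  }
  fit <- train_vae(train_in, val_in, net_cfg, train_cfg, verbose = verbose)

  seg_residual <- function(set) {
    lapply(seq_along(set$volumes), function(i) {
      x_hat <- reconstruct_volume(fit$model, set$volumes[[i]])
      postprocess_residual(residual_map(set$volumes[[i]], x_hat),
                           set$masks[[i]], erosion_radius, median_size)
    })
  }
  calib_res <- seg_residual(calib)
  search <- greedy_threshold_search(calib_res, calib$annotations,
                                    iterations = iterations)
  test_recon <- lapply(test$volumes,
                       function(v) reconstruct_volume(fit$model, v))
  test_res <- lapply(seq_along(test$volumes), function(i) {
    postprocess_residual(residual_map(test$volumes[[i]], test_recon[[i]]),
                         test$masks[[i]], erosion_radius, median_size)
  })
  preds <- lapply(test_res, binarize, threshold = search$best_threshold)
  report <- evaluate_segmentation(preds, test$annotations,
                                  residuals = test_res,
                                  volumes = test$volumes,
                                  reconstructions = test_recon,
                                  masks = test$masks)
  list(fit = fit, search = search, report = report, manifest = manifest)
}
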