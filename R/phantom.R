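#' Specification of a synthetic brain phantom
#'
#' Describes a skull-stripped, intensity-normalized, approximately bilaterally
#' symmetric brain-like volume: an outer ellipsoidal "brain" containing a
#' bright white-matter-like shell, a dark mirrored ventricle-like pair, and
#' further mirrored pairs of random internal substructures, smoothed with a
#' Gaussian kernel. Intensities live in \[0, 1\] and the background is 0, as
#' in preprocessed T1-weighted training data.
#'
#' @param grid_size Cubic volume extent per axis in voxels (default 64).
#' @param brain_axes Ellipsoid semi-axes in voxels; default scales
#'   `c(0.42, 0.34, 0.38) * grid_size` so the brain fits with margin.
#' @param n_substructures Number of additional mirrored substructure pairs.
#' @param noise_sigma Standard deviation of additive in-brain intensity noise.
#' @param symmetry_jitter Maximum per-axis voxel displacement applied to the
#'   mirrored copy of each substructure; `0` gives exact left-right symmetry.
#' @param seed Integer seed controlling every random choice of the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 64L, brain_axes = NULL,
                         n_substructures = 3L, noise_sigma = 0.02,
                         symmetry_jitter = 0, seed = 1L) {
  grid_size <- as.integer(grid_size)
  assert_that(grid_size >= 16L, "grid_size must be >= 16")
  if (is.null(brain_axes)) brain_axes <- c(0.42, 0.34, 0.38) * grid_size
  assert_that(length(brain_axes) == 3 && all(brain_axes > 0),
              "brain_axes must be 3 positive semi-axes")
  assert_that(all(2 * brain_axes < grid_size),
              "brain ellipsoid must fit inside the grid")
  assert_that(noise_sigma >= 0 && noise_sigma < 0.5,
              "noise_sigma must be in [0, 0.5)")
  assert_that(symmetry_jitter >= 0, "symmetry_jitter must be >= 0")
  structure(list(grid_size = grid_size, brain_axes = brain_axes,
                 n_substructures = as.integer(n_substructures),
                 noise_sigma = noise_sigma,
                 symmetry_jitter = symmetry_jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ellipsoid indicator on the voxel grid, evaluated analytically so that a
# center mirrored about the volume midline yields an exactly mirrored field.
ellipsoid_field <- function(g, center, axes) {
  x <- seq_len(g)
  dx2 <- ((x - center[1]) / axes[1])^2
  dy2 <- ((x - center[2]) / axes[2])^2
  dz2 <- ((x - center[3]) / axes[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  (r2 <= 1) * 1
}

#' Generate a healthy synthetic brain volume
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (3D array, values in \[0, 1\]) and `mask`
#'   (binary brain mask, the support of the phantom). Identical seeds give
#'   bit-identical output.
#' @export
generate_healthy <- function(spec) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  g <- spec$grid_size
  ctr <- rep((g + 1) / 2, 3)
  with_seed(spec$seed, {
    brain <- ellipsoid_field(g, ctr, spec$brain_axes)
    vol <- 0.45 * brain
    # white-matter-like bright shell: between 35% and 75% of the brain radius
    inner <- ellipsoid_field(g, ctr, 0.75 * spec$brain_axes)
    core <- ellipsoid_field(g, ctr, 0.35 * spec$brain_axes)
    vol[inner == 1 & core == 0] <- 0.72
    # ventricle-like dark mirrored pair near the center
    voff <- c(0.14, 0.05, 0.05) * g
    vax <- c(0.045, 0.10, 0.16) * g
    for (s in c(-1, 1)) {
      vent <- ellipsoid_field(g, ctr + c(s * voff[1], voff[2], voff[3]), vax)
      vol[vent == 1] <- 0.12
    }
    # additional mirrored substructure pairs
    for (i in seq_len(spec$n_substructures)) {
      off <- c(runif(1, 0.10, 0.28), runif(1, -0.18, 0.18),
               runif(1, -0.20, 0.20)) * g
      ax <- runif(3, 0.03, 0.08) * g
      val <- runif(1, 0.30, 0.85)
      jit <- if (spec$symmetry_jitter > 0) {
        runif(3, -spec$symmetry_jitter, spec$symmetry_jitter)
      } else {
        c(0, 0, 0)
      }
      s1 <- ellipsoid_field(g, ctr + c(off[1], off[2], off[3]), ax)
      s2 <- ellipsoid_field(g, ctr + c(-off[1], off[2], off[3]) + jit, ax)
      vol[s1 == 1] <- val
      vol[s2 == 1] <- val
    }
    vol <- gaussian_smooth(vol, sigma = 1) * brain
    if (spec$noise_sigma > 0) {
      noise <- array(rnorm(g^3, sd = spec$noise_sigma), dim = dim(vol))
      vol <- vol + noise * brain
    }
    list(volume = clip01(vol), mask = brain)
  })
}

#' Specification of synthetic lesions
#'
#' Lesions are spherical blobs whose radius is perturbed by low-order
#' directional harmonics (so they are not perfect spheres), with a smooth
#' random interior texture, placed strictly inside the brain mask.
#'
#' @param n_lesions Number of lesions to insert (>= 1).
#' @param radius_range Min/max base radius in voxels.
#' @param intensity_shift Signed intensity contrast in \[-1, 1\] added inside
#'   the lesion before clipping to \[0, 1\].
#' @param texture_sigma Gaussian smoothness (voxels) of the interior texture.
#' @param seed Integer seed.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(n_lesions = 2L, radius_range = c(3, 6),
                        intensity_shift = 0.35, texture_sigma = 1,
                        seed = 1L) {
  assert_that(n_lesions >= 1, "n_lesions must be >= 1")
  assert_that(length(radius_range) == 2 && radius_range[1] > 0 &&
                radius_range[1] <= radius_range[2],
              "radius_range must be an increasing positive pair")
  assert_that(abs(intensity_shift) <= 1, "intensity_shift must be in [-1, 1]")
  structure(list(n_lesions = as.integer(n_lesions),
                 radius_range = radius_range,
                 intensity_shift = intensity_shift,
                 texture_sigma = texture_sigma, seed = as.integer(seed)),
            class = "lesion_spec")
}

# Voxel offsets of one harmonic-perturbed blob centered at `center`,
# as an index matrix into a grid of size g.
blob_voxels <- function(g, center, r0, coefs) {
  R <- ceiling(r0 * 1.5)
  rng <- lapply(center, function(c0) {
    seq(max(1, floor(c0 - R)), min(g, ceiling(c0 + R)))
  })
  grid <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  dx <- grid$x - center[1]
  dy <- grid$y - center[2]
  dz <- grid$z - center[3]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  u <- ifelse(dist > 0, dx / dist, 0)
  v <- ifelse(dist > 0, dy / dist, 0)
  w <- ifelse(dist > 0, dz / dist, 0)
  pert <- coefs[1] * u + coefs[2] * v + coefs[3] * w +
    coefs[4] * u * v + coefs[5] * u * w + coefs[6] * v * w
  keep <- dist <= r0 * (1 + pert)
  as.matrix(grid[keep, , drop = FALSE])
}

#' Insert lesions into a healthy volume
#'
#' @param vol Healthy volume (3D array in \[0, 1\]).
#' @param mask Binary brain mask aligned to `vol`.
#' @param lspec A [lesion_spec()].
#' @param max_tries Placement retries per lesion before failing.
#' @return A list with `volume` (lesioned, clipped to \[0, 1\]) and
#'   `annotation` (binary ground-truth mask, a subset of the brain mask).
#'   Voxels outside the annotation are bit-identical to the input.
#' @export
insert_lesions <- function(vol, mask, lspec, max_tries = 200L) {
  assert_that(inherits(lspec, "lesion_spec"), "lspec must be a lesion_spec")
  mask <- as_binary_array(mask)
  assert_that(identical(dim(vol), dim(mask)), "volume/mask shape mismatch")
  g <- dim(vol)[1]
  assert_that(2 * lspec$radius_range[2] < g, "lesion radii must fit the grid")
  annotation <- array(0, dim = dim(vol))
  out <- vol
  in_mask <- which(mask == 1, arr.ind = TRUE)
  with_seed(lspec$seed, {
    for (i in seq_len(lspec$n_lesions)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- runif(1, lspec$radius_range[1], lspec$radius_range[2])
        coefs <- runif(6, -0.12, 0.12)
        center <- in_mask[sample.int(nrow(in_mask), 1L), ] +
          runif(3, -0.5, 0.5)
        vox <- blob_voxels(g, center, r0, coefs)
        if (nrow(vox) == 0) next
        inside <- mask[vox] == 1
        if (!all(inside)) next
        # reject contact (within one voxel, Chebyshev) with earlier lesions so
        # lesions stay disjoint connected components
        near <- FALSE
        if (sum(annotation) > 0) {
          prev <- which(annotation == 1, arr.ind = TRUE)
          for (j in seq_len(nrow(vox))) {
            cheb <- pmax(abs(prev[, 1] - vox[j, 1]),
                         pmax(abs(prev[, 2] - vox[j, 2]),
                              abs(prev[, 3] - vox[j, 3])))
            if (any(cheb <= 1)) { near <- TRUE; break }
          }
        }
        if (near) next
        # smooth interior texture in (0.5, 1], scaling the contrast
        box <- apply(vox, 2, range)
        bd <- box[2, ] - box[1, ] + 1
        tex_raw <- array(runif(prod(bd), -1, 1), dim = bd)
        tex_s <- gaussian_smooth(tex_raw, lspec$texture_sigma)
        loc <- cbind(vox[, 1] - box[1, 1] + 1, vox[, 2] - box[1, 2] + 1,
                     vox[, 3] - box[1, 3] + 1)
        tvals <- tex_s[loc]
        rng_t <- range(tvals)
        tex <- if (diff(rng_t) > 0) {
          0.5 + 0.5 * (tvals - rng_t[1]) / diff(rng_t)
        } else {
          rep(1, length(tvals))
        }
        out[vox] <- clip01(out[vox] + lspec$intensity_shift * tex)
        annotation[vox] <- 1
        placed <- TRUE
        break
      }
      if (!placed) {
        abort_bad(sprintf("could not place lesion %d inside the mask", i),
                  class = "erasevae_placement_error")
      }
    }
  })
  list(volume = out, annotation = annotation)
}

#' Generate a phantom cohort on disk
#'
#' Writes NIfTI volumes, brain masks and (for lesioned subjects) annotation
#' masks, together with a headered CSV manifest. Healthy subjects are split
#' into `train` and `val-healthy` roles; lesioned subjects into `val-anom`
#' (threshold calibration) and `test`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_healthy,n_lesioned Subject counts (>= 0).
#' @param spec Cohort-level [phantom_spec()]; each subject reuses it with a
#'   subject-specific derived seed.
#' @param lspec [lesion_spec()] for lesioned subjects (subject-derived seeds).
#' @param seed Master seed; identical seeds reproduce identical files.
#' @param healthy_val_frac Fraction of healthy subjects assigned `val-healthy`.
#' @param calib_frac Fraction of lesioned subjects assigned `val-anom`.
#' @return A tibble manifest with columns `path`, `mask_path`,
#'   `annotation_path`, `role`, `seed`; also written as `manifest.csv`.
#' @export
generate_cohort <- function(out_dir, n_healthy, n_lesioned,
                            spec = phantom_spec(), lspec = lesion_spec(),
                            seed = 1L, healthy_val_frac = 0.2,
                            calib_frac = 0.5) {
  assert_that(n_healthy >= 0 && n_lesioned >= 0, "counts must be >= 0")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      rlang::abort(sprintf("cannot create output directory '%s'", out_dir),
                   class = c("erasevae_io_error", "erasevae_error"))
    }
  }
  n <- n_healthy + n_lesioned
  rows <- vector("list", n)
  n_val_h <- round(healthy_val_frac * n_healthy)
  n_calib <- round(calib_frac * n_lesioned)
  for (i in seq_len(n)) {
    sub_seed <- derive_seed(seed, i)
    healthy <- i <= n_healthy
    role <- if (healthy) {
      if (i > n_healthy - n_val_h) "val-healthy" else "train"
    } else {
      if (i - n_healthy <= n_calib) "val-anom" else "test"
    }
    sspec <- spec
    sspec$seed <- sub_seed
    ph <- generate_healthy(sspec)
    base <- file.path(out_dir, sprintf("sub-%04d", i))
    vol_path <- paste0(base, ".nii.gz")
    mask_path <- paste0(base, "_mask.nii.gz")
    annot_path <- NA_character_
    if (!healthy) {
      slspec <- lspec
      slspec$seed <- derive_seed(sub_seed, 7919L)
      les <- insert_lesions(ph$volume, ph$mask, slspec)
      ph$volume <- les$volume
      annot_path <- paste0(base, "_annot.nii.gz")
      save_volume(les$annotation, annot_path)
    }
    save_volume(ph$volume, vol_path)
    save_volume(ph$mask, mask_path)
    rows[[i]] <- tibble::tibble(path = vol_path, mask_path = mask_path,
                                annotation_path = annot_path, role = role,
                                seed = sub_seed)
  }
  manifest <- dplyr::bind_rows(rows)
  if (n == 0) {
    manifest <- tibble::tibble(path = character(), mask_path = character(),
                               annotation_path = character(),
                               role = character(), seed = integer())
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
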