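#' Spatial erasing configuration
#'
#' Configures the structured input-erasing augmentation: a single random
#' patch/cube, multiple patches/cubes, or one lateral brain half (in a random
#' axial slab for volumes), filled with zeros or with noise sampled from the
#' image's own intensity distribution. Erasing is applied to the network
#' input only; the optimization target stays untouched, so training becomes a
#' partial in-painting task.
#'
#' @param strategy One of `"none"`, `"single"`, `"multi"`, `"half"`.
#' @param fill `"zero"` or `"noise"` (i.i.d. draws from the image's own
#'   element values).
#' @param apply_prob Probability of applying erasing to a sample (default
#'   0.5, so the network still sees unmodified images).
#' @param budget_range Erased-size interval as a fraction of the total
#'   element count (default 1% to 25%); applies to `single` and `multi`.
#' @param max_regions Maximum region count for `multi` (default 10).
#' @param slab_range Axial slab extent interval for 3D `half` (default 1-32
#'   consecutive slices).
#' @return An object of class `erasing_config`.
#' @export
erasing_config <- function(strategy = c("none", "single", "multi", "half"),
                           fill = c("zero", "noise"), apply_prob = 0.5,
                           budget_range = c(0.01, 0.25), max_regions = 10L,
                           slab_range = c(1L, 32L)) {
  strategy <- match.arg(strategy)
  fill <- match.arg(fill)
  assert_that(apply_prob >= 0 && apply_prob <= 1,
              "apply_prob must be in [0, 1]")
  assert_that(length(budget_range) == 2 && budget_range[1] > 0 &&
                budget_range[1] <= budget_range[2] && budget_range[2] < 1,
              "budget_range must satisfy 0 < lo <= hi < 1")
  assert_that(max_regions >= 1, "max_regions must be >= 1")
  assert_that(length(slab_range) == 2 && slab_range[1] >= 1 &&
                slab_range[1] <= slab_range[2],
              "slab_range must be an increasing interval of >= 1")
  structure(list(strategy = strategy, fill = fill, apply_prob = apply_prob,
                 budget_range = budget_range,
                 max_regions = as.integer(max_regions),
                 slab_range = as.integer(slab_range)),
            class = "erasing_config")
}

new_erased_sample <- function(input, target, erase_mask, nominal_size = 0,
                              n_regions = 0L) {
  structure(list(input = input, target = target, erase_mask = erase_mask,
                 nominal_size = nominal_size, n_regions = as.integer(n_regions)),
            class = "erased_sample")
}

#' @export
print.erased_sample <- function(x, ...) {
  cat(sprintf("<erased_sample> %s, %d elements erased (nominal %d)\n",
              paste(dim(x$input), collapse = "x"), sum(x$erase_mask),
              x$nominal_size))
  invisible(x)
}

# Integer region side lengths whose product lands on `budget_n` elements:
# raw per-axis lengths are log-uniform, rescaled so their product hits the
# drawn budget, rounded, then nudged so the product stays in [lo_n, hi_n].
draw_region_lengths <- function(dims, budget_n, lo_n, hi_n) {
  r <- length(dims)
  raw <- exp(runif(r, log(1), log(dims)))
  scale <- (budget_n / prod(raw))^(1 / r)
  lens <- pmin(pmax(round(raw * scale), 1), dims)
  repeat {
    p <- prod(lens)
    if (p > hi_n && any(lens > 1)) {
      i <- which.max(lens)
      lens[i] <- lens[i] - 1
    } else if (p < lo_n && any(lens < dims)) {
      cand <- which(lens < dims)
      i <- cand[which.min(lens[cand])]
      lens[i] <- lens[i] + 1
    } else {
      break
    }
  }
  lens
}

# Place a region of side lengths `lens` at a uniformly drawn center; the
# region is clipped at the borders (the nominal size is the pre-clip size).
place_region <- function(dims, lens) {
  center <- vapply(dims, function(d) sample.int(d, 1L), integer(1))
  lo <- pmax(center - floor((lens - 1) / 2), 1)
  hi <- pmin(center + ceiling((lens - 1) / 2), dims)
  mask <- array(FALSE, dim = dims)
  idx <- lapply(seq_along(dims), function(a) lo[a]:hi[a])
  do.call(`[<-`, c(list(mask), idx, list(TRUE)))
}

#' Fill erased elements
#'
#' @param img Numeric array (2D or 3D).
#' @param erase_mask Logical array of elements to fill.
#' @param fill `"zero"` writes exact 0; `"noise"` writes i.i.d. draws (with
#'   replacement) from the multiset of the image's own element values.
#' @return The filled image.
#' @export
fill_region <- function(img, erase_mask, fill = c("zero", "noise")) {
  fill <- match.arg(fill)
  assert_that(identical(dim(img), dim(erase_mask)),
              "image/erase mask shape mismatch")
  n <- sum(erase_mask)
  if (n == 0) return(img)
  img[erase_mask] <- if (fill == "zero") {
    0
  } else {
    sample(as.vector(img), n, replace = TRUE)
  }
  img
}

#' Erase a single random patch or cube
#'
#' One axis-aligned rectangle (2D) or cuboid (3D) with a random center and a
#' nominal size drawn between 1% and 25% of the total element count, clipped
#' at the image borders.
#'
#' @param img 2D or 3D numeric array.
#' @param cfg An [erasing_config()] with `strategy = "single"`.
#' @return An `erased_sample`: `input` (erased), `target` (bit-identical copy
#'   of `img`), `erase_mask`, and the nominal (pre-clip) erased size.
#' @export
erase_single <- function(img, cfg) {
  dims <- dim(img)
  n <- prod(dims)
  b <- runif(1, cfg$budget_range[1], cfg$budget_range[2])
  lens <- draw_region_lengths(dims, b * n, cfg$budget_range[1] * n,
                              cfg$budget_range[2] * n)
  mask <- place_region(dims, lens)
  new_erased_sample(fill_region(img, mask, cfg$fill), img, mask,
                    nominal_size = prod(lens), n_regions = 1L)
}

#' Erase multiple random patches or cubes
#'
#' Up to `max_regions` regions (count uniform in `1:max_regions`); the total
#' drawn budget is split over the regions by symmetric Dirichlet weights and
#' the summed nominal size stays within the 1%-25% budget. Regions may
#' overlap; the erase mask is their union.
#'
#' @inheritParams erase_single
#' @param cfg An [erasing_config()] with `strategy = "multi"`.
#' @return An `erased_sample`.
#' @export
erase_multi <- function(img, cfg) {
  dims <- dim(img)
  n <- prod(dims)
  m <- sample.int(cfg$max_regions, 1L)
  b <- runif(1, cfg$budget_range[1], cfg$budget_range[2])
  w <- rgamma(m, 1)
  w <- w / sum(w)
  lo_n <- cfg$budget_range[1] * n
  hi_n <- cfg$budget_range[2] * n
  lens <- lapply(seq_len(m), function(i) {
    r <- length(dims)
    raw <- exp(runif(r, log(1), log(dims)))
    scale <- (max(w[i] * b * n, 1) / prod(raw))^(1 / r)
    pmin(pmax(round(raw * scale), 1), dims)
  })
  # nudge the largest/smallest region so the summed nominal size stays in
  # budget (each region keeps at least one element)
  repeat {
    tot <- sum(vapply(lens, prod, numeric(1)))
    if (tot > hi_n) {
      sizes <- vapply(lens, prod, numeric(1))
      i <- which.max(sizes)
      if (all(lens[[i]] == 1)) break
      j <- which.max(lens[[i]])
      lens[[i]][j] <- lens[[i]][j] - 1
    } else if (tot < lo_n) {
      sizes <- vapply(lens, prod, numeric(1))
      i <- which.min(sizes)
      if (all(lens[[i]] == dims)) break
      cand <- which(lens[[i]] < dims)
      j <- cand[which.min(lens[[i]][cand])]
      lens[[i]][j] <- lens[[i]][j] + 1
    } else {
      break
    }
  }
  mask <- array(FALSE, dim = dims)
  for (i in seq_len(m)) mask <- mask | place_region(dims, lens[[i]])
  new_erased_sample(fill_region(img, mask, cfg$fill), img, mask,
                    nominal_size = sum(vapply(lens, prod, numeric(1))),
                    n_regions = m)
}

#' Erase one lateral brain half
#'
#' In 2D, one lateral half of the slice (left-right axis = axis 1) is erased.
#' In 3D, a contiguous axial slab of `k` slices (`k` uniform in `slab_range`)
#' has one lateral half erased; the side is chosen uniformly. The midline is
#' the geometric volume midline, as preprocessing centers the brain.
#'
#' @inheritParams erase_single
#' @param cfg An [erasing_config()] with `strategy = "half"`.
#' @return An `erased_sample`.
#' @export
erase_half <- function(img, cfg) {
  dims <- dim(img)
  r <- length(dims)
  half <- floor(dims[1] / 2)
  side <- sample(c("left", "right"), 1L)
  lr <- if (side == "left") 1:half else (half + 1):dims[1]
  mask <- array(FALSE, dim = dims)
  if (r == 2) {
    mask[lr, ] <- TRUE
  } else {
    assert_that(cfg$slab_range[2] <= dims[3],
                "slab_range exceeds the axial extent")
    k <- cfg$slab_range[1] +
      sample.int(cfg$slab_range[2] - cfg$slab_range[1] + 1L, 1L) - 1L
    start <- sample.int(dims[3] - k + 1L, 1L)
    mask[lr, , start:(start + k - 1L)] <- TRUE
  }
  new_erased_sample(fill_region(img, mask, cfg$fill), img, mask,
                    nominal_size = sum(mask), n_regions = 1L)
}

#' Apply the configured erasing strategy
#'
#' With probability `1 - apply_prob` (and always for `strategy = "none"`)
#' the input is returned unmodified with an empty erase mask; otherwise the
#' configured strategy is dispatched. The target is always a bit-identical
#' copy of `img`.
#'
#' @inheritParams erase_single
#' @param cfg An [erasing_config()].
#' @return An `erased_sample`.
#' @export
apply_erasing <- function(img, cfg) {
  assert_that(inherits(cfg, "erasing_config"),
              "cfg must be an erasing_config")
  identity_sample <- function() {
    new_erased_sample(img, img, array(FALSE, dim = dim(img)), 0)
  }
  if (cfg$strategy == "none") return(identity_sample())
  if (runif(1) >= cfg$apply_prob) return(identity_sample())
  switch(cfg$strategy,
         single = erase_single(img, cfg),
         multi = erase_multi(img, cfg),
         half = erase_half(img, cfg),
         abort_bad(sprintf("unknown erasing strategy '%s'", cfg$strategy)))
}
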