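# Shared internal helpers: seeded RNG scoping, array axis operations, binary
# morphology, and argument validation.

abort_bad <- function(msg, class = "erasevae_validation_error") {
  rlang::abort(msg, class = c(class, "erasevae_error"))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort_bad(msg)
  invisible(TRUE)
}

# Run `code` under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed, staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483587) + 1L
}

array_rank <- function(x) length(dim(x))

as_binary_array <- function(x, what = "mask") {
  v <- as.vector(x)
  assert_that(all(v %in% c(0, 1)), sprintf("%s must be binary (0/1)", what))
  array(as.numeric(v), dim = dim(x))
}

is_binaryish <- function(x) all(as.vector(x) %in% c(0, 1))

# Apply matrix M (n_out x n_axis) along one axis of an array.
apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  r <- length(d)
  perm <- c(axis, setdiff(seq_len(r), axis))
  x <- aperm(arr, perm)
  dim(x) <- c(d[axis], prod(d[-axis]))
  y <- M %*% x
  dim(y) <- c(nrow(M), d[perm[-1]])
  aperm(y, order(perm))
}

# Keys cubic-convolution (Catmull-Rom, a = -1/2) kernel.
keys_kernel <- function(t) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  i2 <- at > 1 & at < 2
  w[i1] <- 1.5 * at[i1]^3 - 2.5 * at[i1]^2 + 1
  w[i2] <- -0.5 * at[i2]^3 + 2.5 * at[i2]^2 - 4 * at[i2] + 2
  w
}

# Resampling matrix mapping n_in samples to n_out samples along one axis,
# center-aligned in physical coordinates, cubic interpolation with edge clamp.
cubic_resample_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (j in seq_len(n_out)) {
    u <- (j - 0.5) * scale - 0.5       # continuous 0-based input index
    i0 <- floor(u)
    for (m in -1:2) {
      i <- i0 + m
      w <- keys_kernel(u - i)
      ic <- min(max(i, 0), n_in - 1)   # clamp at edges
      M[j, ic + 1] <- M[j, ic + 1] + w
    }
  }
  M
}

# Separable Gaussian smoothing with zero-padded borders.
gaussian_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  h <- ceiling(3 * sigma)
  t <- (-h):h
  k <- exp(-t^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in seq_along(dim(arr))) {
    n <- dim(arr)[axis]
    M <- matrix(0, n, n)
    for (j in seq_len(n)) {
      idx <- j + t
      keep <- idx >= 1 & idx <= n
      M[j, idx[keep]] <- k[keep]
    }
    arr <- apply_axis(arr, M, axis)
  }
  arr
}

# One-step binary erosion with the 6-neighbourhood (4-neighbourhood in 2D);
# voxels beyond the array border count as background.
erode_once <- function(mask) {
  d <- dim(mask)
  r <- length(d)
  out <- mask
  for (axis in seq_len(r)) {
    for (s in c(-1L, 1L)) {
      shifted <- array(0, dim = d)
      idx_to <- lapply(d, seq_len)
      idx_from <- idx_to
      n <- d[axis]
      if (s == 1L) {
        idx_to[[axis]] <- seq_len(n - 1L)
        idx_from[[axis]] <- 2:n
      } else {
        idx_to[[axis]] <- 2:n
        idx_from[[axis]] <- seq_len(n - 1L)
      }
      shifted <- do.call(`[<-`, c(list(shifted), idx_to,
                                  list(do.call(`[`, c(list(mask), idx_from)))))
      out <- out * shifted
    }
  }
  out
}

#' Erode a binary mask
#'
#' Repeated one-voxel erosion with the face-connected (6-neighbourhood in 3D,
#' 4-neighbourhood in 2D) structuring element.
#'
#' @param mask Binary array.
#' @param radius Number of erosion passes; `0` returns the mask unchanged.
#' @return Binary array of the same shape.
#' @export
erode_mask <- function(mask, radius = 1) {
  mask <- as_binary_array(mask)
  assert_that(radius >= 0, "erosion radius must be >= 0")
  for (i in seq_len(radius)) mask <- erode_once(mask)
  mask
}

# Mirror an array along the left-right axis (axis 1).
mirror_lr <- function(arr) {
  d <- dim(arr)
  idx <- c(list(rev(seq_len(d[1]))), lapply(d[-1], seq_len))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
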