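# Internal helpers: seeded RNG scoping, derived sub-seeds, smooth random
# fields, separable Gaussian smoothing.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tabseg <- function(...) stop(sprintf(...), call. = FALSE)

assert_that_ <- function(ok, ...) if (!isTRUE(ok)) stop_tabseg(...)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Deterministically derive a child seed from (seed, k), kept inside 32-bit
# signed range. SplitMix-flavoured integer hash done in double precision.
derive_seed <- function(seed, k) {
  x <- (as.numeric(seed) * 2654435761 + as.numeric(k) * 40503 + 12345) %% 2147483647
  as.integer(x %% 2147483629 + 1)
}

# Smooth scalar field on a cubic grid: a seeded mixture of low-frequency
# cosine modes, rescaled to max |value| = 1. Frequencies <= max_cycles per
# field of view, so the field varies slowly across the volume.
smooth_field <- function(d, n_modes = 6L, max_cycles = 1.5, seed = 1L) {
  with_seed_(seed, {
    ax <- seq_len(d) - 1
    g <- array(0, dim = c(d, d, d))
    for (m in seq_len(n_modes)) {
      f <- stats::runif(3, 0.3, max_cycles) / d
      ph <- stats::runif(3, 0, 2 * pi)
      a <- stats::runif(1, 0.5, 1)
      cx <- cos(2 * pi * f[1] * ax + ph[1])
      cy <- cos(2 * pi * f[2] * ax + ph[2])
      cz <- cos(2 * pi * f[3] * ax + ph[3])
      g <- g + a * (outer(cx, cy) %o% cz)
    }
    g / max(abs(g))
  })
}

# 1D Gaussian kernel truncated at 3 sigma (odd length, normalized).
gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve a (d,d,d) array with a 1D kernel along one axis, zero padding.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)[1]
  r <- (length(kernel) - 1L) / 2L
  # banded d x d convolution matrix with zero boundary
  km <- matrix(0, d, d)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- seq_len(d)
    src <- idx + off
    keep <- src >= 1 & src <= d
    km[cbind(idx[keep], src[keep])] <- km[cbind(idx[keep], src[keep])] + kernel[j]
  }
  if (axis == 1L) {
    array(km %*% matrix(a, d, d * d), dim = dim(a))
  } else if (axis == 2L) {
    ap <- aperm(a, c(2, 1, 3))
    aperm(array(km %*% matrix(ap, d, d * d), dim = dim(a)), c(2, 1, 3))
  } else {
    ap <- aperm(a, c(3, 2, 1))
    aperm(array(km %*% matrix(ap, d, d * d), dim = dim(a)), c(3, 2, 1))
  }
}

# Separable 3D Gaussian smoothing (sigma in voxels); sigma = 0 is identity.
gauss_smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gauss_kernel1d(sigma)
  conv_axis(conv_axis(conv_axis(a, k, 1L), k, 2L), k, 3L)
}
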