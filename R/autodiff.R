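# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices, with fused primitives for the 3D operations the networks need.
#
# Feature maps are stored as (N_voxels, C) matrices in column-major voxel
# order (first spatial axis fastest). Convolution is realized as a cached
# im2col gather followed by one BLAS matrix multiply; its input gradient is
# again a gather-based convolution with the spatially flipped, channel-
# transposed kernel, so no scatter-add is ever needed on the hot path.

is_node <- function(x) inherits(x, "ad_node")

nd <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  class(e) <- "ad_node"
  e
}

val <- function(x) if (is_node(x)) x$value else x

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$ops <- vector("list", 256L)
  t$n <- 0L
  t
}

push_op <- function(tape, out, inputs, backward) {
  if (is.null(tape)) return(out)
  n <- tape$n + 1L
  if (n > length(tape$ops)) tape$ops <- c(tape$ops, vector("list", length(tape$ops)))
  tape$ops[[n]] <- list(out = out, inputs = inputs, backward = backward)
  tape$n <- n
  out
}

accumulate_grad <- function(node, g) {
  if (is.null(g) || !is_node(node)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Seed d(loss)/d(out_node) = dout and sweep the tape in reverse.
backprop <- function(tape, out_node, dout) {
  out_node$grad <- dout
  for (i in rev(seq_len(tape$n))) {
    rec <- tape$ops[[i]]
    g <- rec$out$grad
    if (is.null(g)) next
    gs <- rec$backward(g)
    for (j in seq_along(rec$inputs)) accumulate_grad(rec$inputs[[j]], gs[[j]])
  }
  invisible(NULL)
}

# ---- geometry caches -------------------------------------------------------

.tabseg_geom <- new.env(parent = emptyenv())

# im2col index matrix for a 3x3x3 stride-1 zero-padded convolution on an
# s^3 grid with C channels: (N, 27*C) indices into the padded (s+2)^3 x C
# matrix viewed as a vector. Column order: channel-major, offset fast.
geom_k3 <- function(s, C) {
  key <- sprintf("k3_%d_%d", s, C)
  hit <- .tabseg_geom[[key]]
  if (!is.null(hit)) return(hit)
  sp <- s + 2L
  n <- s^3
  x0 <- rep.int(0:(s - 1L), times = s * s)
  y0 <- rep.int(rep(0:(s - 1L), each = s), times = s)
  z0 <- rep(0:(s - 1L), each = s * s)
  base <- 1L + (x0 + 1L) + sp * (y0 + 1L) + sp * sp * (z0 + 1L)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  delta <- offs[, 1] + sp * offs[, 2] + sp * sp * offs[, 3]
  idx27 <- outer(base, as.integer(delta), `+`)         # N x 27
  fidx <- matrix(0L, n, 27L * C)
  for (c in seq_len(C)) {
    fidx[, ((c - 1L) * 27L + 1L):(c * 27L)] <- idx27 + (c - 1L) * sp^3
  }
  g <- list(fidx = as.integer(fidx), inner = base, sp3 = sp^3, n = n)
  .tabseg_geom[[key]] <- g
  g
}

# 2x2x2 stride-2 partition on a fine grid of side s (s even): (M, 8*C)
# indices, M = (s/2)^3, giving each coarse voxel its 8 fine children.
geom_k2 <- function(s, C) {
  key <- sprintf("k2_%d_%d", s, C)
  hit <- .tabseg_geom[[key]]
  if (!is.null(hit)) return(hit)
  sc <- s %/% 2L
  m <- sc^3
  x0 <- rep.int(0:(sc - 1L), times = sc * sc)
  y0 <- rep.int(rep(0:(sc - 1L), each = sc), times = sc)
  z0 <- rep(0:(sc - 1L), each = sc * sc)
  offs <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  idx8 <- matrix(0L, m, 8L)
  for (o in 1:8) {
    idx8[, o] <- 1L + (2L * x0 + offs[o, 1]) + s * (2L * y0 + offs[o, 2]) +
      s * s * (2L * z0 + offs[o, 3])
  }
  fidx <- matrix(0L, m, 8L * C)
  for (c in seq_len(C)) {
    fidx[, ((c - 1L) * 8L + 1L):(c * 8L)] <- idx8 + (c - 1L) * s^3
  }
  g <- list(idx8 = idx8, fidx = as.integer(fidx), m = m)
  .tabseg_geom[[key]] <- g
  g
}

pad_gather_k3 <- function(X, s, C) {
  g <- geom_k3(s, C)
  Xp <- matrix(0, g$sp3, C)
  Xp[g$inner, ] <- X
  G <- Xp[g$fidx]
  dim(G) <- c(g$n, 27L * C)
  G
}

add_bias_ <- function(x, bv) x + rep(bv, each = nrow(x))

# ---- primitives ------------------------------------------------------------

# Elementwise / linear-algebra primitives. Each returns an ad_node and (when
# a tape is supplied) registers a closure producing gradients for its node
# inputs; plain numeric inputs are treated as constants.

ad_matmul <- function(tape, A, B) {
  a <- val(A); b <- val(B)
  out <- nd(a %*% b)
  push_op(tape, out, list(A, B), function(dY) {
    list(tcrossprod(dY, b), crossprod(a, dY))
  })
}

# Y = scale * A %*% t(B)  (attention scores)
ad_matmul_nt <- function(tape, A, B, scale = 1) {
  a <- val(A); b <- val(B)
  out <- nd(scale * tcrossprod(a, b))
  push_op(tape, out, list(A, B), function(dY) {
    list(scale * (dY %*% b), scale * crossprod(dY, a))
  })
}

ad_add <- function(tape, A, B) {
  out <- nd(val(A) + val(B))
  push_op(tape, out, list(A, B), function(dY) list(dY, dY))
}

# bias: length-C vector added to every row of an (N, C) matrix
ad_add_bias <- function(tape, A, b) {
  bv <- val(b)
  out <- nd(add_bias_(val(A), as.vector(bv)))
  push_op(tape, out, list(A, b), function(dY) {
    db <- colSums(dY)
    dim(db) <- dim(bv)
    list(dY, db)
  })
}

ad_mul <- function(tape, A, B) {
  a <- val(A); b <- val(B)
  out <- nd(a * b)
  push_op(tape, out, list(A, B), function(dY) list(dY * b, dY * a))
}

ad_scale <- function(tape, A, s) {
  out <- nd(val(A) * s)
  push_op(tape, out, list(A), function(dY) list(dY * s))
}

ad_relu <- function(tape, A) {
  a <- val(A)
  out <- nd(pmax(a, 0))
  push_op(tape, out, list(A), function(dY) list(dY * (a > 0)))
}

ad_sigmoid <- function(tape, A) {
  y <- 1 / (1 + exp(-val(A)))
  out <- nd(y)
  push_op(tape, out, list(A), function(dY) list(dY * y * (1 - y)))
}

# row-wise softmax (used both for attention weights and for the channel
# softmax head, where each voxel is a row and each tissue a column)
ad_softmax_rows <- function(tape, A) {
  a <- val(A)
  rowmax <- Reduce(pmax, lapply(seq_len(ncol(a)), function(j) a[, j]))
  e <- exp(a - rowmax)
  y <- e / rowSums(e)
  out <- nd(y)
  push_op(tape, out, list(A), function(dY) {
    list(y * (dY - rowSums(dY * y)))
  })
}

ad_dropout <- function(tape, A, rate) {
  if (rate <= 0) return(if (is_node(A)) A else nd(A))
  a <- val(A)
  keep <- (stats::runif(length(a)) >= rate) / (1 - rate)
  dim(keep) <- dim(a)
  out <- nd(a * keep)
  push_op(tape, out, list(A), function(dY) list(dY * keep))
}

# row permutation (token reordering); perm must be a permutation of rows
ad_permute_rows <- function(tape, A, perm) {
  a <- val(A)
  out <- nd(a[perm, , drop = FALSE])
  push_op(tape, out, list(A), function(dY) {
    dX <- dY
    dX[perm, ] <- dY
    list(dX)
  })
}

ad_concat_cols <- function(tape, A, B) {
  a <- val(A); b <- val(B)
  na <- ncol(a)
  out <- nd(cbind(a, b))
  push_op(tape, out, list(A, B), function(dY) {
    list(dY[, seq_len(na), drop = FALSE],
         dY[, (na + 1L):ncol(dY), drop = FALSE])
  })
}

ad_cols <- function(tape, A, cols) {
  a <- val(A)
  out <- nd(a[, cols, drop = FALSE])
  push_op(tape, out, list(A), function(dY) {
    dX <- matrix(0, nrow(a), ncol(a))
    dX[, cols] <- dY
    list(dX)
  })
}

# (1, C) matrix of per-channel means over voxels (SE squeeze)
ad_colmeans <- function(tape, A) {
  a <- val(A)
  n <- nrow(a)
  out <- nd(matrix(colMeans(a), 1L))
  push_op(tape, out, list(A), function(dY) {
    list(matrix(rep(dY / n, each = n), n, ncol(a)))
  })
}

# scale each column c of X by a[1, c] (SE excitation)
ad_colscale <- function(tape, X, a) {
  x <- val(X); av <- as.vector(val(a))
  out <- nd(sweep(x, 2L, av, `*`))
  push_op(tape, out, list(X, a), function(dY) {
    list(sweep(dY, 2L, av, `*`), matrix(colSums(dY * x), 1L))
  })
}

# ---- fused network primitives ---------------------------------------------

# 3x3x3 stride-1 zero-padded convolution.
# X: (s^3, Cin); W: (27*Cin, Cout) rows ordered channel-major offset-fast;
# b: (1, Cout). Input gradient = convolution of dY with the spatially
# flipped kernel and transposed channels (exact for zero padding).
ad_conv3 <- function(tape, X, W, b, s) {
  x <- val(X); w <- val(W); bv <- as.vector(val(b))
  cin <- ncol(x); cout <- length(bv)
  G <- pad_gather_k3(x, s, cin)
  out <- nd(sweep(G %*% w, 2L, bv, `+`))
  push_op(tape, out, list(X, W, b), function(dY) {
    dW <- crossprod(G, dY)
    db <- matrix(colSums(dY), 1L)
    dX <- NULL
    if (is_node(X)) {
      Gd <- pad_gather_k3(dY, s, cout)
      wf <- array(w, dim = c(27L, cin, cout))[27:1, , , drop = FALSE]
      Wback <- matrix(aperm(wf, c(1, 3, 2)), 27L * cout, cin)
      dX <- Gd %*% Wback
    }
    list(dX, dW, db)
  })
}

# 2x2x2 stride-2 convolution (downsampling; exact partition of voxels).
# X: (s^3, Cin), s even; W: (8*Cin, Cout); output ((s/2)^3, Cout).
ad_down2 <- function(tape, X, W, b, s) {
  x <- val(X); w <- val(W); bv <- as.vector(val(b))
  cin <- ncol(x)
  g <- geom_k2(s, cin)
  G <- x[g$fidx]
  dim(G) <- c(g$m, 8L * cin)
  out <- nd(add_bias_(G %*% w, bv))
  push_op(tape, out, list(X, W, b), function(dY) {
    dX <- NULL
    if (is_node(X)) {
      dG <- tcrossprod(dY, w)
      dX <- matrix(0, nrow(x), cin)
      dX[g$fidx] <- dG        # each fine voxel belongs to exactly one patch
    }
    list(dX, crossprod(G, dY), matrix(colSums(dY), 1L))
  })
}

# 2x2x2 stride-2 transposed convolution (upsampling).
# X: (s^3, Cin); W: (Cin, 8*Cout) columns ordered offset-major channel-fast
# is NOT used; order: for offset o, channels block ((o-1)*Cout+1):(o*Cout).
# Output: ((2s)^3, Cout); every output voxel receives exactly one term.
ad_up2 <- function(tape, X, W, b, s) {
  x <- val(X); w <- val(W); bv <- as.vector(val(b))
  cout <- length(bv)
  sf <- 2L * s
  g <- geom_k2(sf, 1L)
  Y <- x %*% w                                  # (s^3, 8*Cout)
  OUT <- matrix(0, sf^3, cout)
  for (o in 1:8) {
    OUT[g$idx8[, o], ] <- Y[, ((o - 1L) * cout + 1L):(o * cout), drop = FALSE]
  }
  out <- nd(add_bias_(OUT, bv))
  push_op(tape, out, list(X, W, b), function(dY) {
    dYc <- matrix(0, nrow(x), 8L * cout)
    for (o in 1:8) {
      dYc[, ((o - 1L) * cout + 1L):(o * cout)] <- dY[g$idx8[, o], , drop = FALSE]
    }
    list(tcrossprod(dYc, w), crossprod(x, dYc), matrix(colSums(dY), 1L))
  })
}

# 1x1x1 convolution = per-voxel linear map.
ad_conv1 <- function(tape, X, W, b) {
  ad_add_bias(tape, ad_matmul(tape, X, W), b)
}

# Group normalization over (channels-in-group x all voxels) per sample.
# X: (N, C); gamma, beta: (1, C); groups divides C.
ad_groupnorm <- function(tape, X, gamma, beta, groups, eps = 1e-5) {
  x <- val(X); gv <- as.vector(val(gamma)); bv <- as.vector(val(beta))
  C <- ncol(x); n <- nrow(x)
  cg <- C %/% groups
  y <- matrix(0, n, C)
  xhat <- matrix(0, n, C)
  istd <- numeric(groups)
  for (j in seq_len(groups)) {
    cols <- ((j - 1L) * cg + 1L):(j * cg)
    xs <- x[, cols, drop = FALSE]
    mu <- mean(xs)
    v <- mean((xs - mu)^2)
    istd[j] <- 1 / sqrt(v + eps)
    xh <- (xs - mu) * istd[j]
    xhat[, cols] <- xh
    y[, cols] <- sweep(xh, 2L, gv[cols], `*`) +
      matrix(bv[cols], n, cg, byrow = TRUE)
  }
  out <- nd(y)
  push_op(tape, out, list(X, gamma, beta), function(dY) {
    dX <- matrix(0, n, C)
    for (j in seq_len(groups)) {
      cols <- ((j - 1L) * cg + 1L):(j * cg)
      dxh <- sweep(dY[, cols, drop = FALSE], 2L, gv[cols], `*`)
      xh <- xhat[, cols, drop = FALSE]
      m <- n * cg
      dX[, cols] <- istd[j] * (dxh - sum(dxh) / m - xh * (sum(dxh * xh) / m))
    }
    list(dX,
         matrix(colSums(dY * xhat), 1L),
         matrix(colSums(dY), 1L))
  })
}

# Layer normalization per row (token) over the embedding dimension.
ad_layernorm <- function(tape, X, gamma, beta, eps = 1e-5) {
  x <- val(X); gv <- as.vector(val(gamma)); bv <- as.vector(val(beta))
  E <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- sweep(sweep(xhat, 2L, gv, `*`), 2L, bv, `+`)
  out <- nd(y)
  push_op(tape, out, list(X, gamma, beta), function(dY) {
    dxh <- sweep(dY, 2L, gv, `*`)
    r1 <- rowSums(dxh) / E
    r2 <- rowSums(dxh * xhat) / E
    list((dxh - r1 - xhat * r2) * istd,
         matrix(colSums(dY * xhat), 1L),
         matrix(colSums(dY), 1L))
  })
}
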