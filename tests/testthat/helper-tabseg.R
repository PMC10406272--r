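# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive loops / closed forms so they stay independent of the package's
# vectorized implementations.

tiny_model_config <- function(variant = "tabs", seed = 7L) {
  model_config(variant = variant, input_side = 8L, levels = 2L,
               bottleneck_features = 4L, channel_schedule = c(2L, 4L),
               transformer_layers = 1L, transformer_heads = 2L,
               embed_dim = 8L, norm_groups = 2L, dropout = 0, seed = seed)
}

small_phantom_config <- function(grid = 16L, seed = 1L, ...) {
  phantom_config(grid_side = grid, seed = seed, ...)
}

random_probmap <- function(d, seed) {
  set.seed(seed)
  raw <- array(stats::runif(3 * d^3), dim = c(3, d, d, d))
  tot <- colSums(raw, dims = 1)
  for (k in 1:3) raw[k, , , ] <- raw[k, , , ] / tot
  tissue_prob_map(raw, check = FALSE)
}

random_mask <- function(d, seed, p = 0.5) {
  set.seed(seed)
  m <- array(stats::runif(d^3) < p, dim = c(d, d, d))
  if (!any(m)) m[1, 1, 1] <- TRUE
  m
}

# ---- brute-force oracles ---------------------------------------------------

bf_dice <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    inter <- inter + (a[i] && b[i])
    sa <- sa + a[i]; sb <- sb + b[i]
  }
  if (sa + sb == 0) 1 else 2 * inter / (sa + sb)
}

bf_jaccard <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    inter <- inter + (a[i] && b[i])
    uni <- uni + (a[i] || b[i])
  }
  if (uni == 0) 1 else inter / uni
}

bf_hausdorff <- function(a, b, spacing = c(1, 1, 1)) {
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  directed <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        dd <- sum(((p[i, ] - q[j, ]) * spacing)^2)
        if (dd < best) best <- dd
      }
      if (best > worst) worst <- best
    }
    sqrt(worst)
  }
  max(directed(pa, pb), directed(pb, pa))
}

bf_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bf_rank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

bf_spearman <- function(x, y) bf_pearson(bf_rank(x), bf_rank(y))

bf_mse <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  s / length(x)
}

bf_bbox <- function(arrs, bg) {
  lo <- c(Inf, Inf, Inf); hi <- c(-Inf, -Inf, -Inf)
  for (a in arrs) {
    d <- dim(a)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (a[i, j, k] > bg) {
        lo <- pmin(lo, c(i, j, k)); hi <- pmax(hi, c(i, j, k))
      }
    }
  }
  list(lower = lo - 1, upper = hi)
}

# naive 3x3x3 stride-1 zero-padded convolution; x (N,Cin) on an s^3 grid,
# w indexed [offset, cin, cout] with offsets (dx,dy,dz) in {-1,0,1}^3,
# dx fastest (matching the packed weight layout)
bf_conv3 <- function(x, w_arr, bias, s) {
  cin <- dim(w_arr)[2]; cout <- dim(w_arr)[3]
  xg <- array(x, dim = c(s, s, s, cin))
  out <- array(0, dim = c(s, s, s, cout))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  for (i in 1:s) for (j in 1:s) for (k in 1:s) for (co in 1:cout) {
    acc <- bias[co]
    for (o in 1:27) for (ci in 1:cin) {
      ii <- i + offs$dx[o]; jj <- j + offs$dy[o]; kk <- k + offs$dz[o]
      if (ii >= 1 && ii <= s && jj >= 1 && jj <= s && kk >= 1 && kk <= s) {
        acc <- acc + xg[ii, jj, kk, ci] * w_arr[o, ci, co]
      }
    }
    out[i, j, k, co] <- acc
  }
  matrix(out, s^3, cout)
}

# exact two-sided signed-rank p-value by full enumeration of sign patterns
bf_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- bf_rank(abs(d))
  v <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    vs[m + 1] <- sum(r[bits == 1])
  }
  p_le <- mean(vs <= v + 1e-9)
  p_ge <- mean(vs >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
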