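# Network definitions: a 3D encoder/decoder with four variants sharing depth
# and channel schedule --
#   unet     plain convolutional blocks
#   unet_se  squeeze-and-excitation blocks before each downsampling
#   resunet  residual convolutional blocks
#   tabs     resunet plus a vision-transformer bottleneck
# The input is one normalized T1w channel; the output is a 3-channel tissue
# probability map (softmax over GM/WM/CSF at every voxel).

MODEL_VARIANTS <- c("unet", "unet_se", "resunet", "tabs")

# largest divisor of all channel counts that is <= 8
auto_norm_groups <- function(schedule) {
  for (g in rev(seq_len(8))) if (all(schedule %% g == 0)) return(g)
  1L
}

#' Model configuration
#'
#' Describes one architecture variant and every dimension needed to build
#' it. Defaults reproduce the native geometry: 192^3 input, 5 levels (4
#' downsamplings) to a 128 x 12^3 bottleneck, and for the `tabs` variant a
#' 4-layer / 8-head transformer over 1728 tokens of width 512.
#'
#' @param variant one of `"unet"`, `"unet_se"`, `"resunet"`, `"tabs"`.
#' @param input_side voxels per axis; must be divisible by `2^(levels - 1)`.
#' @param levels encoder depth (5 levels = 4 downsamplings).
#' @param bottleneck_features `f`, the channel count at the deepest level.
#' @param channel_schedule per-level channel counts ending in
#'   `bottleneck_features`; default geometric doubling (8,16,32,64,128).
#' @param transformer_layers,transformer_heads transformer encoder size.
#' @param embed_dim token embedding width; divisible by `transformer_heads`.
#' @param norm_groups group-normalization group count; must divide every
#'   entry of the channel schedule. `NULL` picks the largest divisor <= 8.
#' @param dropout dropout rate inside transformer sublayers (training only).
#' @param seed weight-initialization seed.
#' @return an object of class `model_config`.
#' @export
model_config <- function(variant = "tabs", input_side = 192L, levels = 5L,
                         bottleneck_features = 128L, channel_schedule = NULL,
                         transformer_layers = 4L, transformer_heads = 8L,
                         embed_dim = 512L, norm_groups = NULL, dropout = 0.1,
                         seed = 1L) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  levels <- as.integer(levels)
  f <- as.integer(bottleneck_features)
  if (is.null(channel_schedule)) {
    channel_schedule <- f %/% 2^((levels - 1):0)
    if (channel_schedule[1] < 1 || any(channel_schedule * 2^((levels - 1):0) != f)) {
      stop_tabseg("model_config: cannot derive a doubling channel schedule ending at f = %d over %d levels", f, levels)
    }
  }
  channel_schedule <- as.integer(channel_schedule)
  if (is.null(norm_groups)) norm_groups <- auto_norm_groups(channel_schedule)
  cfg <- list(variant = variant, input_side = as.integer(input_side),
              levels = levels, bottleneck_features = f,
              channel_schedule = channel_schedule,
              transformer_layers = as.integer(transformer_layers),
              transformer_heads = as.integer(transformer_heads),
              embed_dim = as.integer(embed_dim),
              norm_groups = as.integer(norm_groups),
              dropout = dropout, seed = as.integer(seed))
  class(cfg) <- "model_config"
  validate_model_config(cfg)
  cfg
}

#' Scaled-down TABS configuration for CPU-scale runs
#'
#' The canonical desk-scale geometry: input 32^3, f = 16, embedding width
#' 64, 2 transformer layers with 4 heads, and 3 levels (channel schedule
#' 4, 8, 16; bottleneck side 8, i.e. 512 tokens). Used by the acceptance
#' protocol and as the CLI training default.
#'
#' @param variant architecture variant (default `"tabs"`).
#' @param seed weight-initialization seed.
#' @return a [model_config()].
#' @export
scaled_model_config <- function(variant = "tabs", seed = 1L) {
  model_config(variant = variant, input_side = 32L, levels = 3L,
               bottleneck_features = 16L, channel_schedule = c(4L, 8L, 16L),
               transformer_layers = 2L, transformer_heads = 4L,
               embed_dim = 64L, seed = seed)
}

validate_model_config <- function(cfg) {
  assert_that_(cfg$levels >= 2, "model_config: need at least 2 levels")
  down <- 2^(cfg$levels - 1)
  assert_that_(cfg$input_side %% down == 0,
               "model_config: input_side %d not divisible by 2^(levels-1) = %d",
               cfg$input_side, down)
  assert_that_(length(cfg$channel_schedule) == cfg$levels,
               "model_config: channel_schedule must have one entry per level")
  assert_that_(cfg$channel_schedule[cfg$levels] == cfg$bottleneck_features,
               "model_config: channel_schedule must end at bottleneck_features")
  assert_that_(all(cfg$channel_schedule >= 1), "model_config: channels must be >= 1")
  assert_that_(cfg$embed_dim %% cfg$transformer_heads == 0,
               "model_config: embed_dim %d not divisible by heads %d",
               cfg$embed_dim, cfg$transformer_heads)
  assert_that_(all(cfg$channel_schedule %% cfg$norm_groups == 0),
               "model_config: norm_groups %d must divide every channel count",
               cfg$norm_groups)
  assert_that_(cfg$dropout >= 0 && cfg$dropout < 1,
               "model_config: dropout must be in [0, 1)")
  invisible(cfg)
}

#' Infer the bottleneck tensor shape from a configuration
#'
#' The encoder halves the grid `levels - 1` times, so the deepest feature
#' tensor is `f x s x s x s` with `s = input_side / 2^(levels - 1)`
#' (128 x 12^3 for the default configuration).
#'
#' @param cfg a [model_config()].
#' @return named integer vector with `channels` and `spatial_side`.
#' @export
infer_bottleneck_shape <- function(cfg) {
  validate_model_config(cfg)
  c(channels = cfg$bottleneck_features,
    spatial_side = cfg$input_side %/% 2^(cfg$levels - 1))
}

# token row (1-based, column-major voxel order) for 0-based token index k:
# token k sits at spatial position (k %/% s^2, (k %/% s) %% s, k %% s).
token_permutation <- function(s) {
  k <- 0:(s^3 - 1)
  a <- k %/% (s * s)
  b <- (k %/% s) %% s
  cc <- k %% s
  as.integer(1 + a + s * b + s * s * cc)
}

# ---- parameter construction ------------------------------------------------

init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

se_hidden <- function(c) max(1L, c %/% 16L)

# Ordered parameter templates (name, nrow, ncol, init sd or fixed value).
# The same table drives initialization, the analytic architecture
# inventory, and the built-model summary, so the three cannot drift apart.
param_table <- function(cfg) {
  L <- cfg$levels
  ch <- cfg$channel_schedule
  E <- cfg$embed_dim
  f <- cfg$bottleneck_features
  sb <- cfg$input_side %/% 2^(L - 1)
  residual <- cfg$variant %in% c("resunet", "tabs")
  rows <- list()
  add <- function(name, nr, nc, sd = NULL, fill = NULL, stage) {
    rows[[length(rows) + 1L]] <<- list(name = name, nr = as.integer(nr),
                                       nc = as.integer(nc), sd = sd,
                                       fill = fill, stage = stage)
  }
  block <- function(prefix, cin, cout, stage) {
    add(paste0(prefix, ".conv1.w"), 27 * cin, cout, sd = sqrt(2 / (27 * cin)), stage = stage)
    add(paste0(prefix, ".conv1.b"), 1, cout, fill = 0, stage = stage)
    add(paste0(prefix, ".gn1.g"), 1, cout, fill = 1, stage = stage)
    add(paste0(prefix, ".gn1.b"), 1, cout, fill = 0, stage = stage)
    add(paste0(prefix, ".conv2.w"), 27 * cout, cout, sd = sqrt(2 / (27 * cout)), stage = stage)
    add(paste0(prefix, ".conv2.b"), 1, cout, fill = 0, stage = stage)
    add(paste0(prefix, ".gn2.g"), 1, cout, fill = 1, stage = stage)
    add(paste0(prefix, ".gn2.b"), 1, cout, fill = 0, stage = stage)
    if (residual && cin != cout) {
      add(paste0(prefix, ".short.w"), cin, cout, sd = sqrt(1 / cin), stage = stage)
      add(paste0(prefix, ".short.b"), 1, cout, fill = 0, stage = stage)
    }
  }
  for (i in seq_len(L)) {
    cin <- if (i == 1) 1L else ch[i]
    block(sprintf("enc%d", i), cin, ch[i], stage = "encoder")
    if (i < L) {
      if (cfg$variant == "unet_se") {
        h <- se_hidden(ch[i])
        add(sprintf("se%d.fc1.w", i), ch[i], h, sd = sqrt(2 / ch[i]), stage = "encoder")
        add(sprintf("se%d.fc1.b", i), 1, h, fill = 0, stage = "encoder")
        add(sprintf("se%d.fc2.w", i), h, ch[i], sd = sqrt(1 / h), stage = "encoder")
        add(sprintf("se%d.fc2.b", i), 1, ch[i], fill = 0, stage = "encoder")
      }
      add(sprintf("down%d.w", i), 8 * ch[i], ch[i + 1], sd = sqrt(2 / (8 * ch[i])), stage = "encoder")
      add(sprintf("down%d.b", i), 1, ch[i + 1], fill = 0, stage = "encoder")
    }
  }
  if (cfg$variant == "tabs") {
    add("tok.proj.w", f, E, sd = sqrt(1 / f), stage = "transformer")
    add("tok.proj.b", 1, E, fill = 0, stage = "transformer")
    add("tok.pos", sb^3, E, sd = 0.02, stage = "transformer")
    for (l in seq_len(cfg$transformer_layers)) {
      p <- sprintf("tr%d", l)
      add(paste0(p, ".ln1.g"), 1, E, fill = 1, stage = "transformer")
      add(paste0(p, ".ln1.b"), 1, E, fill = 0, stage = "transformer")
      for (nm in c("wq", "wk", "wv", "wo")) {
        add(paste0(p, ".", nm, ".w"), E, E, sd = sqrt(1 / E), stage = "transformer")
        add(paste0(p, ".", nm, ".b"), 1, E, fill = 0, stage = "transformer")
      }
      add(paste0(p, ".ln2.g"), 1, E, fill = 1, stage = "transformer")
      add(paste0(p, ".ln2.b"), 1, E, fill = 0, stage = "transformer")
      add(paste0(p, ".mlp1.w"), E, 4 * E, sd = sqrt(2 / E), stage = "transformer")
      add(paste0(p, ".mlp1.b"), 1, 4 * E, fill = 0, stage = "transformer")
      add(paste0(p, ".mlp2.w"), 4 * E, E, sd = sqrt(1 / (4 * E)), stage = "transformer")
      add(paste0(p, ".mlp2.b"), 1, E, fill = 0, stage = "transformer")
    }
    add("tr.lnf.g", 1, E, fill = 1, stage = "transformer")
    add("tr.lnf.b", 1, E, fill = 0, stage = "transformer")
    add("detok.conv.w", 27 * E, f, sd = sqrt(2 / (27 * E)), stage = "transformer")
    add("detok.conv.b", 1, f, fill = 0, stage = "transformer")
  }
  for (i in rev(seq_len(L - 1))) {
    add(sprintf("up%d.w", i), ch[i + 1], 8 * ch[i], sd = sqrt(2 / ch[i + 1]), stage = "decoder")
    add(sprintf("up%d.b", i), 1, ch[i], fill = 0, stage = "decoder")
    block(sprintf("dec%d", i), 2L * ch[i], ch[i], stage = "decoder")
  }
  add("head.w", ch[1], 3, sd = sqrt(1 / ch[1]), stage = "decoder")
  add("head.b", 1, 3, fill = 0, stage = "decoder")
  rows
}

#' Build a segmentation model
#'
#' Instantiates the variant described by `cfg` with seeded random weights
#' (He-style initialization for convolutions, unit-gain normalization
#' parameters). All four variants share encoder depth and channel schedule;
#' `tabs` differs from `resunet` only by the transformer bottleneck stage.
#'
#' @param cfg a [model_config()].
#' @return an object of class `tabs_model` (configuration plus named
#'   parameter list).
#' @export
build_model <- function(cfg) {
  validate_model_config(cfg)
  tab <- param_table(cfg)
  params <- with_seed_(cfg$seed, {
    ps <- vector("list", length(tab))
    names(ps) <- vapply(tab, `[[`, "", "name")
    for (i in seq_along(tab)) {
      r <- tab[[i]]
      ps[[i]] <- if (!is.null(r$fill)) {
        matrix(r$fill, r$nr, r$nc)
      } else {
        init_mat(r$nr, r$nc, r$sd)
      }
    }
    ps
  })
  structure(list(cfg = cfg, params = params), class = "tabs_model")
}

#' @export
print.tabs_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<tabs_model> variant %s, input %d^3, %d levels, %s parameters\n",
              x$cfg$variant, x$cfg$input_side, x$cfg$levels,
              format(np, big.mark = ",")))
  invisible(x)
}

# ---- forward pass ----------------------------------------------------------

# Two-conv block with group norm; residual shortcut for resunet/tabs.
fwd_block <- function(tape, P, x, prefix, cin, cout, cfg, s) {
  g <- cfg$norm_groups
  h <- ad_conv3(tape, x, P[[paste0(prefix, ".conv1.w")]],
                P[[paste0(prefix, ".conv1.b")]], s)
  h <- ad_relu(tape, ad_groupnorm(tape, h, P[[paste0(prefix, ".gn1.g")]],
                                  P[[paste0(prefix, ".gn1.b")]], g))
  h <- ad_conv3(tape, h, P[[paste0(prefix, ".conv2.w")]],
                P[[paste0(prefix, ".conv2.b")]], s)
  h <- ad_groupnorm(tape, h, P[[paste0(prefix, ".gn2.g")]],
                    P[[paste0(prefix, ".gn2.b")]], g)
  if (cfg$variant %in% c("resunet", "tabs")) {
    sc <- if (cin == cout) x else {
      ad_conv1(tape, x, P[[paste0(prefix, ".short.w")]],
               P[[paste0(prefix, ".short.b")]])
    }
    h <- ad_add(tape, h, sc)
  }
  ad_relu(tape, h)
}

fwd_se <- function(tape, P, x, i) {
  z <- ad_colmeans(tape, x)
  z <- ad_relu(tape, ad_add_bias(tape,
         ad_matmul(tape, z, P[[sprintf("se%d.fc1.w", i)]]),
         P[[sprintf("se%d.fc1.b", i)]]))
  a <- ad_sigmoid(tape, ad_add_bias(tape,
         ad_matmul(tape, z, P[[sprintf("se%d.fc2.w", i)]]),
         P[[sprintf("se%d.fc2.b", i)]]))
  ad_colscale(tape, x, a)
}

fwd_mha <- function(tape, P, x, prefix, heads) {
  E <- ncol(val(x))
  dh <- E %/% heads
  q <- ad_add_bias(tape, ad_matmul(tape, x, P[[paste0(prefix, ".wq.w")]]),
                   P[[paste0(prefix, ".wq.b")]])
  k <- ad_add_bias(tape, ad_matmul(tape, x, P[[paste0(prefix, ".wk.w")]]),
                   P[[paste0(prefix, ".wk.b")]])
  v <- ad_add_bias(tape, ad_matmul(tape, x, P[[paste0(prefix, ".wv.w")]]),
                   P[[paste0(prefix, ".wv.b")]])
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    qh <- ad_cols(tape, q, cols)
    kh <- ad_cols(tape, k, cols)
    vh <- ad_cols(tape, v, cols)
    sc <- ad_matmul_nt(tape, qh, kh, scale = 1 / sqrt(dh))
    p <- ad_softmax_rows(tape, sc)
    outs[[h]] <- ad_matmul(tape, p, vh)
  }
  o <- outs[[1]]
  for (h in seq_len(heads)[-1]) o <- ad_concat_cols(tape, o, outs[[h]])
  ad_add_bias(tape, ad_matmul(tape, o, P[[paste0(prefix, ".wo.w")]]),
              P[[paste0(prefix, ".wo.b")]])
}

fwd_transformer_layer <- function(tape, P, x, prefix, cfg, training) {
  drop <- if (training) cfg$dropout else 0
  a <- ad_layernorm(tape, x, P[[paste0(prefix, ".ln1.g")]],
                    P[[paste0(prefix, ".ln1.b")]])
  a <- fwd_mha(tape, P, a, prefix, cfg$transformer_heads)
  x <- ad_add(tape, x, ad_dropout(tape, a, drop))
  m <- ad_layernorm(tape, x, P[[paste0(prefix, ".ln2.g")]],
                    P[[paste0(prefix, ".ln2.b")]])
  m <- ad_relu(tape, ad_add_bias(tape,
         ad_matmul(tape, m, P[[paste0(prefix, ".mlp1.w")]]),
         P[[paste0(prefix, ".mlp1.b")]]))
  m <- ad_add_bias(tape, ad_matmul(tape, m, P[[paste0(prefix, ".mlp2.w")]]),
                   P[[paste0(prefix, ".mlp2.b")]])
  ad_add(tape, x, ad_dropout(tape, m, drop))
}

fwd_tokenize <- function(tape, P, x, perm) {
  t <- ad_permute_rows(tape, x, perm)
  t <- ad_add_bias(tape, ad_matmul(tape, t, P[["tok.proj.w"]]), P[["tok.proj.b"]])
  ad_add(tape, t, P[["tok.pos"]])
}

fwd_detokenize <- function(tape, P, x, perm, s) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  g <- ad_permute_rows(tape, x, inv)
  ad_conv3(tape, g, P[["detok.conv.w"]], P[["detok.conv.b"]], s)
}

# Full forward pass. x: (input_side^3, 1) matrix of normalized intensities.
# Returns list(probs, logits) of ad_nodes of shape (N, 3).
model_forward <- function(model, x, training = FALSE, tape = NULL) {
  cfg <- model$cfg
  P <- model$params
  if (!is.null(tape)) P <- lapply(P, nd)
  L <- cfg$levels
  ch <- cfg$channel_schedule
  s <- cfg$input_side
  skips <- vector("list", L - 1)
  h <- x
  for (i in seq_len(L)) {
    cin <- if (i == 1) 1L else ch[i]
    h <- fwd_block(tape, P, h, sprintf("enc%d", i), cin, ch[i], cfg, s)
    if (i < L) {
      if (cfg$variant == "unet_se") h <- fwd_se(tape, P, h, i)
      skips[[i]] <- h
      h <- ad_down2(tape, h, P[[sprintf("down%d.w", i)]],
                    P[[sprintf("down%d.b", i)]], s)
      s <- s %/% 2L
    }
  }
  if (cfg$variant == "tabs") {
    perm <- token_permutation(s)
    t <- fwd_tokenize(tape, P, h, perm)
    for (l in seq_len(cfg$transformer_layers)) {
      t <- fwd_transformer_layer(tape, P, t, sprintf("tr%d", l), cfg, training)
    }
    t <- ad_layernorm(tape, t, P[["tr.lnf.g"]], P[["tr.lnf.b"]])
    h <- fwd_detokenize(tape, P, t, perm, s)
  }
  for (i in rev(seq_len(L - 1))) {
    h <- ad_up2(tape, h, P[[sprintf("up%d.w", i)]], P[[sprintf("up%d.b", i)]], s)
    s <- s * 2L
    h <- ad_concat_cols(tape, h, skips[[i]])
    h <- fwd_block(tape, P, h, sprintf("dec%d", i), 2L * ch[i], ch[i], cfg, s)
  }
  logits <- ad_conv1(tape, h, P[["head.w"]], P[["head.b"]])
  probs <- ad_softmax_rows(tape, logits)
  list(probs = probs, logits = logits, pnodes = P)
}

volume_to_input <- function(volume) {
  matrix(as.vector(volume$values), ncol = 1L)
}

probmap_to_target <- function(probmap) {
  d <- dim(probmap$values)[2]
  t(matrix(probmap$values, 3L, d^3))
}

matrix_to_probmap <- function(m, d, spacing = c(1, 1, 1)) {
  vals <- array(t(m), dim = c(3L, d, d, d))
  tissue_prob_map(vals, spacing = spacing, check = FALSE)
}

#' Predict a tissue probability map for one volume
#'
#' Runs a forward pass in evaluation mode (dropout off). The input must be
#' normalized to \[-1, 1\] and have the configured spatial side.
#'
#' @param object a [build_model()] result.
#' @param volume a normalized [volume3d()].
#' @param ... unused.
#' @return a [tissue_prob_map()] whose channels sum to 1 at every voxel.
#' @export
predict.tabs_model <- function(object, volume, ...) {
  stopifnot(inherits(volume, "volume3d"))
  d <- dim(volume$values)
  if (!all(d == object$cfg$input_side)) {
    stop_tabseg("predict: volume is %s but model expects %d^3",
                paste(d, collapse = "x"), object$cfg$input_side)
  }
  out <- model_forward(object, volume_to_input(volume), training = FALSE)
  matrix_to_probmap(val(out$probs), d[1], spacing = volume$spacing)
}

# ---- exposed bottleneck operations (tabs) ----------------------------------

#' Tokenize a bottleneck feature grid
#'
#' One token per spatial location: a learned linear projection from `f`
#' channels to `embed_dim` plus a learned positional embedding. Token `k`
#' (0-based) corresponds to spatial position
#' `(k %/% s^2, (k %/% s) %% s, k %% s)`.
#'
#' @param model a built `tabs` model.
#' @param features numeric array of shape (f, s, s, s).
#' @return token matrix of shape (s^3, embed_dim).
#' @export
tokenize <- function(model, features) {
  stopifnot(inherits(model, "tabs_model"), model$cfg$variant == "tabs")
  bs <- infer_bottleneck_shape(model$cfg)
  dm <- dim(features)
  if (length(dm) != 4L || dm[1] != bs["channels"] || any(dm[2:4] != bs["spatial_side"])) {
    stop_tabseg("tokenize: features must be (%d, %d, %d, %d)",
                bs["channels"], bs["spatial_side"], bs["spatial_side"], bs["spatial_side"])
  }
  s <- dm[2]
  x <- t(matrix(features, dm[1], s^3))            # (s^3, f), voxel-major
  val(fwd_tokenize(NULL, model$params, x, token_permutation(s)))
}

#' Run the transformer encoder stack over a token matrix
#'
#' Pre-norm multi-head self-attention encoder; shape-preserving.
#'
#' @param model a built `tabs` model.
#' @param tokens matrix (n_tokens, embed_dim).
#' @return matrix of the same shape.
#' @export
transformer_encode <- function(model, tokens) {
  stopifnot(inherits(model, "tabs_model"), model$cfg$variant == "tabs")
  cfg <- model$cfg
  bs <- infer_bottleneck_shape(cfg)
  if (!is.matrix(tokens) || ncol(tokens) != cfg$embed_dim ||
      nrow(tokens) != bs[["spatial_side"]]^3) {
    stop_tabseg("transformer_encode: tokens must be (%d, %d)",
                bs[["spatial_side"]]^3, cfg$embed_dim)
  }
  t <- tokens
  for (l in seq_len(cfg$transformer_layers)) {
    t <- fwd_transformer_layer(NULL, model$params, t, sprintf("tr%d", l), cfg,
                               training = FALSE)
  }
  val(ad_layernorm(NULL, t, model$params[["tr.lnf.g"]], model$params[["tr.lnf.b"]]))
}

#' Map a token matrix back to a bottleneck feature grid
#'
#' Reshapes the (n_tokens, embed_dim) matrix to an (embed_dim, s, s, s)
#' grid (inverting the tokenization order) and reduces the channel count
#' back to `f` with a learned 3x3x3 convolution.
#'
#' @param model a built `tabs` model.
#' @param tokens matrix (n_tokens, embed_dim); n_tokens must be a cube.
#' @return numeric array of shape (f, s, s, s).
#' @export
detokenize <- function(model, tokens) {
  stopifnot(inherits(model, "tabs_model"), model$cfg$variant == "tabs")
  s <- round(nrow(tokens)^(1 / 3))
  if (s^3 != nrow(tokens)) {
    stop_tabseg("detokenize: token count %d is not a cube", nrow(tokens))
  }
  out <- val(fwd_detokenize(NULL, model$params, tokens, token_permutation(s), s))
  array(t(out), dim = c(ncol(out), s, s, s))
}

# ---- architecture inventory ------------------------------------------------

#' Analytic architecture inventory for a configuration
#'
#' Lists every trainable parameter tensor (name, shape, element count,
#' pipeline stage) without building weights; derived from the same table
#' that drives initialization, so it provably matches [build_model()].
#'
#' @param cfg a [model_config()].
#' @return data.frame with columns `name`, `rows`, `cols`, `n_params`, `stage`.
#' @export
architecture_inventory <- function(cfg) {
  validate_model_config(cfg)
  tab <- param_table(cfg)
  data.frame(name = vapply(tab, `[[`, "", "name"),
             rows = vapply(tab, `[[`, 0L, "nr"),
             cols = vapply(tab, `[[`, 0L, "nc"),
             n_params = vapply(tab, function(r) r$nr * r$nc, 0),
             stage = vapply(tab, `[[`, "", "stage"),
             stringsAsFactors = FALSE)
}

#' Stage-by-stage tensor shapes of the network
#'
#' Pure shape inference (no weights): the bottleneck grid, the token block
#' the transformer operates on (embed_dim x n_tokens), the reshape back to
#' a grid, and the final output shape.
#'
#' @param cfg a [model_config()].
#' @return named list of integer shape vectors.
#' @export
architecture_shapes <- function(cfg) {
  validate_model_config(cfg)
  bs <- infer_bottleneck_shape(cfg)
  s <- bs[["spatial_side"]]
  d <- cfg$input_side
  list(bottleneck = c(channels = bs[["channels"]], side = s),
       tokens = c(n_tokens = s^3, embed_dim = cfg$embed_dim),
       transformer_out = c(embed_dim = cfg$embed_dim, n_tokens = s^3),
       reshaped = c(cfg$embed_dim, s, s, s),
       detokenized = c(cfg$bottleneck_features, s, s, s),
       output = c(3L, d, d, d))
}

#' Summarize a built model
#'
#' @param model a [build_model()] result.
#' @return data.frame as [architecture_inventory()], with shapes taken from
#'   the actual parameter tensors.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "tabs_model"))
  data.frame(name = names(model$params),
             rows = vapply(model$params, nrow, 0L),
             cols = vapply(model$params, ncol, 0L),
             n_params = vapply(model$params, length, 0),
             stage = architecture_inventory(model$cfg)$stage,
             row.names = NULL, stringsAsFactors = FALSE)
}
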