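test_that("bottleneck shape inference matches the architecture arithmetic", {
  expect_equal(unname(infer_bottleneck_shape(model_config("tabs"))), c(128L, 12L))
  cfg64 <- model_config("tabs", input_side = 64, levels = 5,
                        bottleneck_features = 32, embed_dim = 64,
                        transformer_heads = 4)
  expect_equal(unname(infer_bottleneck_shape(cfg64)), c(32L, 4L))
  cfg48 <- model_config("tabs", input_side = 48, levels = 3,
                        bottleneck_features = 16, embed_dim = 64,
                        transformer_heads = 4)
  expect_equal(unname(infer_bottleneck_shape(cfg48)), c(16L, 12L))
  expect_error(model_config("tabs", input_side = 50), "divisible")
})

test_that("every variant maps 1-channel input to a 3-channel softmax output", {
  set.seed(20)
  x <- matrix(rnorm(16^3), ncol = 1)
  for (variant in c("unet", "unet_se", "resunet", "tabs")) {
    cfg <- model_config(variant, input_side = 16, levels = 3,
                        bottleneck_features = 8, transformer_layers = 1,
                        transformer_heads = 2, embed_dim = 16, seed = 3)
    m <- build_model(cfg)
    out <- tabseg:::model_forward(m, x)
    p <- tabseg:::val(out$probs)
    expect_equal(dim(p), c(16^3, 3L))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-5)
    expect_true(all(p > 0))
    # softmax equals the brute-force exp / sum(exp) of the logits
    l <- tabseg:::val(out$logits)
    oracle <- exp(l) / rowSums(exp(l))
    expect_equal(p, oracle, tolerance = 1e-9)
  }
  expect_error(model_config(variant = "resnet50"))
})

test_that("weight initialization is a pure function of the seed", {
  cfg <- tiny_model_config("tabs", seed = 99L)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_model_config("tabs", seed = 100L))
  expect_false(identical(m1$params, m3$params))
  # and forward passes are deterministic in evaluation mode
  x <- matrix(rnorm(8^3), ncol = 1)
  expect_identical(tabseg:::val(tabseg:::model_forward(m1, x)$probs),
                   tabseg:::val(tabseg:::model_forward(m2, x)$probs))
})

test_that("tokenization realizes one token per spatial position", {
  m <- build_model(tiny_model_config("tabs"))
  bs <- infer_bottleneck_shape(m$cfg)   # f = 4, side = 4
  s <- bs[["spatial_side"]]; f <- bs[["channels"]]; E <- m$cfg$embed_dim
  set.seed(21)
  feats <- array(rnorm(f * s^3), dim = c(f, s, s, s))
  tok <- tokenize(m, feats)
  expect_equal(dim(tok), c(s^3, E))
  # positional embedding: one learned vector per token position
  expect_equal(dim(m$params[["tok.pos"]]), c(s^3, E))
  # token k corresponds to (k %/% s^2, (k %/% s) %% s, k %% s), brute force
  W <- m$params[["tok.proj.w"]]; b <- as.vector(m$params[["tok.proj.b"]])
  for (k in sample(0:(s^3 - 1), 8)) {
    a <- k %/% (s * s); bb <- (k %/% s) %% s; cc <- k %% s
    expected <- as.vector(feats[, a + 1, bb + 1, cc + 1] %*% W) + b +
      m$params[["tok.pos"]][k + 1, ]
    expect_equal(tok[k + 1, ], expected, tolerance = 1e-12)
  }
  expect_error(tokenize(m, array(0, dim = c(f, s, s, s + 1))), "features")
})

test_that("the transformer encoder preserves token-matrix shape deterministically", {
  m <- build_model(tiny_model_config("tabs"))
  bs <- infer_bottleneck_shape(m$cfg)
  set.seed(22)
  tok <- matrix(rnorm(bs[["spatial_side"]]^3 * m$cfg$embed_dim),
                bs[["spatial_side"]]^3, m$cfg$embed_dim)
  enc1 <- transformer_encode(m, tok)
  enc2 <- transformer_encode(m, tok)
  expect_equal(dim(enc1), dim(tok))
  expect_identical(enc1, enc2)
  expect_error(transformer_encode(m, tok[, 1:3]), "tokens must be")
})

test_that("detokenization reshapes and reduces channels as stated", {
  m <- build_model(tiny_model_config("tabs"))
  bs <- infer_bottleneck_shape(m$cfg)
  s <- bs[["spatial_side"]]
  set.seed(23)
  tok <- matrix(rnorm(s^3 * m$cfg$embed_dim), s^3, m$cfg$embed_dim)
  grid <- detokenize(m, tok)
  expect_equal(dim(grid), c(bs[["channels"]], s, s, s))
  expect_error(detokenize(m, tok[1:7, , drop = FALSE]), "cube")
  # round trip of the spatial ordering: tokenize(detokenize-like grid)
  # re-reads positions in the same order (permutation is self-consistent)
  perm <- tabseg:::token_permutation(s)
  expect_setequal(perm, seq_len(s^3))
})

test_that("tabs without its transformer stage is exactly the resunet graph", {
  args <- list(input_side = 16, levels = 3, bottleneck_features = 8,
               transformer_layers = 1, transformer_heads = 2, embed_dim = 16,
               seed = 5)
  inv_tabs <- architecture_inventory(do.call(model_config, c(list("tabs"), args)))
  inv_res <- architecture_inventory(do.call(model_config, c(list("resunet"), args)))
  ablated <- inv_tabs[inv_tabs$stage != "transformer", ]
  rownames(ablated) <- NULL
  expect_identical(ablated, inv_res)
  # encoder+decoder parameter counts agree; the difference is the transformer
  expect_equal(sum(ablated$n_params), sum(inv_res$n_params))
  expect_gt(sum(inv_tabs$n_params), sum(inv_res$n_params))
})

test_that("the analytic inventory matches actually built models", {
  for (variant in c("unet", "unet_se", "resunet", "tabs")) {
    cfg <- tiny_model_config(variant)
    m <- build_model(cfg)
    expect_identical(model_summary(m), architecture_inventory(cfg))
  }
})
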