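# Probability-map regression training: Adam on a mean-squared-error loss
# over the full 3-channel output tensor, early stopping on validation loss,
# best-validation checkpoint returned.

#' Training configuration
#'
#' Defaults follow the full-scale protocol: up to 350 epochs with early
#' stopping, batch size 3, Adam with learning rate 1e-5 and weight decay
#' 1e-6. `patience` (epochs without validation improvement before stopping)
#' is a package default of 25, configurable.
#'
#' @param epochs maximum epoch count.
#' @param batch_size volumes per optimizer step.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty coupled into the Adam gradient.
#' @param patience early-stop epochs without validation improvement.
#' @param seed RNG seed for data order, dropout and any stochastic layer.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 350L, batch_size = 3L, lr = 1e-5,
                         weight_decay = 1e-6, patience = 25L, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              lr = lr, weight_decay = weight_decay,
              patience = as.integer(patience), seed = as.integer(seed),
              checkpoint_policy = "best_validation")
  assert_that_(cfg$epochs >= 1, "train_config: epochs must be >= 1")
  assert_that_(cfg$batch_size >= 1, "train_config: batch_size must be >= 1")
  assert_that_(cfg$lr > 0, "train_config: lr must be > 0")
  assert_that_(cfg$weight_decay >= 0, "train_config: weight_decay must be >= 0")
  assert_that_(cfg$patience >= 1, "train_config: patience must be >= 1")
  class(cfg) <- "train_config"
  cfg
}

#' Mean-squared-error loss between probability maps
#'
#' Mean over all channels and voxels of the squared difference; the loss is
#' computed over the full 3 x D^3 tensor (evaluation, not training, is
#' restricted to brain voxels).
#'
#' @param pred,target [tissue_prob_map()] objects or numeric arrays/matrices
#'   of identical shape.
#' @return scalar loss.
#' @export
mse_loss <- function(pred, target) {
  p <- if (inherits(pred, "tissue_prob_map")) pred$values else pred
  t <- if (inherits(target, "tissue_prob_map")) target$values else target
  if (!identical(dim(p), dim(t))) {
    stop_tabseg("mse_loss: shape mismatch (%s vs %s)",
                paste(dim(p), collapse = "x"), paste(dim(t), collapse = "x"))
  }
  mean((p - t)^2)
}

# Convert a phantom dataset into normalized model-ready tensors.
# Each sample: x = (N, 1) input matrix in [-1, 1], y = (N, 3) target matrix.
as_training_data <- function(dataset) {
  if (!inherits(dataset, "phantom_dataset")) return(dataset)
  prep <- function(sub) {
    v <- normalize_minus1_1(sub$volume)
    list(x = volume_to_input(v), y = probmap_to_target(sub$probmap), id = sub$id)
  }
  list(train = lapply(dataset_split(dataset, "train"), prep),
       val = lapply(dataset_split(dataset, "val"), prep))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (wd > 0) g <- g + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# loss + parameter gradients for one sample
sample_grads <- function(model, x, y, training = TRUE) {
  tape <- ad_tape()
  out <- model_forward(model, x, training = training, tape = tape)
  pred <- val(out$probs)
  loss <- mean((pred - y)^2)
  dpred <- 2 * (pred - y) / length(y)
  backprop(tape, out$probs, dpred)
  grads <- lapply(out$pnodes, function(n) n$grad)
  list(loss = loss, grads = grads)
}

eval_loss <- function(model, samples) {
  mean(vapply(samples, function(s) {
    out <- model_forward(model, s$x, training = FALSE)
    mean((val(out$probs) - s$y)^2)
  }, numeric(1)))
}

#' Train a segmentation model
#'
#' Mini-batch Adam on the MSE between predicted and ground-truth tissue
#' probability maps. Stops early after `patience` epochs without strict
#' validation improvement, never exceeding `epochs`, and returns the
#' weights of the best-validation epoch (not the last). Fully seeded: data
#' order, dropout and initialization reproduce bit-identically for a fixed
#' seed.
#'
#' @param model a [build_model()] result.
#' @param data a [make_phantom_dataset()] result (volumes are normalized to
#'   \[-1, 1\] internally) or a prepared list with `train` and `val` sample
#'   lists (`x` = (N,1) input matrix, `y` = (N,3) target matrix).
#' @param cfg a [train_config()].
#' @param verbose print one log line per epoch.
#' @return list with `model` (best-validation weights), `history`
#'   (data.frame epoch/train_loss/val_loss) and `best_epoch`.
#' @export
train_model <- function(model, data, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "tabs_model"))
  data <- as_training_data(data)
  if (length(data$train) == 0) stop_tabseg("train_model: empty training split")
  if (length(data$val) == 0) stop_tabseg("train_model: empty validation split")
  params <- model$params
  state <- adam_init(params)
  hist_epoch <- integer(0)
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  best_val <- Inf
  best_params <- params
  best_epoch <- NA_integer_
  wait <- 0L
  with_seed_(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(data$train))
      batch_losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        ids <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
        acc <- NULL
        bl <- 0
        for (j in ids) {
          model$params <- params
          sg <- sample_grads(model, data$train[[j]]$x, data$train[[j]]$y)
          if (!is.finite(sg$loss)) {
            stop_tabseg("train_model: non-finite loss at epoch %d (sample %s)",
                        epoch, data$train[[j]]$id %||% j)
          }
          bl <- bl + sg$loss
          acc <- if (is.null(acc)) sg$grads else {
            Map(function(a, g) {
              if (is.null(a)) g else if (is.null(g)) a else a + g
            }, acc, sg$grads)
          }
        }
        acc <- lapply(acc, function(g) if (is.null(g)) NULL else g / length(ids))
        upd <- adam_step(params, acc, state, cfg$lr, cfg$weight_decay)
        params <- upd$params
        state <- upd$state
        batch_losses <- c(batch_losses, bl / length(ids))
        i <- i + cfg$batch_size
      }
      model$params <- params
      vl <- eval_loss(model, data$val)
      hist_epoch <- c(hist_epoch, epoch)
      hist_train <- c(hist_train, mean(batch_losses))
      hist_val <- c(hist_val, vl)
      if (verbose) {
        message(sprintf("epoch %3d  train %.6f  val %.6f", epoch,
                        mean(batch_losses), vl))
      }
      if (vl < best_val) {
        best_val <- vl
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$params <- best_params
  history <- data.frame(epoch = hist_epoch, train_loss = hist_train,
                        val_loss = hist_val)
  list(model = model, history = history, best_epoch = best_epoch,
       best_val_loss = best_val)
}
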