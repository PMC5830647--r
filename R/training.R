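#' Training hyperparameters
#'
#' Defaults reproduce the published training procedure: starting learning
#' rate 0.001 under a polynomial decay of power 0.9 over a decay length of
#' 200 epochs, batches of 8 patches, spatial class weights 1.1 / 1.0 / 1.3
#' for background / myelin / axon, dropout 0.25, batch-norm momentum
#' scheduled from 0.7 towards 0.9, and the Adam optimizer.
#'
#' @param lr0 Starting learning rate.
#' @param decay_power Polynomial decay exponent.
#' @param decay_epochs Decay length in epochs (training stops there unless
#'   `epochs` is set lower in [train_network()]).
#' @param batch_size Patches per batch.
#' @param class_weights Length-3 weights (background, myelin, axon).
#' @param dropout Dropout rate on block convolutions.
#' @param bn_momentum_start,bn_momentum_end Endpoints of the batch-norm
#'   momentum schedule.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   stabilizer.
#' @param seed Integer seed controlling shuffling, augmentation and dropout.
#' @return A `training_config` list.
#' @export
training_config <- function(lr0 = 0.001, decay_power = 0.9,
                            decay_epochs = 200L, batch_size = 8L,
                            class_weights = c(1.1, 1.0, 1.3),
                            dropout = 0.25, bn_momentum_start = 0.7,
                            bn_momentum_end = 0.9, adam_beta1 = 0.9,
                            adam_beta2 = 0.999, adam_eps = 1e-8,
                            seed = 1L) {
  stopifnot(lr0 > 0, decay_power > 0, decay_epochs >= 1, batch_size >= 1,
            length(class_weights) == 3L, all(class_weights > 0))
  structure(list(lr0 = lr0, decay_power = decay_power,
                 decay_epochs = as.integer(decay_epochs),
                 batch_size = as.integer(batch_size),
                 class_weights = class_weights, dropout = dropout,
                 bn_momentum_start = bn_momentum_start,
                 bn_momentum_end = bn_momentum_end,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "training_config")
}

#' Spatially-weighted multi-class cross-entropy
#'
#' `mean over pixels of w[class] * (-log p_class)`, with probabilities
#' floored at 1e-12 before the log. With unit weights this is the ordinary
#' cross-entropy.
#'
#' @param probs Softmax output, dim `(H, W, 3, N)` (lower-dimensional input
#'   is promoted).
#' @param classes Ground-truth classes in \{0, 1, 2\}, dim `(H, W, N)` or a
#'   matrix.
#' @param w Length-3 class weights (background, myelin, axon).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, classes, w = c(1.1, 1.0, 1.3)) {
  probs <- as_batch(probs)
  d <- dim(probs)
  if (is.matrix(classes)) classes <- array(classes, dim = c(dim(classes), 1L))
  if (!identical(as.integer(dim(classes)), as.integer(d[c(1, 2, 4)])))
    stop("probability and class shapes do not match")
  p_true <- gather_true_prob(probs, classes)
  wpix <- array(w[as.vector(classes) + 1L], dim = dim(classes))
  mean(wpix * (-log(pmax(p_true, 1e-12))))
}

# probability assigned to the true class of every pixel; dim (H, W, N)
gather_true_prob <- function(probs, classes) {
  d <- dim(probs)
  plane <- d[1] * d[2]
  pix <- rep(seq_len(plane), times = d[4])
  samp <- rep(seq_len(d[4]) - 1L, each = plane)
  lin <- pix + plane * as.vector(classes) + plane * d[3] * samp
  array(probs[lin], dim = c(d[1], d[2], d[4]))
}

# gradient of weighted_cross_entropy w.r.t. the classifier logits
wce_logit_gradient <- function(probs, classes, w) {
  d <- dim(probs)
  plane <- d[1] * d[2]
  n_pix <- plane * d[4]
  wpix <- w[as.vector(classes) + 1L]
  g <- matrix(probs, plane, d[3] * d[4])
  pix <- rep(seq_len(plane), times = d[4])
  samp <- rep(seq_len(d[4]) - 1L, each = plane)
  lin <- pix + plane * as.vector(classes) + plane * d[3] * samp
  g[lin] <- g[lin] - 1
  for (n in seq_len(d[4])) {
    rows <- (n - 1L) * plane + seq_len(plane)
    cols <- (n - 1L) * d[3] + seq_len(d[3])
    g[, cols] <- g[, cols] * wpix[rows]
  }
  array(g / n_pix, dim = d)
}

#' Polynomial learning-rate decay
#'
#' `lr = lr0 * (1 - t / T_total)^power`, evaluated per optimizer step, with
#' `T_total = decay_epochs * steps_per_epoch`; clamped at 0 beyond the
#' decay length.
#'
#' @param step Global step index (0-based).
#' @param steps_per_epoch Optimizer steps per epoch.
#' @param cfg A [training_config()].
#' @return The learning rate at `step`.
#' @export
lr_at <- function(step, steps_per_epoch, cfg = training_config()) {
  t_total <- cfg$decay_epochs * steps_per_epoch
  frac <- pmin(pmax(step / t_total, 0), 1)
  cfg$lr0 * (1 - frac)^cfg$decay_power
}

#' Batch-normalization momentum schedule
#'
#' Exponential approach from the starting momentum to the end momentum:
#' `m(e) = end - (end - start) * exp(-5 e / decay_epochs)`, i.e. 0.7 at
#' epoch 0 rising to ~0.899 at the decay length. A low early momentum lets
#' the running statistics track the batches quickly; the high late momentum
#' stabilizes them.
#'
#' @param epoch Epoch index (0-based).
#' @param cfg A [training_config()].
#' @return The momentum at `epoch`.
#' @export
bn_momentum_at <- function(epoch, cfg = training_config()) {
  cfg$bn_momentum_end - (cfg$bn_momentum_end - cfg$bn_momentum_start) *
    exp(-5 * epoch / cfg$decay_epochs)
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(t) list(m = t * 0, v = t * 0))
  })
}

grad_name <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")

adam_step <- function(params, grads, opt, lr, cfg, t) {
  b1 <- cfg$adam_beta1
  b2 <- cfg$adam_beta2
  corr1 <- 1 - b1^t
  corr2 <- 1 - b2^t
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[grad_name[[nm]]]]
      st <- opt[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (st$m / corr1) / (sqrt(st$v / corr2) + cfg$adam_eps)
      opt[[i]][[nm]] <- st
    }
  }
  list(params = params, opt = opt)
}

#' Train a segmentation network on a split patch set
#'
#' Per epoch: shuffle the training patches, iterate batches (last partial
#' batch kept), optionally augment each patch on the fly, normalize
#' (histogram equalization + standardization), forward, weighted
#' cross-entropy, Adam update with the per-step polynomial learning rate
#' and the per-epoch batch-norm momentum; then evaluate validation loss
#' and pixel accuracy (no augmentation, batch statistics off). The model
#' with the lowest validation loss is kept.
#'
#' @param model A `fiberseg_network` (its `spec$dropout` is overridden by
#'   `cfg$dropout`).
#' @param ps A `patch_set` with masks and an assigned train/val split.
#' @param cfg A [training_config()].
#' @param aug An [augmentation_spec()], or `NULL` to disable augmentation.
#' @param epochs Number of epochs to run (default the full decay length;
#'   reduce for desk-scale runs).
#' @param normalize Apply [normalize_patch()] to each patch (default TRUE;
#'   set FALSE if patches are pre-normalized).
#' @param checkpoint_dir If non-`NULL`, the best model is saved there via
#'   [save_model()].
#' @param log_file Optional TSV path receiving one row per epoch.
#' @param verbose Print per-epoch progress to stderr.
#' @return `list(model, history, best_epoch)`; `history` has one row per
#'   epoch (`epoch`, `lr`, `bn_momentum`, `train_loss`, `val_loss`,
#'   `val_accuracy`).
#' @export
train_network <- function(model, ps, cfg = training_config(),
                          aug = augmentation_spec(), epochs = NULL,
                          normalize = TRUE, checkpoint_dir = NULL,
                          log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "fiberseg_network"), inherits(ps, "patch_set"))
  if (is.null(ps$masks)) stop("patch set has no masks")
  train_idx <- which(ps$split == "train")
  val_idx <- which(ps$split == "val")
  if (!length(train_idx)) stop("empty training split")
  if (!length(val_idx)) stop("empty validation split")
  if (is.null(epochs)) epochs <- cfg$decay_epochs
  model$spec$dropout <- cfg$dropout
  steps_per_epoch <- ceiling(length(train_idx) / cfg$batch_size)
  opt <- adam_init(model$params)
  history <- data.frame()
  best <- list(loss = Inf, params = model$params, state = model$state,
               epoch = NA_integer_)
  # pre-normalized validation patches, evaluated in small chunks to bound
  # peak memory
  val_x <- make_batch(ps, val_idx, normalize)
  val_y <- array(unlist(ps$masks[val_idx]),
                 dim = c(ps$patch_size, ps$patch_size, length(val_idx)))
  validate <- function(model) {
    n <- dim(val_x)[4]
    loss <- 0
    correct <- 0
    for (s in seq(1, n, by = 4)) {
      j <- s:min(s + 3, n)
      vf <- nn_forward(model, val_x[, , , j, drop = FALSE],
                       training = FALSE)
      yj <- val_y[, , j, drop = FALSE]
      loss <- loss + length(j) *
        weighted_cross_entropy(vf$probs, yj, cfg$class_weights)
      correct <- correct + sum(channel_argmax(vf$probs) == yj)
    }
    list(loss = loss / n, acc = correct / length(val_y))
  }
  set.seed(cfg$seed)
  step <- 0L
  adam_t <- 0L
  for (epoch in seq_len(epochs) - 1L) {
    mom <- bn_momentum_at(epoch, cfg)
    order <- sample(train_idx)
    ep_loss <- 0
    for (b in seq_len(steps_per_epoch)) {
      idx <- order[((b - 1) * cfg$batch_size + 1):
                     min(b * cfg$batch_size, length(order))]
      idx <- idx[!is.na(idx)]
      xb <- array(0, dim = c(ps$patch_size, ps$patch_size, 1L, length(idx)))
      yb <- array(0L, dim = c(ps$patch_size, ps$patch_size, length(idx)))
      for (j in seq_along(idx)) {
        im <- ps$images[[idx[j]]]
        mk <- ps$masks[[idx[j]]]
        if (!is.null(aug)) {
          a <- augment(im, mk, aug)
          im <- a$image
          mk <- a$mask
        }
        xb[, , 1, j] <- if (normalize) normalize_patch(im) else im
        yb[, , j] <- mk
      }
      lr <- lr_at(step, steps_per_epoch, cfg)
      fw <- nn_forward(model, xb, training = TRUE, bn_momentum = mom,
                       keep_cache = TRUE)
      model$state <- fw$state
      loss <- weighted_cross_entropy(fw$probs, yb, cfg$class_weights)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch, ", batch ", b,
             "; aborting")
      dlogits <- wce_logit_gradient(fw$probs, yb, cfg$class_weights)
      cache <- fw$cache
      rm(fw)
      grads <- nn_backward(model, cache, dlogits)
      rm(cache, dlogits)
      adam_t <- adam_t + 1L
      upd <- adam_step(model$params, grads, opt, lr, cfg, adam_t)
      model$params <- upd$params
      opt <- upd$opt
      ep_loss <- ep_loss + loss * length(idx)
      step <- step + 1L
      rm(grads, upd, xb, yb)
      gc(FALSE)
    }
    ep_loss <- ep_loss / length(train_idx)
    val <- validate(model)
    val_loss <- val$loss
    val_acc <- val$acc
    row <- data.frame(epoch = epoch, lr = lr_at(step, steps_per_epoch, cfg),
                      bn_momentum = mom, train_loss = ep_loss,
                      val_loss = val_loss, val_accuracy = val_acc)
    history <- rbind(history, row)
    if (verbose)
      message(sprintf(
        "epoch %3d  lr %.2e  mom %.3f  train %.4f  val %.4f  acc %.4f",
        epoch, row$lr, mom, ep_loss, val_loss, val_acc))
    if (val_loss < best$loss)
      best <- list(loss = val_loss, params = model$params,
                   state = model$state, epoch = epoch)
  }
  model$params <- best$params
  model$state <- best$state
  if (!is.null(log_file))
    write.table(history, log_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(checkpoint_dir)) save_model(model, checkpoint_dir)
  list(model = model, history = history, best_epoch = best$epoch)
}

make_batch <- function(ps, idx, normalize = TRUE) {
  x <- array(0, dim = c(ps$patch_size, ps$patch_size, 1L, length(idx)))
  for (j in seq_along(idx))
    x[, , 1, j] <- if (normalize) normalize_patch(ps$images[[idx[j]]])
                   else ps$images[[idx[j]]]
  x
}

# per-pixel argmax over the channel dimension, ties to the lowest class
channel_argmax <- function(probs) {
  d <- dim(probs)
  plane <- d[1] * d[2]
  m <- matrix(probs, plane, d[3] * d[4])
  cls <- matrix(0L, plane, d[4])
  for (n in seq_len(d[4])) {
    bestp <- m[, (n - 1L) * d[3] + 1L]
    for (c in 2:d[3]) {
      pc <- m[, (n - 1L) * d[3] + c]
      take <- pc > bestp
      cls[take, n] <- c - 1L
      bestp[take] <- pc[take]
    }
  }
  array(cls, dim = c(d[1], d[2], d[4]))
}
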