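#' Architectural description of the encoder-decoder segmentation network
#'
#' A depth-4 fully convolutional encoder-decoder. Contracting path: per
#' block, `convs_per_block` bias-free convolutions (5x5 kernels in the
#' first block, 3x3 elsewhere), each followed by batch normalization and
#' ReLU, then one channel-preserving 5x5 stride-2 convolution (BN, ReLU)
#' that halves the resolution. Channel widths double per block starting at
#' `base_width` (16 -> 32 -> 64 -> 128 by default). Expanding path, deepest
#' level first: bilinear x2 upsampling followed by a 2x2 convolution down
#' to the skip width (BN, ReLU), concatenation with the block's pre-stride
#' features, then `convs_per_block` convolutions (the first halves the
#' concatenated width; 3x3 kernels except 5x5 at the finest level).
#' A biased 1x1 convolution to 3 channels and a softmax produce per-pixel
#' class probabilities. The `"sem"` variant uses 3 convolutions per block,
#' `"tem"` uses 2; all other structure is shared.
#'
#' @param variant `"sem"` or `"tem"`.
#' @param base_width First-block channel width (default 16; reduce for
#'   desk-scale experiments).
#' @param depth Number of resolution levels (default 4; input sides must be
#'   divisible by `2^depth`).
#' @param dropout Dropout rate on block convolutions during training
#'   (default 0.25).
#' @param convs_per_block Override the per-variant default (3 SEM / 2 TEM).
#' @param pixel_size Working pixel size of the model in micrometers
#'   (default 0.1 for SEM, 0.01 for TEM).
#' @return A `network_spec` object.
#' @export
network_spec <- function(variant = c("sem", "tem"), base_width = 16L,
                         depth = 4L, dropout = 0.25, convs_per_block = NULL,
                         pixel_size = NULL) {
  variant <- match.arg(variant)
  if (is.null(convs_per_block))
    convs_per_block <- if (variant == "sem") 3L else 2L
  if (is.null(pixel_size))
    pixel_size <- if (variant == "sem") 0.1 else 0.01
  structure(list(variant = variant, depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 widths = as.integer(base_width * 2^(seq_len(depth) - 1)),
                 convs_per_block = as.integer(convs_per_block),
                 dropout = dropout, pixel_size = pixel_size, n_classes = 3L),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s: depth %d, widths %s, %d convs/block, dropout %.2f, %g um/pixel\n",
              toupper(x$variant), x$depth,
              paste(x$widths, collapse = "/"), x$convs_per_block, x$dropout,
              x$pixel_size))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

# Ordered forward plan. Entries: conv (k, in_ch, out_ch, stride, bn, bias,
# relu, dropout), store_skip (id), upsample, concat (id).
network_layers <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  conv <- function(k, in_ch, out_ch, stride = 1L, bn = TRUE, bias = FALSE,
                   relu = TRUE, dropout = FALSE)
    list(type = "conv", k = as.integer(k), in_ch = as.integer(in_ch),
         out_ch = as.integer(out_ch), stride = as.integer(stride),
         bn = bn, bias = bias, relu = relu, dropout = dropout)
  layers <- list()
  in_ch <- 1L
  for (b in seq_len(spec$depth)) {
    k <- if (b == 1L) 5L else 3L
    for (j in seq_len(spec$convs_per_block)) {
      layers[[length(layers) + 1L]] <- conv(k, in_ch, spec$widths[b],
                                            dropout = TRUE)
      in_ch <- spec$widths[b]
    }
    layers[[length(layers) + 1L]] <- list(type = "store_skip", id = b)
    layers[[length(layers) + 1L]] <- conv(5L, in_ch, in_ch, stride = 2L)
  }
  for (l in rev(seq_len(spec$depth))) {
    k <- if (l == 1L) 5L else 3L
    layers[[length(layers) + 1L]] <- list(type = "upsample")
    layers[[length(layers) + 1L]] <- conv(2L, in_ch, spec$widths[l])
    in_ch <- spec$widths[l]
    layers[[length(layers) + 1L]] <- list(type = "concat", id = l)
    in_ch <- 2L * in_ch
    for (j in seq_len(spec$convs_per_block)) {
      layers[[length(layers) + 1L]] <- conv(k, in_ch, spec$widths[l],
                                            dropout = TRUE)
      in_ch <- spec$widths[l]
    }
  }
  layers[[length(layers) + 1L]] <- conv(1L, in_ch, spec$n_classes,
                                        bn = FALSE, bias = TRUE, relu = FALSE)
  layers
}

#' Per-layer trainable-parameter ledger
#'
#' One row per convolution in forward order, with the kernel-weight, batch
#' normalization (scale + shift) and bias counts.
#'
#' @param spec A [network_spec()].
#' @return A data frame with columns `kernel`, `in_ch`, `out_ch`, `stride`,
#'   `weights`, `bn`, `bias`.
#' @export
parameter_ledger <- function(spec) {
  layers <- Filter(function(l) l$type == "conv", network_layers(spec))
  do.call(rbind, lapply(layers, function(l)
    data.frame(kernel = l$k, in_ch = l$in_ch, out_ch = l$out_ch,
               stride = l$stride, weights = l$k^2 * l$in_ch * l$out_ch,
               bn = if (l$bn) 2L * l$out_ch else 0L,
               bias = if (l$bias) l$out_ch else 0L)))
}

#' Count trainable parameters of a network specification
#'
#' Sums convolution kernel weights, classifier bias, and batch
#' normalization scale/shift pairs (running statistics are not trainable).
#' The default SEM and TEM variants have 1,953,219 and 1,552,387 trainable
#' parameters respectively.
#'
#' @param spec A [network_spec()].
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(spec) {
  led <- parameter_ledger(spec)
  as.integer(sum(led$weights) + sum(led$bn) + sum(led$bias))
}

#' Instantiate a network with randomly initialized weights
#'
#' Kernel weights use fan-in-scaled (He) normal initialization
#' `N(0, 2/(k^2 in_ch))`; batch-norm scales start at 1, shifts and biases
#' at 0; running statistics at mean 0 / variance 1.
#'
#' @param spec A [network_spec()].
#' @param seed Optional integer seed (caller's RNG preserved).
#' @return A `fiberseg_network` model object.
#' @export
build_network <- function(spec, seed = NULL) {
  layers <- network_layers(spec)
  params <- with_seed(seed, lapply(layers, function(l) {
    if (l$type != "conv") return(NULL)
    p <- list(W = array(rnorm(l$k^2 * l$in_ch * l$out_ch,
                              sd = sqrt(2 / (l$k^2 * l$in_ch))),
                        dim = c(l$k, l$k, l$in_ch, l$out_ch)))
    if (l$bias) p$b <- numeric(l$out_ch)
    if (l$bn) {
      p$gamma <- rep(1, l$out_ch)
      p$beta <- numeric(l$out_ch)
    }
    p
  }))
  state <- lapply(layers, function(l) {
    if (l$type != "conv" || !l$bn) return(NULL)
    list(rmean = numeric(l$out_ch), rvar = rep(1, l$out_ch))
  })
  structure(list(spec = spec, layers = layers, params = params,
                 state = state),
            class = "fiberseg_network")
}

#' @export
print.fiberseg_network <- function(x, ...) {
  np <- count_trainable_parameters(x$spec)
  cat(sprintf("<fiberseg_network> %s variant, %s trainable parameters\n",
              toupper(x$spec$variant), format(np, big.mark = ",")))
  invisible(x)
}

as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 4L)
  x
}

concat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# subtract the per-pixel channel max, exponentiate, normalize;
# operates on the (H*W, C, N) matrix view to avoid dimension dropping
softmax4 <- function(z) {
  d <- dim(z)
  m <- matrix(z, d[1] * d[2], d[3] * d[4])
  for (n in seq_len(d[4])) {
    cols <- (n - 1L) * d[3] + seq_len(d[3])
    sub <- m[, cols, drop = FALSE]
    mx <- sub[, 1]
    for (c in 2:d[3]) mx <- pmax(mx, sub[, c])
    e <- exp(sub - mx)
    m[, cols] <- e / rowSums(e)
  }
  array(m, dim = d)
}

add_channel_bias <- function(z, b) {
  d <- dim(z)
  m <- matrix(z, d[1] * d[2], d[3] * d[4])
  m <- sweep(m, 2, rep(b, d[4]), `+`)
  array(m, dim = d)
}

#' Forward pass: per-pixel 3-class probabilities
#'
#' In evaluation mode (`training = FALSE`, the default) dropout is off and
#' batch normalization uses the stored running statistics, so the output is
#' deterministic. In training mode batch statistics are used and running
#' statistics are updated with momentum `bn_momentum` (the updated state is
#' returned, not applied in place).
#'
#' @param model A `fiberseg_network`.
#' @param x Input batch: matrix, or array `(H, W, 1, N)`; sides must be
#'   divisible by `2^depth`.
#' @param training Use batch statistics and dropout.
#' @param bn_momentum Running-statistic momentum used when `training`.
#' @param keep_cache Keep per-layer activations for backpropagation.
#' @return `list(probs, cache, state)`; `probs` has dim `(H, W, 3, N)` and
#'   sums to 1 over channels at every pixel.
#' @export
nn_forward <- function(model, x, training = FALSE, bn_momentum = 0.9,
                       keep_cache = FALSE) {
  stopifnot(inherits(model, "fiberseg_network"))
  x <- as_batch(x)
  d <- dim(x)
  div <- 2^model$spec$depth
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop("input sides must be divisible by ", div, "; got ",
         d[1], " x ", d[2])
  drop_rate <- if (training) model$spec$dropout else 0
  layers <- model$layers
  cache <- if (keep_cache) vector("list", length(layers))
  state <- model$state
  skips <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "store_skip") {
      skips[[l$id]] <- x
      next
    }
    if (l$type == "upsample") {
      if (keep_cache) cache[[i]] <- list(in_dim = dim(x))
      x <- cpp_upsample2_forward(x)
      next
    }
    if (l$type == "concat") {
      if (keep_cache) cache[[i]] <- list(split_at = dim(x)[3])
      x <- concat_channels(x, skips[[l$id]])
      next
    }
    # conv; BN -> ReLU -> dropout run as one fused kernel
    p <- model$params[[i]]
    x_in <- x
    z <- cpp_conv2d_forward(x_in, p$W, l$stride)
    if (l$bias) z <- add_channel_bias(z, p$b)
    if (l$bn) {
      keep <- if (l$dropout && drop_rate > 0) 1 - drop_rate else 1
      st <- state[[i]]
      po <- cpp_post_forward(z, p$gamma, p$beta, st$rmean, st$rvar,
                             training, 1e-5, l$relu, keep)
      if (training) {
        st$rmean <- bn_momentum * st$rmean + (1 - bn_momentum) * po$mean
        st$rvar <- bn_momentum * st$rvar + (1 - bn_momentum) * po$var
        state[[i]] <- st
      }
      a <- po$y
      if (keep_cache)
        cache[[i]] <- list(x_in = x_in, z = z, bn_mean = po$mean,
                           bn_var = po$var, relu_mask = po$relu_mask,
                           drop_mask = po$drop_mask, keep = keep)
    } else {
      a <- z
      relu_mask <- NULL
      if (l$relu) {
        r <- cpp_relu_forward(a)
        a <- r$y
        relu_mask <- r$mask
      }
      if (keep_cache)
        cache[[i]] <- list(x_in = x_in, z = z, relu_mask = relu_mask,
                           keep = 1)
    }
    x <- a
  }
  probs <- softmax4(x)
  cache_env <- NULL
  if (keep_cache) {
    # held in an environment so backpropagation can release each layer's
    # activations as soon as they have been consumed
    cache_env <- new.env(parent = emptyenv())
    cache_env$layers <- cache
  }
  list(probs = probs, cache = cache_env, state = state)
}

# Backpropagate from the loss gradient w.r.t. the classifier logits.
# Returns a list parallel to model$layers with entries (dW, db, dgamma,
# dbeta) for conv layers.
nn_backward <- function(model, cache, dlogits) {
  layers <- model$layers
  grads <- vector("list", length(layers))
  dx <- dlogits
  d_skips <- list()
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "store_skip") {
      dx <- dx + d_skips[[l$id]]
      d_skips[l$id] <- list(NULL)
      next
    }
    if (l$type == "upsample") {
      d_in <- cache$layers[[i]]$in_dim
      dx <- cpp_upsample2_backward(dx, d_in[1], d_in[2])
      next
    }
    if (l$type == "concat") {
      s <- cache$layers[[i]]$split_at
      d_skips[[l$id]] <- dx[, , (s + 1):dim(dx)[3], , drop = FALSE]
      dx <- dx[, , seq_len(s), , drop = FALSE]
      next
    }
    cc <- cache$layers[[i]]
    cache$layers[i] <- list(NULL)
    p <- model$params[[i]]
    g <- list()
    if (l$bn) {
      bn <- cpp_post_backward(cc$z, dx, p$gamma, cc$bn_mean, cc$bn_var,
                              1e-5, cc$relu_mask, cc$drop_mask, cc$keep)
      g$dgamma <- bn$dgamma
      g$dbeta <- bn$dbeta
      dx <- bn$dx
    } else if (l$relu) {
      dx <- cpp_mask_mul(dx, cc$relu_mask, 1)
    }
    if (l$bias) g$db <- apply(dx, 3, sum)
    cb <- cpp_conv2d_backward(cc$x_in, p$W, dx, l$stride)
    rm(cc)
    g$dW <- cb$dw
    dx <- cb$dx
    grads[[i]] <- g
  }
  grads
}

#' Save / load a trained model
#'
#' `save_model()` writes `weights.rds` (parameters, running statistics) and
#' a human-readable `network_spec.json` sidecar into `dir`.
#'
#' @param model A `fiberseg_network`.
#' @param dir Directory to write to / read from.
#' @return `save_model()` returns `dir`; `load_model()` the model.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "fiberseg_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(params = model$params, state = model$state),
          file.path(dir, "weights.rds"))
  jsonlite::write_json(unclass(model$spec),
                       file.path(dir, "network_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  sp <- jsonlite::read_json(file.path(dir, "network_spec.json"),
                            simplifyVector = TRUE)
  spec <- network_spec(variant = sp$variant, base_width = sp$base_width,
                       depth = sp$depth, dropout = sp$dropout,
                       convs_per_block = sp$convs_per_block,
                       pixel_size = sp$pixel_size)
  wt <- readRDS(file.path(dir, "weights.rds"))
  model <- build_network(spec)
  model$params <- wt$params
  model$state <- wt$state
  model
}
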