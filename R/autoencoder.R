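#' Convolutional auto-encoder specification
#'
#' The encoder is a stack of `n_blocks` 3x3 convolutions with stride 2;
#' channel width starts at `base_channels` and doubles at every block
#' except the last, whose width is chosen so that flattening its output
#' yields exactly `bottleneck_dim` values. All blocks but the last apply
#' batch normalisation then ReLU; the last is linear. The decoder mirrors
#' it: the embedding is reshaped to a (h/2^n x w/2^n) map, then each of
#' `n_blocks` stages applies factor-2 nearest-neighbour up-sampling
#' followed by two (conv + BN + ReLU) blocks, and a final linear 3x3
#' convolution restores the single-channel spectrogram.
#'
#' @param input_shape `c(channels, height, width)`; height and width must
#'   be divisible by `2^n_blocks`.
#' @param bottleneck_dim Embedding dimension; must be divisible by
#'   `(height/2^n_blocks) * (width/2^n_blocks)`.
#' @param base_channels First-block channel width (32 in the reference
#'   configuration; smaller values give a cheaper model for experiments).
#' @param n_blocks Number of stride-2 halvings (default 5).
#' @return An object of class `"ae_spec"`.
#' @examples
#' ae_spec()                       # 128x128 in, 256-D bottleneck
#' ae_spec(c(1, 32, 32), 64, 4)    # toy variant
#' @export
ae_spec <- function(input_shape = c(1L, 128L, 128L), bottleneck_dim = 256L,
                    base_channels = 32L, n_blocks = 5L) {
  h <- input_shape[2]; w <- input_shape[3]
  if (h %% 2^n_blocks != 0 || w %% 2^n_blocks != 0) {
    stop("input spatial dims (", h, "x", w, ") must be divisible by 2^",
         n_blocks)
  }
  hb <- h %/% 2^n_blocks; wb <- w %/% 2^n_blocks
  if (bottleneck_dim %% (hb * wb) != 0) {
    stop("bottleneck_dim (", bottleneck_dim, ") must be divisible by ",
         hb * wb, " (the ", hb, "x", wb, " bottleneck map)")
  }
  structure(list(input_shape = as.integer(input_shape),
                 bottleneck_dim = as.integer(bottleneck_dim),
                 base_channels = as.integer(base_channels),
                 n_blocks = as.integer(n_blocks),
                 kernel = 3L, stride = 2L,
                 bottleneck_hw = c(hb, wb),
                 bottleneck_ch = as.integer(bottleneck_dim %/% (hb * wb))),
            class = "ae_spec")
}

# encoder channel schedule: base * 2^(i-1) for blocks 1..n-1, then the
# bottleneck-determined width
encoder_channels <- function(spec) {
  n <- spec$n_blocks
  c(spec$base_channels * 2^(seq_len(n - 1) - 1), spec$bottleneck_ch)
}

build_encoder <- function(spec) {
  chans <- c(spec$input_shape[1], encoder_channels(spec))
  layers <- list()
  n <- spec$n_blocks
  for (i in seq_len(n)) {
    layers <- c(layers, list(layer_conv(chans[i], chans[i + 1],
                                        kernel = spec$kernel,
                                        stride = spec$stride, pad = 1L)))
    if (i < n) {
      layers <- c(layers, list(layer_bn(chans[i + 1]), layer_relu()))
    }
  }
  c(layers, list(layer_flatten()))
}

build_decoder <- function(spec) {
  n <- spec$n_blocks
  enc <- encoder_channels(spec)
  # mirrored widths: coarse-to-fine, ending at base_channels
  dec <- c(rev(enc[-n]), spec$base_channels)
  chans <- c(spec$bottleneck_ch, dec)
  layers <- list(layer_unflatten(spec$bottleneck_hw[1],
                                 spec$bottleneck_hw[2], spec$bottleneck_ch))
  for (i in seq_len(n)) {
    layers <- c(layers, list(layer_upsample2()))
    for (j in 1:2) {
      cin <- if (j == 1) chans[i] else chans[i + 1]
      layers <- c(layers, list(layer_conv(cin, chans[i + 1],
                                          kernel = spec$kernel,
                                          stride = 1L, pad = 1L),
                               layer_bn(chans[i + 1]), layer_relu()))
    }
  }
  # final linear projection back to the input channel count
  c(layers, list(layer_conv(chans[n + 1], spec$input_shape[1],
                            kernel = spec$kernel, stride = 1L, pad = 1L)))
}

#' Create an untrained auto-encoder
#'
#' @param spec An [ae_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `"autoencoder"` holding encoder and decoder
#'   layer stacks.
#' @export
autoencoder <- function(spec = ae_spec(), seed = 1L) {
  set.seed(seed)
  structure(list(spec = spec,
                 encoder = net_init(build_encoder(spec)),
                 decoder = net_init(build_decoder(spec)),
                 seed = as.integer(seed), trained_steps = 0L),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Convolutional auto-encoder: %dx%dx%d -> %d-D bottleneck\n",
              s$input_shape[1], s$input_shape[2], s$input_shape[3],
              s$bottleneck_dim))
  cat(sprintf("  %d encoder blocks (channels %s), trained %d steps\n",
              s$n_blocks, paste(encoder_channels(s), collapse = ","),
              x$trained_steps))
  invisible(x)
}

#' Number of trainable parameters
#' @param model An `autoencoder`.
#' @return Named vector with encoder/decoder parameter counts.
#' @export
n_parameters <- function(model) {
  count <- function(net) sum(vapply(net, function(l)
    sum(vapply(l$params, length, 1L)), 1L))
  c(encoder = count(model$encoder), decoder = count(model$decoder))
}

# coerce a batch to (H, W, C, B) from (B, C, H, W)-style inputs
as_hwcb <- function(x, spec) {
  if (is.matrix(x)) stop("expected a 4-d spectrogram batch array")
  d <- dim(x)
  tgt <- spec$input_shape  # (C, H, W)
  if (length(d) == 3) {    # (H, W, B) single-channel
    dim(x) <- c(d[1], d[2], 1L, d[3])
    d <- dim(x)
  }
  if (d[1] == tgt[2] && d[2] == tgt[3] && d[3] == tgt[1]) return(x)
  if (d[2] == tgt[1] && d[3] == tgt[2] && d[4] == tgt[3]) {
    return(aperm(x, c(3, 4, 2, 1)))  # (B,C,H,W) -> (H,W,C,B)
  }
  stop("batch shape (", paste(d, collapse = ","),
       ") does not match model input (C,H,W) = (",
       paste(tgt, collapse = ","), ")")
}

#' Encode spectrograms into bottleneck embeddings
#'
#' Runs the encoder in inference mode (batch-norm uses running
#' statistics, so identical inputs give identical embeddings).
#'
#' @param model An [autoencoder()].
#' @param batch Spectrogram array, `(H, W, B)`, `(H, W, 1, B)` or
#'   `(B, 1, H, W)`.
#' @return Matrix `B x bottleneck_dim` of class `"embedding_matrix"` with
#'   attribute `space = "bottleneck"`.
#' @export
encode <- function(model, batch) {
  x <- as_hwcb(batch, model$spec)
  out <- net_forward(model$encoder, x, training = FALSE)$out
  emb <- t(out)
  attr(emb, "space") <- "bottleneck"
  class(emb) <- c("embedding_matrix", class(emb))
  emb
}

#' Decode embeddings back to spectrograms
#'
#' @param model An [autoencoder()].
#' @param embeddings Matrix `B x bottleneck_dim`.
#' @return Array `(H, W, 1, B)` of reconstructions.
#' @export
decode <- function(model, embeddings) {
  if (ncol(embeddings) != model$spec$bottleneck_dim) {
    stop("embeddings have ", ncol(embeddings), " columns; expected ",
         model$spec$bottleneck_dim)
  }
  z <- t(unclass(embeddings))
  net_forward(model$decoder, z, training = FALSE)$out
}

#' Mean squared reconstruction error
#'
#' @param x,x_hat Arrays of identical shape.
#' @return Mean of squared per-bin differences (scalar, >= 0).
#' @export
mse_loss <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat))) {
    stop("shape mismatch: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(x_hat), collapse = "x"))
  }
  mean((x - x_hat)^2)
}

#' Fixed-weight convolutional feature extractor
#'
#' A frozen VGG-style stack of stride-2 3x3 convolution + ReLU stages
#' with random (fixed-seed) weights, used as the default feature space of
#' the perceptual loss. Random convolutional features preserve
#' spectro-temporal structure while discounting diffuse background
#' energy; an ImageNet-trained extractor can be substituted by supplying
#' any function/stack of the same contract.
#'
#' @param in_ch Input channels (1 for spectrograms).
#' @param stages Number of conv+ReLU stages; activations after every
#'   stage are the feature maps compared by [perceptual_loss()].
#' @param width Channel width of the stages.
#' @param seed Seed fixing the random weights.
#' @return A frozen layer stack of class `"feature_extractor"`.
#' @export
feature_extractor <- function(in_ch = 1L, stages = 3L, width = 16L,
                              seed = 17L) {
  set.seed(seed)
  layers <- list()
  chans <- c(in_ch, rep(width, stages))
  for (i in seq_len(stages)) {
    layers <- c(layers, list(layer_conv(chans[i], chans[i + 1],
                                        stride = 2L, pad = 1L),
                             layer_relu()))
  }
  structure(lapply(layers, init_layer_params), class = "feature_extractor")
}

# identity extractor: perceptual loss degenerates to plain MSE
#' @rdname feature_extractor
#' @export
identity_extractor <- function() structure(list(), class = "feature_extractor")

# forward through the frozen extractor collecting post-ReLU feature maps
extractor_forward <- function(extractor, x) {
  if (length(extractor) == 0) {
    return(list(feats = list(x), caches = list(), out = x))
  }
  feats <- list()
  caches <- vector("list", length(extractor))
  for (i in seq_along(extractor)) {
    step <- layer_forward(extractor[[i]], x, training = FALSE)
    x <- step$out
    caches[[i]] <- step$cache
    if (extractor[[i]]$type == "relu") feats[[length(feats) + 1]] <- x
  }
  list(feats = feats, caches = caches, out = x)
}

#' Perceptual reconstruction loss
#'
#' Mean squared difference between feature maps of a frozen third-party
#' (or fixed-random) convolutional network applied to the input and the
#' reconstruction, averaged over feature maps. With the identity
#' extractor this equals [mse_loss()]. Emphasises salient foreground
#' structure (vocalisation contours) over diffuse background noise.
#'
#' @param x,x_hat Arrays of identical shape `(H, W, C, B)`.
#' @param extractor A [feature_extractor()] (default) or
#'   [identity_extractor()].
#' @return Scalar loss >= 0.
#' @export
perceptual_loss <- function(x, x_hat, extractor = feature_extractor()) {
  if (!identical(dim(x), dim(x_hat))) {
    stop("shape mismatch: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(x_hat), collapse = "x"))
  }
  fx <- extractor_forward(extractor, x)$feats
  fy <- extractor_forward(extractor, x_hat)$feats
  losses <- mapply(function(a, b) mean((a - b)^2), fx, fy)
  if (any(!is.finite(losses))) stop("non-finite extractor activations")
  mean(losses)
}

# loss + gradient wrt x_hat, for training
loss_and_grad <- function(x, x_hat, loss = c("perceptual", "mse"),
                          extractor = NULL) {
  loss <- match.arg(loss)
  if (loss == "mse" ||
      (loss == "perceptual" && length(extractor) == 0)) {
    n <- length(x)
    return(list(loss = mean((x - x_hat)^2),
                grad = 2 * (x_hat - x) / n))
  }
  fx <- extractor_forward(extractor, x)
  fy <- extractor_forward(extractor, x_hat)
  k <- length(fy$feats)
  total <- 0
  # accumulate dL/d(feature) at each tap, then backprop through the
  # frozen extractor from the deepest tap down to the input
  dfeats <- vector("list", k)
  for (j in seq_len(k)) {
    diff <- fy$feats[[j]] - fx$feats[[j]]
    total <- total + mean(diff^2)
    dfeats[[j]] <- 2 * diff / (length(diff) * k)
  }
  relu_idx <- which(vapply(extractor, function(l) l$type == "relu", TRUE))
  dout <- array(0, dim(fy$out))
  tap <- k
  for (i in rev(seq_along(extractor))) {
    if (extractor[[i]]$type == "relu" && tap > 0) {
      if (i == relu_idx[tap]) {
        dout <- dout + dfeats[[tap]]
        tap <- tap - 1
      }
    }
    dout <- layer_backward(extractor[[i]], dout, fy$caches[[i]])$dx
  }
  list(loss = total / k, grad = dout)
}

#' Training stop rule on the loss history
#'
#' Training stops when the median loss over the most recent `window`
#' steps has not decreased relative to the median over the `window` steps
#' before it (equality counts as "not decreased"). Returns `FALSE` until
#' `2 * window` steps exist. Only the last `2 * window` values influence
#' the decision.
#'
#' @param history Numeric vector of per-step losses, chronological.
#' @param window Comparison window in steps (default 1000).
#' @return Logical.
#' @examples
#' should_stop(seq(2, 1, length.out = 2000))  # FALSE: still improving
#' should_stop(rep(1, 2000))                  # TRUE: plateau
#' @export
should_stop <- function(history, window = 1000L) {
  n <- length(history)
  if (n < 2L * window) return(FALSE)
  recent <- history[(n - window + 1L):n]
  previous <- history[(n - 2L * window + 1L):(n - window)]
  stats::median(recent) >= stats::median(previous)
}

#' Train the auto-encoder
#'
#' Adam steps on shuffled mini-batches until [should_stop()] fires or
#' `max_steps` is reached. All randomness (weight init happens at
#' [autoencoder()] creation; here batch shuffling) is governed by `seed`,
#' so runs are reproducible.
#'
#' @param model An [autoencoder()].
#' @param batch Spectrogram array accepted by [encode()]; all units of
#'   the training set.
#' @param loss `"perceptual"` (default) or `"mse"`.
#' @param extractor Feature extractor for the perceptual loss; default
#'   [feature_extractor()] matched to the input channel count.
#' @param batch_size Mini-batch size (reference setting 128).
#' @param lr Adam learning rate.
#' @param window Stop-rule window in steps (reference setting 1000).
#' @param max_steps Hard cap guaranteeing termination.
#' @param seed Seed for batch shuffling.
#' @param verbose Print progress every 100 steps.
#' @return The model with trained weights and a `history` element (per-
#'   step losses).
#' @export
train_autoencoder <- function(model, batch, loss = c("perceptual", "mse"),
                              extractor = NULL, batch_size = 128L,
                              lr = 1e-3, window = 1000L, max_steps = 100000L,
                              seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  x_all <- as_hwcb(batch, model$spec)
  n <- dim(x_all)[4]
  if (n < 1) stop("empty training batch")
  if (loss == "perceptual" && is.null(extractor)) {
    extractor <- feature_extractor(in_ch = model$spec$input_shape[1])
  }
  set.seed(seed)
  enc <- model$encoder
  dec <- model$decoder
  st_enc <- adam_init(enc)
  st_dec <- adam_init(dec)
  history <- numeric(0)
  step <- 0L
  order_pool <- integer(0)
  while (step < max_steps) {
    step <- step + 1L
    if (length(order_pool) < batch_size) {
      order_pool <- c(order_pool, sample.int(n))
    }
    take <- order_pool[seq_len(min(batch_size, n))]
    order_pool <- order_pool[-seq_len(min(batch_size, n))]
    xb <- x_all[, , , take, drop = FALSE]

    fe <- net_forward(enc, xb, training = TRUE)
    fd <- net_forward(dec, fe$out, training = TRUE)
    enc <- fe$net; dec <- fd$net
    lg <- loss_and_grad(xb, fd$out, loss, extractor)
    if (!is.finite(lg$loss)) {
      stop("non-finite loss at step ", step, "; try a lower learning rate")
    }
    bd <- net_backward(dec, lg$grad, fd$caches)
    be <- net_backward(enc, bd$dx, fe$caches)
    upd <- adam_step(dec, bd$grads, st_dec, step, lr)
    dec <- upd$net; st_dec <- upd$state
    upd <- adam_step(enc, be$grads, st_enc, step, lr)
    enc <- upd$net; st_enc <- upd$state

    history[step] <- lg$loss
    if (verbose && step %% 100L == 0L) {
      message("step ", step, " loss ", signif(lg$loss, 4))
    }
    if (should_stop(history, window)) break
  }
  model$encoder <- enc
  model$decoder <- dec
  model$history <- history
  model$trained_steps <- model$trained_steps + step
  model$loss <- loss
  model
}

#' Save / load an auto-encoder checkpoint
#'
#' Weights, running statistics and the architecture spec are serialised
#' together so a checkpoint restores an identical model.
#'
#' @param model An [autoencoder()].
#' @param path Checkpoint file path (`.rds`).
#' @return `save_autoencoder` returns `path` invisibly; `load_autoencoder`
#'   returns the model.
#' @export
save_autoencoder <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "autoencoder"))
  model
}
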