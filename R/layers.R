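# Minimal layer framework backing the auto-encoder. Activations are R
# arrays of dim (H, W, C, B); each layer implements forward/backward and
# exposes its trainable parameters as named arrays. Convolutions run in
# compiled code (src/conv_ops.cpp); batch-norm, ReLU and up-sampling are
# cheap enough in vectorised R.

layer_conv <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch,
       kernel = as.integer(kernel), stride = as.integer(stride),
       pad = as.integer(pad),
       params = list(
         W = array(0, c(kernel, kernel, in_ch, out_ch)),
         b = numeric(out_ch)
       ))
}

layer_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", ch = ch, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       state = list(mean = numeric(ch), var = rep(1, ch)))
}

layer_relu <- function() list(type = "relu", params = list())

layer_upsample2 <- function() list(type = "upsample2", params = list())

# reshape between (H,W,C,B) activations and (d, B) embedding matrices
layer_flatten <- function() list(type = "flatten", params = list())
layer_unflatten <- function(h, w, c) {
  list(type = "unflatten", h = h, w = w, c = c, params = list())
}

# He-uniform initialisation; draws consume the caller's RNG stream so a
# single set.seed() makes whole-network init reproducible.
init_layer_params <- function(layer) {
  if (layer$type == "conv") {
    fan_in <- layer$kernel^2 * layer$in_ch
    bound <- sqrt(6 / fan_in)
    layer$params$W[] <- stats::runif(length(layer$params$W), -bound, bound)
    layer$params$b[] <- 0
  }
  layer
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      out <- conv2d_forward(x, layer$params$W, layer$params$b,
                            layer$stride, layer$pad)
      list(out = out, cache = list(x = x), layer = layer)
    },
    bn = {
      if (training) {
        st <- bn_stats(x)
        mu <- st$mean
        v <- st$var
        layer$state$mean <- (1 - layer$momentum) * layer$state$mean +
          layer$momentum * mu
        layer$state$var <- (1 - layer$momentum) * layer$state$var +
          layer$momentum * v
      } else {
        mu <- layer$state$mean
        v <- layer$state$var
      }
      ap <- bn_apply(x, layer$params$gamma, layer$params$beta, mu, v,
                     layer$eps, keep_xhat = TRUE)
      list(out = ap$y, cache = list(xhat = ap$xhat, var = v,
                                    training = training),
           layer = layer)
    },
    relu = {
      out <- relu_forward(x)
      list(out = out, cache = list(out = out), layer = layer)
    },
    upsample2 = {
      list(out = upsample2_forward(x), cache = list(), layer = layer)
    },
    flatten = {
      d <- dim(x)
      out <- x
      dim(out) <- c(prod(d[1:3]), d[4])
      list(out = out, cache = list(d = d), layer = layer)
    },
    unflatten = {
      out <- x
      dim(out) <- c(layer$h, layer$w, layer$c, ncol(x))
      list(out = out, cache = list(), layer = layer)
    },
    stop("unknown layer type ", layer$type)
  )
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      g <- conv2d_backward(cache$x, layer$params$W, dout,
                           layer$stride, layer$pad)
      list(dx = g$dx, grads = list(W = g$dw, b = g$db))
    },
    bn = {
      g <- bn_backward_cpp(cache$xhat, dout, layer$params$gamma,
                           cache$var, layer$eps, cache$training)
      list(dx = g$dx, grads = list(gamma = g$dgamma, beta = g$dbeta))
    },
    relu = {
      list(dx = relu_backward(dout, cache$out), grads = list())
    },
    upsample2 = {
      list(dx = upsample2_backward(dout), grads = list())
    },
    flatten = {
      dx <- dout
      dim(dx) <- cache$d
      list(dx = dx, grads = list())
    },
    unflatten = {
      dx <- dout
      dim(dx) <- c(layer$h * layer$w * layer$c, dim(dout)[4])
      list(dx = dx, grads = list())
    }
  )
}

net_init <- function(layers, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(layers, init_layer_params)
}

# Forward pass through a list of layers. Returns the output, the list of
# per-layer caches, and the (possibly state-updated, for BN) layers.
net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    step <- layer_forward(net[[i]], x, training)
    x <- step$out
    caches[[i]] <- step$cache
    net[[i]] <- step$layer
  }
  list(out = x, caches = caches, net = net)
}

# Backward pass; returns gradient wrt the input and per-layer gradients
# aligned with the network list.
net_backward <- function(net, dout, caches) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    step <- layer_backward(net[[i]], dout, caches[[i]])
    dout <- step$dx
    grads[[i]] <- step$grads
  }
  list(dx = dout, grads = grads)
}

# ---- Adam optimiser over the nested layer-parameter structure ----

adam_init <- function(net) {
  lapply(net, function(l) lapply(l$params, function(p) {
    list(m = p * 0, v = p * 0)
  }))
}

adam_step <- function(net, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net)) {
    for (nm in names(net[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net[[i]]$params[[nm]] <- net[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}
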