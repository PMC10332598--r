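test_that("encoder and decoder are shape-inverse across size variants", {
  # reference geometry: 128x128 in, 256-D bottleneck, 5 halvings
  spec <- ae_spec()
  expect_equal(vocclust:::encoder_channels(spec), c(32, 64, 128, 256, 16))
  model <- autoencoder(ae_spec(base_channels = 4L), seed = 1)
  x <- array(rnorm(128 * 128 * 2), c(2, 1, 128, 128))  # (B,1,H,W) order
  emb <- encode(model, x)
  expect_equal(dim(emb), c(2L, 256L))
  rec <- decode(model, emb)
  expect_equal(dim(rec), c(128L, 128L, 1L, 2L))
  expect_true(all(is.finite(rec)))

  # k * 2^n variants: 32x32 (k=1) and 64x64 (k=2)
  for (hw in c(32L, 64L)) {
    sp <- ae_spec(c(1L, hw, hw), bottleneck_dim = (hw / 32)^2 * 16L,
                  base_channels = 4L)
    m <- autoencoder(sp, seed = 2)
    xb <- array(rnorm(hw * hw * 3), c(hw, hw, 1, 3))
    e <- encode(m, xb)
    expect_equal(ncol(e), sp$bottleneck_dim)
    expect_equal(dim(decode(m, e)), c(hw, hw, 1L, 3L))
  }
  # spatial shrinkage 128 -> 4 over five stride-2 blocks
  expect_equal(128 / 2^spec$n_blocks, 4)
  expect_error(ae_spec(c(1L, 96L, 96L)), "divisible")
  expect_error(ae_spec(bottleneck_dim = 100L), "divisible")
  expect_error(encode(model, array(0, c(64, 64, 1, 2))), "does not match")
  expect_error(decode(model, matrix(0, 2, 100)), "expected 256")
})

test_that("identical inputs give identical embeddings in inference mode", {
  model <- autoencoder(ae_spec(c(1L, 32L, 32L), 16L, 4L), seed = 3)
  set.seed(4)
  one <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  batch <- array(c(one, one), c(32, 32, 1, 2))
  emb <- encode(model, batch)
  expect_identical(emb[1, ], emb[2, ])
  expect_identical(encode(model, one), encode(model, one))
})

test_that("parameter counts are a pure function of the architecture spec", {
  count_expected <- function(spec) {
    chans <- c(spec$input_shape[1], vocclust:::encoder_channels(spec))
    enc <- 0
    for (i in seq_len(spec$n_blocks)) {
      enc <- enc + 9 * chans[i] * chans[i + 1] + chans[i + 1]    # conv W+b
      if (i < spec$n_blocks) enc <- enc + 2 * chans[i + 1]       # BN
    }
    dec_ch <- c(spec$bottleneck_ch,
                rev(chans[2:spec$n_blocks]), spec$base_channels)
    dec <- 0
    for (i in seq_len(spec$n_blocks)) {
      for (j in 1:2) {
        cin <- if (j == 1) dec_ch[i] else dec_ch[i + 1]
        dec <- dec + 9 * cin * dec_ch[i + 1] + dec_ch[i + 1] +
          2 * dec_ch[i + 1]
      }
    }
    dec <- dec + 9 * dec_ch[spec$n_blocks + 1] * spec$input_shape[1] +
      spec$input_shape[1]
    c(encoder = enc, decoder = dec)
  }
  for (spec in list(ae_spec(base_channels = 8L),
                    ae_spec(c(1L, 32L, 32L), 64L, 4L))) {
    expect_equal(n_parameters(autoencoder(spec, seed = 1)),
                 count_expected(spec))
  }
})

test_that("losses match brute-force oracles", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  expect_equal(mse_loss(x, x), 0)
  expect_equal(mse_loss(array(0, c(4, 4, 1, 1)), array(1, c(4, 4, 1, 1))), 1)
  # elementwise loop oracle
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  expect_equal(mse_loss(x, y), acc / length(x))
  expect_error(mse_loss(x, array(0, c(4, 4, 1, 2))), "mismatch")

  ex <- feature_extractor(1, stages = 2, width = 4, seed = 6)
  expect_equal(perceptual_loss(x, x, ex), 0)
  expect_equal(perceptual_loss(x, y, ex), perceptual_loss(y, x, ex))
  expect_gt(perceptual_loss(x, y, ex), 0)
  expect_equal(perceptual_loss(x, y, identity_extractor()), mse_loss(x, y))
})

test_that("backpropagated gradients match numerical differentiation", {
  ns <- asNamespace("vocclust")
  set.seed(7)
  net <- ns$net_init(list(
    ns$layer_conv(2, 3, stride = 2L, pad = 1L), ns$layer_bn(3),
    ns$layer_relu(), ns$layer_upsample2(),
    ns$layer_conv(3, 2, stride = 1L, pad = 1L)
  ))
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  target <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  lossfun <- function(net, x) {
    mean((ns$net_forward(net, x, TRUE)$out - target)^2)
  }
  fwd <- ns$net_forward(net, x, TRUE)
  bk <- ns$net_backward(fwd$net, 2 * (fwd$out - target) / length(target),
                        fwd$caches)
  eps <- 1e-6
  idx <- sample(length(x), 15)
  num <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (lossfun(net, xp) - lossfun(net, xm)) / (2 * eps)
  }, 1.0)
  expect_equal(num, bk$dx[idx], tolerance = 1e-6)
  for (li in c(1, 2, 5)) {
    for (nm in names(net[[li]]$params)) {
      p <- net[[li]]$params[[nm]]
      ids <- sample(length(p), min(6, length(p)))
      num <- vapply(ids, function(i) {
        np <- net; np[[li]]$params[[nm]][i] <- p[i] + eps
        nmn <- net; nmn[[li]]$params[[nm]][i] <- p[i] - eps
        (lossfun(np, x) - lossfun(nmn, x)) / (2 * eps)
      }, 1.0)
      expect_equal(num, bk$grads[[li]][[nm]][ids], tolerance = 1e-5,
                   ignore_attr = TRUE)
    }
  }
  # perceptual loss gradient wrt the reconstruction
  ex <- feature_extractor(2, stages = 2, width = 4, seed = 8)
  xh <- array(rnorm(length(x)), dim(x))
  lg <- ns$loss_and_grad(x, xh, "perceptual", ex)
  ids <- sample(length(xh), 10)
  num <- vapply(ids, function(i) {
    a <- xh; a[i] <- a[i] + eps
    b <- xh; b[i] <- b[i] - eps
    (perceptual_loss(x, a, ex) - perceptual_loss(x, b, ex)) / (2 * eps)
  }, 1.0)
  expect_equal(num, lg$grad[ids], tolerance = 1e-6)
})

test_that("stop rule compares medians of consecutive windows", {
  expect_false(should_stop(seq(2, 1, length.out = 2000)))
  expect_true(should_stop(rep(1, 2000)))
  expect_false(should_stop(rep(1, 1999)))          # needs 2 windows
  # constructed medians: previous 1.0, recent 0.9 -> keep training
  h <- c(rep(1.0, 1000), rep(0.9, 1000))
  expect_false(should_stop(h))
  # rising again -> stop
  expect_true(should_stop(c(rep(0.9, 1000), rep(1.0, 1000))))
  # invariant to anything older than 2 * window
  old <- runif(500)
  expect_identical(should_stop(c(old, h)), should_stop(h))
  # shorter windows
  expect_true(should_stop(c(2, 2, 5, 4), window = 2))
  expect_false(should_stop(c(5, 4, 2, 2), window = 2))
})

test_that("training reduces the loss and is seed-reproducible", {
  ds <- tiny_repertoire(n_types = 2L, n_per_type = 12L, seed = 21L)
  batch <- make_spectrograms(ds$annotations, tiny_config())
  spec <- ae_spec(c(1L, 32L, 32L), 32L, 4L)
  m1 <- train_autoencoder(autoencoder(spec, seed = 1), batch$values,
                          loss = "mse", batch_size = 8L, max_steps = 60L,
                          seed = 1)
  expect_length(m1$history, 60L)
  expect_true(all(is.finite(m1$history)))
  q <- 60 %/% 4
  expect_lt(median(m1$history[(60 - q + 1):60]), median(m1$history[1:q]))
  # same seed, same data -> identical loss history
  m2 <- train_autoencoder(autoencoder(spec, seed = 1), batch$values,
                          loss = "mse", batch_size = 8L, max_steps = 60L,
                          seed = 1)
  expect_identical(m1$history, m2$history)
  # perceptual loss runs to termination on the same data
  m3 <- train_autoencoder(autoencoder(spec, seed = 1), batch$values,
                          loss = "perceptual", batch_size = 8L,
                          max_steps = 10L, seed = 1)
  expect_length(m3$history, 10L)
  # checkpoints restore an identical model
  path <- withr::local_tempfile(fileext = ".rds")
  save_autoencoder(m1, path)
  m4 <- load_autoencoder(path)
  xb <- batch$values[, , 1:3]
  expect_identical(encode(m4, xb), encode(m1, xb))
})

test_that("embeddings of a discrete 2-type repertoire are linearly separable", {
  ds <- tiny_repertoire(n_types = 2L, n_per_type = 30L, seed = 31L,
                        snr_db = 30)
  batch <- make_spectrograms(ds$annotations, tiny_config())
  spec <- ae_spec(c(1L, 32L, 32L), 64L, 4L)
  model <- train_autoencoder(autoencoder(spec, seed = 1), batch$values,
                             loss = "mse", batch_size = 16L,
                             max_steps = 150L, seed = 1)
  emb <- encode(model, batch$values)
  y <- as.integer(factor(ds$annotations$label))
  set.seed(32)
  test_idx <- sample(length(y), 20)
  # nearest-centroid probe: a linear decision rule fit on held-in units
  centroids <- rbind(colMeans(emb[-test_idx, ][y[-test_idx] == 1, ]),
                     colMeans(emb[-test_idx, ][y[-test_idx] == 2, ]))
  d2 <- as.matrix(dist(rbind(centroids, emb[test_idx, ])))[-(1:2), 1:2]
  pred <- max.col(-d2)
  expect_gte(mean(pred == y[test_idx]), 0.95)
})
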