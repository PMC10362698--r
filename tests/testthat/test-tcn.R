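test_that("dilated causal convolution matches the hand-computed example", {
  # k = 2, d = 2, single channel, taps (1, 1): out_t = x_{t-2} + x_t
  w <- array(c(1, 1), c(1, 1, 2))
  x <- matrix(c(1, 2, 3, 4, 5), 1)
  expect_equal(causal_dilated_conv(x, w, d = 2), matrix(c(1, 2, 4, 6, 8), 1))

  # k = 1: pointwise linear map regardless of dilation
  w1 <- array(2.5, c(1, 1, 1))
  expect_equal(causal_dilated_conv(x, w1, d = 3), 2.5 * x)
  expect_error(causal_dilated_conv(x, w, d = 0), "dilation")
})

test_that("convolution output before a perturbed column never changes", {
  set.seed(11)
  x <- matrix(rnorm(3 * 20), 3, 20)
  w <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  base <- causal_dilated_conv(x, w, d = 4)
  for (j in c(5, 12, 20)) {
    xp <- x; xp[, j] <- xp[, j] + 1
    pert <- causal_dilated_conv(xp, w, d = 4)
    if (j > 1) expect_equal(pert[, 1:(j - 1)], base[, 1:(j - 1)])
    expect_false(isTRUE(all.equal(pert[, j], base[, j])))
  }
})

test_that("stride recursion gives the textbook receptive fields", {
  expect_equal(receptive_field(list(list(k = 1, s = 1))), 1)
  expect_equal(receptive_field(list(list(k = 2, s = 1), list(k = 2, s = 1))), 3)
  # dilation-aware: two layers k=2, d=(1,2) span 4 columns
  expect_equal(receptive_field_dilated(list(list(k = 2, s = 1, d = 1),
                                            list(k = 2, s = 1, d = 2))), 4)
})

test_that("residual block honors zero-residual, causality and shapes", {
  model <- probe_model(1)
  blk <- model$params$blocks[[1]]

  # zero residual path, identity-ish skip: with all conv weights zero the
  # block reduces to ReLU(skip(x)); make the skip the identity manually
  ident <- blk
  ident$c1$V[] <- 0; ident$c1$g[] <- 0; ident$c1$b[] <- 0
  ident$c2$V[] <- 0; ident$c2$g[] <- 0; ident$c2$b[] <- 0
  n_out <- nrow(ident$skip$V)
  ident$skip$V <- diag(1, n_out, 21)
  ident$skip$g <- rep(1, n_out); ident$skip$b <- rep(0, n_out)
  x <- abs(matrix(rnorm(21 * 10), 21, 10))
  out <- residual_block(x, ident, k = 2, d = 1)
  expect_equal(out, x[1:n_out, ])

  # channel-changing shape contract
  x2 <- matrix(abs(rnorm(21 * 15)), 21, 15)
  out2 <- residual_block(x2, blk, k = 2, d = 1)
  expect_equal(dim(out2), c(n_out, 15))

  # causality inherited by the block
  base <- residual_block(x2, blk, k = 2, d = 1)
  xp <- x2; xp[, 9] <- xp[, 9] + 1
  pert <- residual_block(xp, blk, k = 2, d = 1)
  expect_equal(pert[, 1:8], base[, 1:8])
})

test_that("whole encoder stack is causal for random weights at L = 64", {
  for (nb in c(2, 3)) {
    model <- probe_model(nb)
    set.seed(nb)
    x <- matrix(abs(rnorm(21 * 64)), 21, 64)
    base <- run_blocks(x, model)
    for (j in c(10, 33, 64)) {
      xp <- x; xp[, j] <- xp[, j] + 0.5
      pert <- run_blocks(xp, model)
      if (j > 1)
        expect_equal(pert[, 1:(j - 1)], base[, 1:(j - 1)], tolerance = 1e-12)
    }
  }
})

test_that("dilation-aware recursion equals the empirical dependency span", {
  # brute-force probe: widest (t - j + 1) with nonzero sensitivity
  for (nb in 1:4) {
    model <- probe_model(nb)
    layers <- tcn_layers(model$tcn, nb)
    layers <- layers[rep(seq_len(nrow(layers)), each = 2), ]  # 2 convs/block
    rf_pred <- receptive_field_dilated(layers)
    L <- 64L
    x <- matrix(1, 21, L)
    base <- run_blocks(x, model)
    t_out <- L
    touched <- logical(L)
    for (j in seq_len(L)) {
      xp <- x; xp[, j] <- xp[, j] + 1
      pert <- run_blocks(xp, model)
      touched[j] <- any(abs(pert[, t_out] - base[, t_out]) > 1e-10)
    }
    rf_probe <- t_out - min(which(touched)) + 1L
    expect_equal(rf_probe, rf_pred)
  }
})

test_that("default configuration records the full-scale hyperparameters", {
  cfg <- tcn_config()
  expect_equal(cfg$kernel_size, 2L)
  expect_equal(cfg$stride, 1L)
  expect_equal(cfg$dilation_base, 2L)
  expect_equal(cfg$dropout, 0.2)
  expect_equal(cfg$out_channels, 100L)
  expect_equal(cfg$n_blocks, 3L)
})

test_that("analytic gradients match finite differences on a small model", {
  set.seed(7)
  L <- 8; N <- 3
  fam <- random_family(N, L, seed = 7)
  fam$weights <- c(0.8, 1.2, 1.0)
  tcn <- tcn_config(n_blocks = 2, hidden_channels = 5, out_channels = 6,
                    dropout = 0)
  cfg <- train_config(epochs = 1, dim_z = 2, hidden_layer = 7, seed = 3)
  model <- vae_init(L, tcn, cfg)
  x3 <- tvae:::.family_onehot(fam)
  loss_fn <- function(m) {
    set.seed(99)
    tvae:::.vae_step(x3, fam$weights, m, train = TRUE)$loss
  }
  set.seed(99)
  step <- tvae:::.vae_step(x3, fam$weights, model, train = TRUE)

  paths <- list(c("out", "W"), c("fc", "W"), c("mu", "W"), c("lv", "b"))
  for (p in paths) {
    g <- step$grads[[p[1]]][[p[2]]]
    set.seed(sum(utf8ToInt(paste(p, collapse = ""))))
    for (i in sample(length(g), min(3, length(g)))) {
      m2 <- model; m3 <- model
      m2$params[[p[1]]][[p[2]]][i] <- m2$params[[p[1]]][[p[2]]][i] + 1e-5
      m3$params[[p[1]]][[p[2]]][i] <- m3$params[[p[1]]][[p[2]]][i] - 1e-5
      fd <- (loss_fn(m2) - loss_fn(m3)) / 2e-5
      expect_equal(g[i], fd, tolerance = 1e-4)
    }
  }
  # block parameters, including weight-norm scales and the skip projection
  for (spec in list(c(1, "c1", "V"), c(1, "skip", "g"), c(2, "c2", "V"))) {
    b <- as.integer(spec[1]); comp <- spec[2]; fld <- spec[3]
    g <- step$grads$blocks[[b]][[comp]][[fld]]
    for (i in sample(length(g), 3)) {
      m2 <- model; m3 <- model
      m2$params$blocks[[b]][[comp]][[fld]][i] <-
        m2$params$blocks[[b]][[comp]][[fld]][i] + 1e-5
      m3$params$blocks[[b]][[comp]][[fld]][i] <-
        m3$params$blocks[[b]][[comp]][[fld]][i] - 1e-5
      fd <- (loss_fn(m2) - loss_fn(m3)) / 2e-5
      expect_equal(g[i], fd, tolerance = 1e-4)
    }
  }
})
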