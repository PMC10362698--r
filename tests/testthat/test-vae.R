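test_that("closed-form KL matches analytic anchor points", {
  expect_equal(kl_to_standard_normal(rep(0, 4), rep(0, 4)), 0)
  expect_equal(kl_to_standard_normal(1, 0), 0.5)
  expect_gt(kl_to_standard_normal(c(0.3, -1), c(0.2, 0.4)), 0)
})

test_that("closed-form KL agrees with a Monte-Carlo estimate", {
  # E_q[log q(z) - log p(z)] over a large seeded sample
  set.seed(101)
  for (rep in 1:5) {
    d <- 3
    mu <- runif(d, -2, 2)
    lv <- runif(d, -1, 1)
    n <- 2e5
    z <- matrix(rnorm(n * d), n, d, byrow = FALSE)
    z <- sweep(sweep(z, 2, exp(0.5 * lv), "*"), 2, mu, "+")
    logq <- rowSums(dnorm(z, mean = rep(mu, each = n),
                          sd = rep(exp(0.5 * lv), each = n), log = TRUE))
    logp <- rowSums(dnorm(z, log = TRUE))
    mc <- mean(logq - logp)
    expect_equal(kl_to_standard_normal(mu, lv), mc, tolerance = 0.02)
  }
})

test_that("reparameterisation is seeded, unbiased and degenerates to mu", {
  mu <- c(1.5, -2); lv <- c(0.4, -0.6)
  z1 <- reparameterize(mu, lv, seed = 7)
  z2 <- reparameterize(mu, lv, seed = 7)
  expect_identical(z1, z2)

  # sigma -> 0 limit
  expect_equal(reparameterize(mu, c(-Inf, -Inf), seed = 1), mu)

  # CLT: mean of many draws near mu
  set.seed(11)
  draws <- replicate(2e4, reparameterize(mu, lv))
  se <- exp(0.5 * lv) / sqrt(2e4)
  expect_true(all(abs(rowMeans(draws) - mu) < 4 * se))
})

test_that("decoder emits normalized, deterministic categoricals", {
  model <- vae_init(12, tcn_config(n_blocks = 1, hidden_channels = 4,
                                   out_channels = 4, dropout = 0),
                    train_config(dim_z = 2, hidden_layer = 5, seed = 2))
  z <- c(0.3, -1.1)
  p1 <- vae_decode(z, model)
  expect_equal(dim(p1), c(21, 12, 1))
  expect_equal(apply(p1[, , 1], 2, sum), rep(1, 12), tolerance = 1e-6)
  expect_identical(p1, vae_decode(z, model))

  # zero output layer -> uniform 1/21 everywhere
  model$params$out$W[] <- 0; model$params$out$b[] <- 0
  pu <- vae_decode(z, model)
  expect_equal(as.numeric(pu), rep(1 / 21, 21 * 12), tolerance = 1e-12)
})

test_that("ELBO components behave at the analytic corners", {
  x <- encode_onehot(c(0L, 3L, 17L))
  # perfect reconstruction, zero KL
  comp <- elbo_loss(x, rep(0, 2), rep(0, 2), x, weight = 1)
  expect_equal(comp$reconstruction, 0)
  expect_equal(comp$kl, 0)
  expect_equal(comp$elbo, 0)

  # uniform decoder: reconstruction = -L log 21
  unif <- matrix(1 / 21, 21, 3)
  comp2 <- elbo_loss(x, c(1, 0), c(0, 0), unif, weight = 2)
  expect_equal(comp2$reconstruction, -3 * log(21))
  expect_equal(comp2$elbo, comp2$reconstruction - comp2$kl)
  expect_equal(comp2$loss, 2 * (comp2$kl - comp2$reconstruction))
  expect_lte(comp2$elbo, comp2$reconstruction)
})

test_that("encoding is deterministic in evaluation mode with finite logvar", {
  model <- vae_init(10, tiny_tcn(dropout = 0.2),
                    train_config(dim_z = 3, hidden_layer = 8, seed = 4))
  set.seed(9)
  x <- encode_onehot(sample(0:20, 10, replace = TRUE))
  e1 <- vae_encode(x, model)
  e2 <- vae_encode(x, model)
  expect_identical(e1, e2)
  expect_equal(nrow(e1$mu), 3)
  expect_true(all(is.finite(e1$log_var)))
})

test_that("short training increases the ELBO and is seed-reproducible", {
  fam <- simulate_family(n_leaves = 12, L = 16, seed = 5)$family
  cfg <- train_config(epochs = 60, dim_z = 2, hidden_layer = 16,
                      learning_rate = 2e-3, seed = 11)
  tcn <- tcn_config(n_blocks = 2, hidden_channels = 8, out_channels = 12,
                    dropout = 0.1)
  m1 <- vae_train(fam, cfg, tcn)
  expect_gt(m1$trace$elbo[nrow(m1$trace)], m1$trace$elbo[1])
  expect_true(all(is.finite(m1$trace$kl)))

  m2 <- vae_train(fam, cfg, tcn)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$trace, m2$trace)
})

test_that("fine-tuning validates length and is a no-op at 0 epochs", {
  fam <- suppressWarnings(simulate_family(n_leaves = 8, L = 12, seed = 6))$family
  cfg <- train_config(epochs = 5, dim_z = 2, hidden_layer = 8, seed = 3)
  tcn <- tcn_config(n_blocks = 1, hidden_channels = 6, out_channels = 8,
                    dropout = 0)
  model <- vae_train(fam, cfg, tcn)

  same <- vae_fine_tune(model, fam, train_config(epochs = 0, dim_z = 2,
                                                 hidden_layer = 8))
  expect_identical(same$params, model$params)

  other <- simulate_family(n_leaves = 6, L = 20, seed = 7)$family
  expect_error(vae_fine_tune(model, other, cfg), "length mismatch")

  more <- vae_fine_tune(model, fam, train_config(epochs = 5, dim_z = 2,
                                                 hidden_layer = 8, seed = 4))
  expect_false(identical(more$params, model$params))
})

test_that("fine-tuning on a held-out clade improves its reconstruction", {
  sim <- simulate_family(n_leaves = 40, L = 24, rate = 0.4, threshold = 1.0,
                         seed = 20)
  lab <- sim$labels
  big <- names(which.max(table(lab)))
  hold <- which(lab == as.integer(big))
  rest <- setdiff(seq_along(lab), hold)
  sub <- function(fam, idx) {
    structure(list(ids = fam$ids[idx],
                   matrix = fam$matrix[idx, , drop = FALSE], L = fam$L,
                   weights = rep(1, length(idx))), class = "aligned_family")
  }
  train_fam <- sub(sim$family, rest)
  held_fam <- sub(sim$family, hold)
  cfg <- train_config(epochs = 150, dim_z = 2, hidden_layer = 24,
                      learning_rate = 2e-3, seed = 8)
  tcn <- tcn_config(n_blocks = 2, hidden_channels = 12, out_channels = 16,
                    dropout = 0)
  model <- vae_train(train_fam, cfg, tcn)

  recon_ll <- function(m, fam) {
    enc <- vae_encode(fam, m)
    probs <- vae_decode(enc$mu, m)
    x3 <- tvae:::.family_onehot(fam)
    sum(log(pmax(probs, 1e-300)) * x3)
  }
  before <- recon_ll(model, held_fam)
  tuned <- vae_fine_tune(model, held_fam,
                         train_config(epochs = 150, dim_z = 2,
                                      hidden_layer = 24,
                                      learning_rate = 2e-3, seed = 9))
  after <- recon_ll(tuned, held_fam)
  expect_gt(after, before)
})

test_that("family embedding has the right shape and collapses duplicates", {
  fam <- simulate_family(n_leaves = 10, L = 14, seed = 9)$family
  model <- vae_init(14, tcn_config(n_blocks = 1, hidden_channels = 4,
                                   out_channels = 6, dropout = 0),
                    train_config(dim_z = 2, hidden_layer = 6, seed = 1))
  emb <- embed_family(fam, model)
  expect_equal(dim(emb), c(10, 2))
  expect_equal(rownames(emb), fam$ids)

  dup <- fam
  dup$matrix[2, ] <- dup$matrix[1, ]
  emb2 <- embed_family(dup, model)
  expect_equal(unname(emb2[1, ]), unname(emb2[2, ]))
})

test_that("checkpoints round trip through disk", {
  model <- vae_init(8, tcn_config(n_blocks = 1, hidden_channels = 3,
                                  out_channels = 4, dropout = 0),
                    train_config(dim_z = 2, hidden_layer = 4, seed = 6))
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  saveRDS(list(version = "other"), path)
  expect_error(load_checkpoint(path), "checkpoint")
})
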