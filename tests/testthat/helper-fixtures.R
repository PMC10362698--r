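# Shared fixtures. Heavy trained models are built once per test run and
# memoised, so the memorisation, generation-radius and clade-structure
# checks reuse the same training run.

.fixture_env <- new.env(parent = emptyenv())

make_fasta <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

random_family <- function(n, L, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(0:20, n * L, replace = TRUE), n, L)
  ids <- paste0("r", seq_len(n))
  rownames(m) <- ids
  structure(list(ids = ids, matrix = m, L = L, weights = rep(1, n)),
            class = "aligned_family")
}

tiny_tcn <- function(dropout = 0.2)
  tcn_config(n_blocks = 2L, hidden_channels = 24L, out_channels = 48L,
             dropout = dropout)

# 30-sequence, L = 40 synthetic family and the model trained to memorise it
# (2000 epochs); shared by the memorisation and sampling-radius checks.
tiny_trained <- function() {
  if (!is.null(.fixture_env$tiny)) return(.fixture_env$tiny)
  sim <- simulate_family(n_leaves = 30L, L = 40L, rate = 0.3,
                         threshold = 1.2, seed = 42L)
  cfg <- train_config(epochs = 2000L, dim_z = 3L, hidden_layer = 64L,
                      learning_rate = 2e-3, batch_size = 128L, seed = 42L)
  model <- vae_train(sim$family, cfg, tiny_tcn())
  .fixture_env$tiny <- list(sim = sim, model = model)
  .fixture_env$tiny
}

# 300-leaf, L = 60, multi-clade family with a 2-D model; shared by the
# latent-clade-structure check.
clade_trained <- function() {
  if (!is.null(.fixture_env$clade)) return(.fixture_env$clade)
  sim <- simulate_family(n_leaves = 300L, L = 60L, rate = 0.3,
                         n_clades = 4L, seed = 42L)
  cfg <- train_config(epochs = 400L, dim_z = 2L, hidden_layer = 64L,
                      learning_rate = 2e-3, batch_size = 128L, seed = 42L)
  model <- vae_train(sim$family, cfg, tiny_tcn())
  .fixture_env$clade <- list(sim = sim, model = model)
  .fixture_env$clade
}

# small random positive-weight model for causality / receptive-field probes
probe_model <- function(n_blocks, L = 64L, seed = 5L) {
  tcn <- tcn_config(n_blocks = n_blocks, hidden_channels = 4L,
                    out_channels = 4L, dropout = 0)
  cfg <- train_config(epochs = 1L, dim_z = 2L, hidden_layer = 4L, seed = seed)
  model <- vae_init(L, tcn, cfg)
  # make every weight strictly positive so ReLUs never mask sensitivity
  model$params$blocks <- lapply(model$params$blocks, function(b) {
    lapply(b, function(cv) {
      cv$V <- abs(cv$V) + 0.05
      cv$g <- sqrt(rowSums(cv$V^2))
      cv$b <- rep(0.01, length(cv$b))
      cv
    })
  })
  model
}

# run an input through the block stack only (no pooling), eval mode
run_blocks <- function(x, model) {
  cur <- array(x, c(nrow(x), ncol(x), 1L))
  for (b in seq_along(model$params$blocks)) {
    d <- model$tcn$dilation_base^(b - 1L)
    cur <- tvae:::.block_fwd(cur, model$params$blocks[[b]],
                             model$tcn$kernel_size, d, 0, FALSE)$out
  }
  matrix(cur, dim(cur)[1], dim(cur)[2])
}
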