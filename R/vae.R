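# Variational autoencoder over aligned families.
#
# Encoder: TCN stack -> global average pool -> fully connected tanh layer ->
# linear heads for the latent mean and log-variance. Decoder: z -> fully
# connected tanh layer -> linear logits (21 x L) -> per-column softmax.
# Objective: weighted ELBO (categorical reconstruction log-likelihood minus
# the closed-form KL to the standard normal prior), maximised with Adam and
# L2 weight decay.

#' Training configuration
#'
#' Full-scale defaults: weight decay 1e-4, latent dimension 3, fully
#' connected hidden width 100, seed 42. Pretraining runs
#' 20000 epochs and fine-tuning 8000 at full scale; the default here is the
#' fine-tuning budget, and desk-scale examples use far fewer.
#'
#' @param epochs Full passes over the family.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient added to gradients.
#' @param dim_z Latent dimension (3 at full scale; 2 for visualisation).
#' @param hidden_layer Width of the fully connected layers.
#' @param batch_size Minibatch size (full batch when N is smaller).
#' @param seed Seed controlling initialisation, shuffling, dropout and
#'   latent sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 8000L, learning_rate = 1e-3,
                         weight_decay = 1e-4, dim_z = 3L,
                         hidden_layer = 100L, batch_size = 128L,
                         seed = 42L) {
  stopifnot(epochs >= 0, learning_rate > 0, weight_decay >= 0, dim_z >= 1,
            hidden_layer >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, dim_z = as.integer(dim_z),
                 hidden_layer = as.integer(hidden_layer),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Initialise VAE parameters
#'
#' @param L Alignment length the model is built for.
#' @param tcn A [tcn_config()].
#' @param cfg A [train_config()] (latent and hidden sizes; seed fixes the
#'   random initialisation).
#' @return A parameter list (`vae_params`): TCN blocks, encoder head, decoder.
#' @export
vae_init <- function(L, tcn = tcn_config(), cfg = train_config()) {
  set.seed(cfg$seed)
  k <- tcn$kernel_size
  chans <- c(21L, rep(tcn$hidden_channels, max(tcn$n_blocks - 1L, 0L)))
  chans <- c(chans[seq_len(tcn$n_blocks)], tcn$out_channels)
  blocks <- lapply(seq_len(tcn$n_blocks), function(b)
    .block_init(chans[b], chans[b + 1L], k))
  lin <- function(nr, nc) list(W = matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nc)), nr, nc),
                               b = numeric(nr))
  p <- list(
    blocks = blocks,
    fc   = lin(cfg$hidden_layer, tcn$out_channels),
    mu   = lin(cfg$dim_z, cfg$hidden_layer),
    lv   = lin(cfg$dim_z, cfg$hidden_layer),
    dec  = lin(cfg$hidden_layer, cfg$dim_z),
    out  = lin(21L * L, cfg$hidden_layer)
  )
  structure(list(params = p, L = as.integer(L), tcn = tcn, cfg = cfg),
            class = "vae_params")
}

# ---- closed-form pieces ----------------------------------------------------

#' KL divergence of a diagonal Gaussian to the standard normal
#'
#' Closed form `0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1)`; zero exactly
#' when mu = 0 and sigma = 1.
#'
#' @param mu Mean vector.
#' @param log_var Log-variance vector (same length).
#' @return Nonnegative scalar (nats).
#' @export
kl_to_standard_normal <- function(mu, log_var) {
  stopifnot(length(mu) == length(log_var))
  0.5 * sum(mu^2 + exp(log_var) - log_var - 1)
}

#' Reparameterised latent sample
#'
#' `z = mu + sigma * eps`, with eps standard normal from the current (or
#' seeded) RNG stream; in the sigma -> 0 limit the draw is mu exactly.
#'
#' @param mu Mean vector.
#' @param log_var Log-variance vector.
#' @param seed Optional integer; when given, the draw is taken from a
#'   freshly seeded stream and is repeatable.
#' @return Numeric vector z of the same length.
#' @export
reparameterize <- function(mu, log_var, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(length(mu))
  sd <- exp(0.5 * log_var)
  z <- mu + ifelse(sd == 0, 0, sd * eps)
  z
}

# ---- encoder / decoder forward (batched) -----------------------------------

# x3: 21 x L x N. Returns mu, lv (d x N) and caches when training.
.encode_fwd <- function(x3, model, train = FALSE) {
  p <- model$params
  tc <- .tcn_fwd(x3, p$blocks, model$tcn, train)
  hpre <- p$fc$W %*% tc$pooled + p$fc$b
  h <- tanh(hpre)
  mu <- p$mu$W %*% h + p$mu$b
  lv <- p$lv$W %*% h + p$lv$b
  list(mu = mu, lv = lv, h = h, pooled = tc$pooled, caches = tc$caches)
}

# z: d x N -> probs 21 x L x N plus cache
.decode_fwd <- function(z, model) {
  p <- model$params
  hd <- tanh(p$dec$W %*% z + p$dec$b)
  logits <- p$out$W %*% hd + p$out$b        # (21 L) x N
  n <- ncol(logits)
  lg <- array(logits, c(21L, model$L, n))
  mx <- apply(lg, c(2, 3), max)
  e <- exp(sweep(lg, c(2, 3), mx, "-"))
  cs <- apply(e, c(2, 3), sum)
  probs <- sweep(e, c(2, 3), cs, "/")
  list(probs = probs, hd = hd)
}

#' Encode sequences to their latent Gaussians
#'
#' Evaluation-mode (deterministic, dropout off) encoding of one or more
#' aligned sequences.
#'
#' @param x A 21 x L one-hot matrix, a 21 x L x N array, or an
#'   `aligned_family`.
#' @param model A `vae_params` object.
#' @return List with `mu` and `log_var`, each `dim_z` x N matrices.
#' @export
vae_encode <- function(x, model) {
  x3 <- .as_onehot_tensor(x, model$L)
  enc <- .encode_fwd(x3, model, train = FALSE)
  list(mu = enc$mu, log_var = enc$lv)
}

#' Decode latent vectors to per-position residue distributions
#'
#' @param z A `dim_z`-vector or `dim_z` x N matrix of latent codes.
#' @param model A `vae_params` object.
#' @return A 21 x L x N array of per-column categorical probabilities (each
#'   column sums to 1); for a single z, drop the third dimension with
#'   `[, , 1]`.
#' @export
vae_decode <- function(z, model) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  .decode_fwd(z, model)$probs
}

.as_onehot_tensor <- function(x, L) {
  if (inherits(x, "aligned_family")) return(.family_onehot(x))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(dim(x)[1] == 21L, dim(x)[2] == L)
  x
}

#' ELBO components for one sequence
#'
#' Single-sample evidence lower bound: reconstruction term = log-probability
#' of the observed residues under the decoded per-column categoricals; KL
#' term = closed-form divergence of the encoder Gaussian from the standard
#' normal prior. The training loss is `weight * (kl - reconstruction)`.
#'
#' @param x 21 x L one-hot matrix of the observed sequence.
#' @param mu,log_var Latent Gaussian of the sequence.
#' @param recon 21 x L decoded probability matrix.
#' @param weight Positive sequence weight.
#' @return List with `reconstruction`, `kl`, `elbo`, `loss`.
#' @export
elbo_loss <- function(x, mu, log_var, recon, weight = 1) {
  stopifnot(all(dim(x) == dim(recon)))
  obs <- colSums(x * log(pmax(recon, 1e-300)))
  reconstruction <- sum(obs)
  kl <- kl_to_standard_normal(mu, log_var)
  list(reconstruction = reconstruction, kl = kl,
       elbo = reconstruction - kl,
       loss = weight * (kl - reconstruction))
}

# ---- full forward/backward over a batch ------------------------------------

# returns loss pieces and parameter gradients; w: per-sequence weights
.vae_step <- function(x3, w, model, train = TRUE) {
  p <- model$params
  n <- dim(x3)[3]
  enc <- .encode_fwd(x3, model, train)
  mu <- enc$mu; lv <- enc$lv
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu))
  sd <- exp(0.5 * lv)
  z <- mu + sd * eps
  dec <- .decode_fwd(z, model)
  probs <- dec$probs

  obs_lp <- log(pmax(probs, 1e-300)) * x3
  recon <- apply(obs_lp, 3, sum)                       # per-sequence
  kl <- 0.5 * colSums(mu^2 + exp(lv) - lv - 1)
  loss <- sum(w * (kl - recon)) / n

  # ---- backward ----
  ws <- w / n
  dlogits <- sweep(probs - x3, 3, ws, "*")
  dlog_m <- matrix(dlogits, ncol = n)                  # (21 L) x N
  g_out <- list(W = dlog_m %*% t(dec$hd), b = rowSums(dlog_m))
  dhd <- (t(p$out$W) %*% dlog_m) * (1 - dec$hd^2)
  g_dec <- list(W = dhd %*% t(z), b = rowSums(dhd))
  dz <- t(p$dec$W) %*% dhd
  dmu <- dz + sweep(mu, 2, ws, "*")
  dlv <- dz * eps * 0.5 * sd + sweep(0.5 * (exp(lv) - 1), 2, ws, "*")
  g_mu <- list(W = dmu %*% t(enc$h), b = rowSums(dmu))
  g_lv <- list(W = dlv %*% t(enc$h), b = rowSums(dlv))
  dh <- (t(p$mu$W) %*% dmu + t(p$lv$W) %*% dlv) * (1 - enc$h^2)
  g_fc <- list(W = dh %*% t(enc$pooled), b = rowSums(dh))
  dpool <- t(p$fc$W) %*% dh
  tb <- .tcn_bwd(dpool, p$blocks, enc$caches, model$tcn)

  grads <- list(blocks = tb$grads, fc = g_fc, mu = g_mu, lv = g_lv,
                dec = g_dec, out = g_out)
  list(loss = loss, recon = sum(w * recon) / sum(w),
       kl = sum(w * kl) / sum(w), grads = grads)
}

# ---- Adam over the nested parameter list -----------------------------------

.zeros_like <- function(x) {
  if (is.list(x)) return(lapply(x, .zeros_like))
  x * 0
}

.adam_update <- function(p, g, st, lr, wd, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      if (i > length(g) || is.null(g[[i]])) next
      r <- .adam_update(p[[i]], g[[i]], list(m = st$m[[i]], v = st$v[[i]]),
                        lr, wd, t, b1, b2, eps)
      p[[i]] <- r$p; st$m[[i]] <- r$st$m; st$v[[i]] <- r$st$v
    }
    return(list(p = p, st = st))
  }
  g <- g + wd * p
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train the variational autoencoder on an aligned family
#'
#' Maximises the position-weighted ELBO with Adam (L2 weight decay). All
#' randomness — initialisation, minibatch shuffling, dropout, latent
#' sampling — flows from `cfg$seed`, so two runs with the same data and
#' configuration produce identical checkpoints on a single thread.
#'
#' @param fam An `aligned_family`.
#' @param cfg A [train_config()].
#' @param tcn A [tcn_config()].
#' @param init Optional `vae_params` to continue from (used by
#'   [vae_fine_tune()]); when given, its architecture is kept.
#' @param trace_every Record the loss trace every this many epochs (plus the
#'   first and last).
#' @param verbose Print progress lines.
#' @return A `vae_params` object with a `trace` data frame attached
#'   (`epoch`, `loss`, `reconstruction`, `kl`, `elbo`).
#' @export
vae_train <- function(fam, cfg = train_config(), tcn = tcn_config(),
                      init = NULL, trace_every = 10L, verbose = FALSE) {
  stopifnot(inherits(fam, "aligned_family"))
  n <- nrow(fam$matrix)
  if (n < 2) stop("training needs at least 2 sequences")
  x3 <- .family_onehot(fam)
  w <- fam$weights

  model <- if (is.null(init)) vae_init(fam$L, tcn, cfg) else init
  if (!is.null(init) && init$L != fam$L)
    stop("alignment length mismatch: model built for L=", init$L,
         ", family has L=", fam$L)
  model$cfg <- cfg
  set.seed(cfg$seed + 1L)   # training stream (init consumed cfg$seed)

  st <- list(m = .zeros_like(model$params), v = .zeros_like(model$params))
  bs <- min(cfg$batch_size, n)
  trace <- list()
  t_adam <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- ep_rec <- ep_kl <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      step <- .vae_step(x3[, , idx, drop = FALSE], w[idx], model, train = TRUE)
      if (!is.finite(step$loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; lower the learning rate")
      t_adam <- t_adam + 1L
      upd <- .adam_update(model$params, step$grads, st,
                          cfg$learning_rate, cfg$weight_decay, t_adam)
      model$params <- upd$p; st <- upd$st
      ep_loss <- ep_loss + step$loss; ep_rec <- ep_rec + step$recon
      ep_kl <- ep_kl + step$kl; nb <- nb + 1
    }
    if (ep == 1L || ep == cfg$epochs || ep %% trace_every == 0L) {
      trace[[length(trace) + 1L]] <-
        data.frame(epoch = ep, loss = ep_loss / nb,
                   reconstruction = ep_rec / nb, kl = ep_kl / nb,
                   elbo = ep_rec / nb - ep_kl / nb)
      if (verbose)
        message(sprintf("epoch %d  loss %.3f  recon %.3f  kl %.3f",
                        ep, ep_loss / nb, ep_rec / nb, ep_kl / nb))
    }
  }
  model$trace <- do.call(rbind, trace)
  model
}

#' Fine-tune a trained model on a (labelled) family
#'
#' Continues training from existing parameters, typically on the small
#' labelled subset that will anchor the fitness regression. The family must
#' share the alignment length of the pretraining family. With `epochs = 0`
#' the parameters are returned unchanged.
#'
#' @param model A trained `vae_params`.
#' @param fam An `aligned_family` with the same L.
#' @param cfg A [train_config()] for the fine-tuning phase.
#' @return The fine-tuned `vae_params`.
#' @export
vae_fine_tune <- function(model, fam, cfg = train_config(epochs = 8000L)) {
  stopifnot(inherits(model, "vae_params"))
  if (fam$L != model$L)
    stop("alignment length mismatch: model built for L=", model$L,
         ", family has L=", fam$L)
  if (cfg$epochs == 0L) return(model)
  vae_train(fam, cfg, model$tcn, init = model)
}

#' Embed a family in latent space
#'
#' Evaluation-mode encoder means, one row per sequence — the coordinates
#' used for visualisation and as Gaussian-process features.
#'
#' @param fam An `aligned_family`.
#' @param model A trained `vae_params`.
#' @return N x `dim_z` numeric matrix with the family ids as row names.
#' @export
embed_family <- function(fam, model) {
  enc <- vae_encode(fam, model)
  emb <- t(enc$mu)
  rownames(emb) <- fam$ids
  colnames(emb) <- paste0("z", seq_len(ncol(emb)))
  emb
}

#' Argmax reconstruction of a family through the trained model
#'
#' Encodes each sequence to its latent mean, decodes, and takes the
#' column-wise argmax; useful for memorisation checks.
#'
#' @param fam An `aligned_family`.
#' @param model A trained `vae_params`.
#' @return N x L integer matrix of residue codes.
#' @export
reconstruct_family <- function(fam, model) {
  enc <- vae_encode(fam, model)
  probs <- vae_decode(enc$mu, model)
  out <- matrix(0L, dim(probs)[3], model$L)
  for (i in seq_len(dim(probs)[3]))
    out[i, ] <- decode_onehot(probs[, , i])
  rownames(out) <- fam$ids
  out
}

# fraction of positions at which two code matrices agree, per row
.rowwise_identity <- function(a, b) rowMeans(a == b)

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a version header, the architecture and
#' training configuration, the parameters and the loss trace.
#'
#' @param model A `vae_params`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `vae_params` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "vae_params"))
  saveRDS(list(version = "tvae-checkpoint-1", model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "tvae-checkpoint-1"))
    stop("not a recognised checkpoint file: ", path)
  obj$model
}
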