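# Dilated causal convolution stack (temporal convolutional network).
#
# Tensors are C x L x N arrays: channels x alignment columns x sequences.
# The temporal axis is the alignment column axis; the 21 one-hot rows are
# the input channels. All convolutions are causal: left zero padding of
# (k-1)*d columns, so output column t depends only on input columns <= t
# and output length equals input length.

#' Default TCN encoder configuration
#'
#' Defaults: kernel size 2, stride 1, dilation
#' base 2 (per-block dilations 1, 2, 4, ...), dropout 0.2, 100 output
#' channels, 3 residual blocks; causal left padding of `(k-1)*d` replaces the
#' fixed symmetric padding, which preserves length only at d = 1.
#'
#' @param kernel_size Convolution kernel size (taps per filter).
#' @param dilation_base Dilation of block b is `dilation_base^(b-1)`.
#' @param n_blocks Number of residual blocks.
#' @param hidden_channels Channels of the intermediate blocks.
#' @param out_channels Channels of the final block (the TCN output width).
#' @param dropout Dropout probability inside residual blocks (training only).
#' @return A `tcn_config` list.
#' @export
tcn_config <- function(kernel_size = 2L, dilation_base = 2L, n_blocks = 3L,
                       hidden_channels = 100L, out_channels = 100L,
                       dropout = 0.2) {
  stopifnot(kernel_size >= 1, dilation_base >= 1, n_blocks >= 1,
            hidden_channels >= 1, out_channels >= 1,
            dropout >= 0, dropout < 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 dilation_base = as.integer(dilation_base),
                 n_blocks = as.integer(n_blocks),
                 hidden_channels = as.integer(hidden_channels),
                 out_channels = as.integer(out_channels),
                 dropout = dropout, stride = 1L),
            class = "tcn_config")
}

# shift a C x L x N array right along the column axis by `off`, zero-filling
.shift_right <- function(x, off) {
  if (off == 0) return(x)
  d <- dim(x)
  y <- array(0, d)
  if (off < d[2]) y[, (off + 1):d[2], ] <- x[, 1:(d[2] - off), , drop = FALSE]
  y
}

# stack the k causally shifted copies of x: tap i multiplies S_{t - d*(k-i)}
.tap_stack <- function(x, k, d) {
  if (k == 1) return(x)
  dm <- dim(x)
  out <- array(0, c(dm[1] * k, dm[2], dm[3]))
  for (i in seq_len(k)) {
    rows <- ((i - 1) * dm[1] + 1):(i * dm[1])
    out[rows, , ] <- .shift_right(x, d * (k - i))
  }
  out
}

#' Dilated causal convolution
#'
#' Applies one dilated causal convolution to a channels x length grid. Tap i
#' of the kernel multiplies the input at offset `d*(k-i)` into the past, so
#' the output at column t is a function only of input columns `<= t`
#' (causality); left zero padding keeps the output length equal to the input
#' length.
#'
#' @param x Numeric matrix, `C_in` x L.
#' @param weights Numeric array `C_out` x `C_in` x k (k = kernel size); tap
#'   `i` (third index) multiplies the input delayed by `d*(k-i)` columns.
#' @param d Dilation factor (positive integer).
#' @param bias Optional length-`C_out` bias (default zeros).
#' @return Numeric matrix `C_out` x L.
#' @export
causal_dilated_conv <- function(x, weights, d = 1L, bias = NULL) {
  if (d < 1) stop("dilation must be a positive integer")
  if (length(dim(weights)) == 2) weights <- array(weights, c(dim(weights), 1L))
  k <- dim(weights)[3]
  if (k < 1) stop("kernel size must be a positive integer")
  stopifnot(dim(weights)[2] == nrow(x))
  x3 <- array(x, c(nrow(x), ncol(x), 1L))
  # weight matrix columns ordered tap-major to match .tap_stack layout
  wm <- matrix(0, dim(weights)[1], dim(weights)[2] * k)
  for (i in seq_len(k))
    wm[, ((i - 1) * dim(weights)[2] + 1):(i * dim(weights)[2])] <- weights[, , i]
  xc <- .tap_stack(x3, k, d)
  out <- wm %*% matrix(xc, nrow = dim(xc)[1])
  if (!is.null(bias)) out <- out + bias
  matrix(out, dim(weights)[1], ncol(x))
}

#' Receptive field by the stride recursion
#'
#' The plain (dilation-blind) recursion `RF_i = RF_{i-1} + (k_i - 1) * S_i`
#' with `S_i` the product of the strides of all earlier layers.
#'
#' @param layers Data frame or list of lists with elements `k` (kernel) and
#'   `s` (stride) per layer.
#' @return Receptive field (positive integer) after the last layer.
#' @seealso [receptive_field_dilated()] for the dilation-aware recursion the
#'   network actually obeys.
#' @export
receptive_field <- function(layers) {
  layers <- .as_layer_list(layers)
  rf <- 1; sp <- 1
  for (ly in layers) {
    rf <- rf + (ly$k - 1) * sp
    sp <- sp * ly$s
  }
  rf
}

#' Dilation-aware receptive field
#'
#' `RF_i = RF_{i-1} + (k_i - 1) * d_i * S_i`: each dilated tap reaches
#' `d_i` columns further back, which is what makes the field grow
#' geometrically with depth when dilations double. This is the recursion the
#' stacked network satisfies (validated against a brute-force sensitivity
#' probe in the test suite).
#'
#' @param layers Data frame or list of lists with elements `k`, `s`, and `d`
#'   (dilation) per layer.
#' @return Receptive field (positive integer) after the last layer.
#' @export
receptive_field_dilated <- function(layers) {
  layers <- .as_layer_list(layers)
  rf <- 1; sp <- 1
  for (ly in layers) {
    d <- if (is.null(ly$d)) 1 else ly$d
    rf <- rf + (ly$k - 1) * d * sp
    sp <- sp * ly$s
  }
  rf
}

.as_layer_list <- function(layers) {
  if (is.data.frame(layers)) layers <- split(layers, seq_len(nrow(layers)))
  if (length(layers) == 0) stop("layer list must be nonempty")
  lapply(layers, function(ly) {
    ly <- as.list(ly)
    if (is.null(ly$s)) ly$s <- 1L
    stopifnot(ly$k >= 1, ly$s >= 1)
    ly
  })
}

#' Per-layer convolution ledger of a TCN configuration
#'
#' Expands a block configuration into the flat list of its convolution
#' layers (two per residual block, sharing the block dilation), suitable for
#' [receptive_field_dilated()].
#'
#' @param cfg A [tcn_config()].
#' @param n_blocks Optional override of the number of blocks.
#' @return Data frame with columns `block`, `k`, `s`, `d`.
#' @export
tcn_layers <- function(cfg, n_blocks = cfg$n_blocks) {
  do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    d <- cfg$dilation_base^(b - 1L)
    data.frame(block = b, k = cfg$kernel_size, s = 1L, d = d)
  }))
}

# ---- weight-normalised convolution with cache (internal) -------------------
# Weight norm: W = diag(g / ||v_row||) V, per output channel.

.wn_weight <- function(V, g) {
  rn <- pmax(sqrt(rowSums(V^2)), 1e-12)
  (g / rn) * V
}

.wn_backward <- function(V, g, dW) {
  rn <- pmax(sqrt(rowSums(V^2)), 1e-12)
  dir <- V / rn
  dg <- rowSums(dW * dir)
  dV <- (g / rn) * dW - ((g * dg) / rn^2) * V
  list(dV = dV, dg = dg)
}

# forward conv on a 3D batch with weight norm; returns output + cache
.conv_fwd <- function(x3, V, g, b, k, d) {
  xc <- .tap_stack(x3, k, d)
  W <- .wn_weight(V, g)
  dm <- dim(xc)
  out <- W %*% matrix(xc, nrow = dm[1]) + b
  list(out = array(out, c(length(b), dm[2], dm[3])), xc = xc)
}

# backward: given dOut (C_out x L x N), cached taps and params
.conv_bwd <- function(dout, cache, V, g, k, d, c_in) {
  dm <- dim(dout)
  dmat <- matrix(dout, nrow = dm[1])
  xmat <- matrix(cache$xc, nrow = dim(cache$xc)[1])
  dW <- dmat %*% t(xmat)
  db <- rowSums(dmat)
  W <- .wn_weight(V, g)
  dxc <- array(t(W) %*% dmat, dim(cache$xc))
  # fold tap gradients back onto the input
  dx <- array(0, c(c_in, dm[2], dm[3]))
  for (i in seq_len(k)) {
    rows <- ((i - 1) * c_in + 1):(i * c_in)
    off <- d * (k - i)
    if (off == 0) {
      dx <- dx + dxc[rows, , , drop = FALSE]
    } else if (off < dm[2]) {
      dx[, 1:(dm[2] - off), ] <- dx[, 1:(dm[2] - off), , drop = FALSE] +
        dxc[rows, (off + 1):dm[2], , drop = FALSE]
    }
  }
  wn <- .wn_backward(V, g, dW)
  list(dx = dx, dV = wn$dV, dg = wn$dg, db = db)
}

# ---- residual block --------------------------------------------------------
# F(x) = [conv -> weight norm -> ReLU -> dropout] x 2; out = ReLU(skip + F(x));
# skip is identity, or a 1x1 convolution when channel counts differ.

.block_init <- function(c_in, c_out, k, rng_sd = 0.1) {
  mk <- function(nr, nc) {
    V <- matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nc)), nr, nc)
    list(V = V, g = sqrt(rowSums(V^2)), b = numeric(nr))
  }
  p <- list(c1 = mk(c_out, c_in * k), c2 = mk(c_out, c_out * k))
  if (c_in != c_out) p$skip <- mk(c_out, c_in)
  p
}

.dropout_mask <- function(dm, p) {
  if (p <= 0) return(NULL)
  array(stats::rbinom(prod(dm), 1, 1 - p) / (1 - p), dm)
}

.block_fwd <- function(x3, p, k, d, dropout, train) {
  c_in <- dim(x3)[1]
  f1 <- .conv_fwd(x3, p$c1$V, p$c1$g, p$c1$b, k, d)
  a1 <- pmax(f1$out, 0)
  m1 <- if (train) .dropout_mask(dim(a1), dropout) else NULL
  d1 <- if (is.null(m1)) a1 else a1 * m1
  f2 <- .conv_fwd(d1, p$c2$V, p$c2$g, p$c2$b, k, d)
  a2 <- pmax(f2$out, 0)
  m2 <- if (train) .dropout_mask(dim(a2), dropout) else NULL
  d2 <- if (is.null(m2)) a2 else a2 * m2
  if (is.null(p$skip)) {
    s <- x3
    sk <- NULL
  } else {
    sk <- .conv_fwd(x3, p$skip$V, p$skip$g, p$skip$b, 1L, 1L)
    s <- sk$out
  }
  pre <- s + d2
  out <- pmax(pre, 0)
  list(out = out,
       cache = list(x3 = x3, f1 = f1, h1 = f1$out, m1 = m1, d1 = d1,
                    f2 = f2, h2 = f2$out, m2 = m2, sk = sk, pre = pre,
                    c_in = c_in))
}

.block_bwd <- function(dout, p, cache, k, d) {
  dpre <- dout * (cache$pre > 0)
  # skip path
  if (is.null(p$skip)) {
    dx_skip <- dpre
    gskip <- NULL
  } else {
    bs <- .conv_bwd(dpre, cache$sk, p$skip$V, p$skip$g, 1L, 1L, cache$c_in)
    dx_skip <- bs$dx
    gskip <- list(V = bs$dV, g = bs$dg, b = bs$db)
  }
  # residual path, second conv
  da2 <- if (is.null(cache$m2)) dpre else dpre * cache$m2
  dh2 <- da2 * (cache$h2 > 0)
  b2 <- .conv_bwd(dh2, cache$f2, p$c2$V, p$c2$g, k, d, dim(cache$d1)[1])
  da1 <- if (is.null(cache$m1)) b2$dx else b2$dx * cache$m1
  dh1 <- da1 * (cache$h1 > 0)
  b1 <- .conv_bwd(dh1, cache$f1, p$c1$V, p$c1$g, k, d, cache$c_in)
  grads <- list(c1 = list(V = b1$dV, g = b1$dg, b = b1$db),
                c2 = list(V = b2$dV, g = b2$dg, b = b2$db))
  if (!is.null(gskip)) grads$skip <- gskip
  list(dx = b1$dx + dx_skip, grads = grads)
}

#' Apply one residual block (evaluation mode)
#'
#' Runs a single TCN residual block on a channels x length grid with dropout
#' disabled, mainly for inspection and testing of the causality and shape
#' contracts.
#'
#' @param x Numeric matrix `C_in` x L.
#' @param params Block parameter list as created inside [vae_init()] (fields
#'   `c1`, `c2`, optional `skip`, each with `V`, `g`, `b`).
#' @param k Kernel size.
#' @param d Dilation.
#' @return Numeric matrix `C_out` x L.
#' @export
residual_block <- function(x, params, k = 2L, d = 1L) {
  x3 <- array(x, c(nrow(x), ncol(x), 1L))
  out <- .block_fwd(x3, params, k, d, dropout = 0, train = FALSE)$out
  matrix(out, dim(out)[1], dim(out)[2])
}

# full TCN stack forward over a batch; returns pooled C_out x N features
.tcn_fwd <- function(x3, blocks, cfg, train) {
  caches <- vector("list", length(blocks))
  cur <- x3
  for (b in seq_along(blocks)) {
    d <- cfg$dilation_base^(b - 1L)
    r <- .block_fwd(cur, blocks[[b]], cfg$kernel_size, d, cfg$dropout, train)
    caches[[b]] <- r$cache
    cur <- r$out
  }
  L <- dim(cur)[2]
  pooled <- apply(cur, 3, rowMeans)          # C_out x N (global average pool)
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = dim(cur)[1])
  list(pooled = pooled, caches = caches, L = L)
}

.tcn_bwd <- function(dpooled, blocks, caches, cfg) {
  L <- dim(caches[[length(caches)]]$pre)[2]
  n <- ncol(dpooled)
  c_out <- nrow(dpooled)
  dcur <- aperm(array(dpooled / L, c(c_out, n, L)), c(1, 3, 2))
  grads <- vector("list", length(blocks))
  for (b in rev(seq_along(blocks))) {
    d <- cfg$dilation_base^(b - 1L)
    r <- .block_bwd(dcur, blocks[[b]], caches[[b]], cfg$kernel_size, d)
    grads[[b]] <- r$grads
    dcur <- r$dx
  }
  list(dx = dcur, grads = grads)
}
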