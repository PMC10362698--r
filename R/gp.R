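# Gaussian-process regression from latent codes to fitness (e.g. T50).
# RBF kernel k(z1,z2) = sig_g^2 exp(-||z1-z2||^2 / (2 lambda^2)), constant
# mean (training mean of y), observation noise sig_n^2 with a 1e-8 floor,
# hyperparameters by multi-start maximisation of the log marginal likelihood.

#' Radial basis function kernel
#'
#' `sig_g^2 * exp(-||z1 - z2||^2 / (2 * lambda^2))`: symmetric, maximal
#' (`= sig_g^2`) at zero distance.
#'
#' @param z1,z2 Numeric vectors of equal length.
#' @param signal_var Signal variance `sig_g^2` (> 0).
#' @param length_scale Length scale `lambda` (> 0).
#' @return Scalar covariance in `(0, sig_g^2]`.
#' @export
rbf_kernel <- function(z1, z2, signal_var = 1, length_scale = 1) {
  if (length_scale <= 0) stop("length_scale must be positive")
  if (signal_var <= 0) stop("signal_var must be positive")
  stopifnot(length(z1) == length(z2))
  signal_var * exp(-sum((z1 - z2)^2) / (2 * length_scale^2))
}

# squared Euclidean distance matrix between rows of A and rows of B
.sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}

.kernel_matrix <- function(A, B, sg2, lam) sg2 * exp(-.sqdist(A, B) / (2 * lam^2))

.NOISE_FLOOR <- 1e-8

# negative log marginal likelihood at log-parameters th = log(sg2, lam, sn2)
.gp_nll <- function(th, D2, yc) {
  sg2 <- exp(th[1]); lam <- exp(th[2]); sn2 <- max(exp(th[3]), .NOISE_FLOOR)
  n <- length(yc)
  K <- sg2 * exp(-D2 / (2 * lam^2)) + diag(sn2, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  as.numeric(0.5 * sum(yc * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi))
}

#' Fit a Gaussian process fitness model
#'
#' Maximises the log marginal likelihood over (signal variance, length
#' scale, noise variance) in log space with L-BFGS-B from one
#' moment-matched start (variance of y, median pairwise distance) plus
#' `n_restarts` seeded random perturbations, keeping the best optimum. The
#' target is centred by its mean internally; the noise variance has a 1e-8
#' floor so the kernel matrix stays positive definite.
#'
#' @param z n x d matrix of latent features.
#' @param y Length-n fitness values (no missing values).
#' @param hyper Optional list(signal_var, length_scale, noise_var): fixes
#'   the hyperparameters and skips optimisation.
#' @param n_restarts Random restarts for the marginal-likelihood search.
#' @param seed Seed of the restart stream.
#' @return A `gp_model`: hyperparameters, cached Cholesky factorisation and
#'   the training data.
#' @export
fit_gp <- function(z, y, hyper = NULL, n_restarts = 5L, seed = 1L) {
  z <- as.matrix(z)
  y <- as.numeric(y)
  n <- nrow(z)
  if (n < 2) stop("GP fitting needs at least 2 observations")
  if (length(y) != n) stop("z and y sizes disagree")
  if (anyNA(y) || anyNA(z)) stop("missing values in GP inputs")
  ybar <- mean(y)
  yc <- y - ybar
  D2 <- .sqdist(z, z)

  if (is.null(hyper)) {
    vy <- stats::var(y)
    if (vy == 0) vy <- 1e-6
    med <- stats::median(sqrt(D2[upper.tri(D2)]))
    if (!is.finite(med) || med == 0) med <- 1
    th0 <- log(c(vy, med, 0.1 * vy))
    lower <- c(log(1e-6), log(1e-4), log(.NOISE_FLOOR))
    upper <- c(log(1e6), log(1e4), log(1e6))
    set.seed(seed)
    starts <- c(list(th0), lapply(seq_len(n_restarts), function(i)
      th0 + stats::rnorm(3, sd = 1)))
    best <- NULL
    for (s in starts) {
      op <- tryCatch(
        stats::optim(s, .gp_nll, D2 = D2, yc = yc, method = "L-BFGS-B",
                     lower = lower, upper = upper),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    if (is.null(best)) stop("marginal-likelihood optimisation failed")
    if (best$value > .gp_nll(th0, D2, yc) + 1e-6)
      best <- list(par = th0, value = .gp_nll(th0, D2, yc))
    hyper <- list(signal_var = exp(best$par[1]),
                  length_scale = exp(best$par[2]),
                  noise_var = max(exp(best$par[3]), .NOISE_FLOOR))
  } else {
    hyper$noise_var <- max(hyper$noise_var, 0)
  }

  K <- .kernel_matrix(z, z, hyper$signal_var, hyper$length_scale) +
    diag(hyper$noise_var + .NOISE_FLOOR, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  structure(list(hyper = hyper, z = z, ybar = ybar, chol = ch, alpha = alpha,
                 n = n, d = ncol(z)),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf(
    "gp_model: n=%d d=%d  signal_var=%.4g length_scale=%.4g noise_var=%.4g\n",
    x$n, x$d, x$hyper$signal_var, x$hyper$length_scale, x$hyper$noise_var))
  invisible(x)
}

#' Gaussian-process posterior prediction
#'
#' Posterior predictive mean and variance at new latent points. The variance
#' includes the fitted observation noise, so far from all training points it
#' reverts to `signal_var + noise_var` and the mean reverts to the training
#' mean of y.
#'
#' @param model A fitted `gp_model`.
#' @param znew m x d matrix (or a single d-vector) of query points.
#' @return Data frame with columns `mean` and `var`.
#' @export
gp_predict <- function(model, znew) {
  if (is.null(dim(znew))) znew <- matrix(znew, nrow = 1)
  znew <- as.matrix(znew)
  stopifnot(ncol(znew) == model$d)
  Ks <- .kernel_matrix(znew, model$z, model$hyper$signal_var,
                       model$hyper$length_scale)       # m x n
  mean <- model$ybar + as.numeric(Ks %*% model$alpha)
  V <- forwardsolve(t(model$chol), t(Ks))              # n x m
  var <- model$hyper$signal_var + model$hyper$noise_var - colSums(V^2)
  data.frame(mean = mean, var = pmax(var, 0))
}

#' @export
predict.gp_model <- function(object, newdata, ...) gp_predict(object, newdata)

#' Regression evaluation metrics
#'
#' Pearson product-moment correlation and mean absolute deviation
#' `mean(|pred - truth|)`, the two indicators used throughout for fitness
#' prediction quality.
#'
#' @param pred,truth Numeric vectors of equal length (n >= 2).
#' @return List with `pearson` (NA with a warning if `truth` is constant)
#'   and `mad` (same units as `truth`).
#' @export
eval_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  r <- if (stats::sd(truth) == 0) {
    warning("truth is constant; Pearson correlation undefined", call. = FALSE)
    NA_real_
  } else stats::cor(pred, truth)
  list(pearson = r, mad = mean(abs(pred - truth)))
}

#' Seeded train/test split
#'
#' Splits n items into test (`round(n * test_frac)`) and train indices with
#' a seeded uniform draw, no stratification. With 278 items and
#' `test_frac = 0.2` this reproduces the 222/56 protocol.
#'
#' @param n Number of items.
#' @param test_frac Test fraction in (0, 1).
#' @param seed Seed of the draw.
#' @return List with integer vectors `train` and `test`.
#' @export
train_test_split <- function(n, test_frac = 0.2, seed = 42L) {
  stopifnot(n >= 2, test_frac > 0, test_frac < 1)
  set.seed(seed)
  n_test <- round(n * test_frac)
  test <- sort(sample.int(n, n_test))
  list(train = setdiff(seq_len(n), test), test = test)
}
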