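# Latent-neighbourhood variant generation, pairwise identity scoring and
# fitness-window screening.

#' Sample latent points around a reference posterior
#'
#' Draws `z_i = mu + scale * sigma * eps_i` with standard-normal `eps_i`
#' from a seeded stream. `scale = 1` reproduces the reference's encoder
#' posterior; `scale = 0` collapses every draw onto the mean; larger scales
#' explore a wider neighbourhood.
#'
#' @param mu,log_var Latent Gaussian of the reference sequence (d-vectors).
#' @param n Number of points.
#' @param scale Nonnegative sampling radius multiplier.
#' @param seed Seed of the draw.
#' @return d x n matrix of latent points.
#' @export
sample_around <- function(mu, log_var, n, scale = 1, seed = 42L) {
  stopifnot(n >= 1, scale >= 0, length(mu) == length(log_var))
  set.seed(seed)
  d <- length(mu)
  eps <- matrix(stats::rnorm(d * n), d, n)
  mu + scale * exp(0.5 * log_var) * eps
}

#' Decode latent points into residue sequences
#'
#' Column-wise argmax of the decoder distributions. The aligned form (with
#' gap symbols) is returned; `gapless = TRUE` additionally strips gaps for
#' FASTA-style output.
#'
#' @param latents d x n matrix (or a single d-vector) of latent points.
#' @param model A trained `vae_params`.
#' @param gapless Also return gap-stripped strings.
#' @return Data frame with `id` (`Generate_<k>`, k from 1), `aligned`
#'   (length-L residue string, may contain `-`), and, when requested,
#'   `sequence` (gap-free).
#' @export
realize_sequences <- function(latents, model, gapless = TRUE) {
  if (is.null(dim(latents))) latents <- matrix(latents, ncol = 1)
  probs <- vae_decode(latents, model)
  n <- dim(probs)[3]
  aligned <- character(n)
  for (i in seq_len(n))
    aligned[i] <- .codes_to_string(decode_onehot(probs[, , i]))
  out <- data.frame(id = paste0("Generate_", seq_len(n)), aligned = aligned)
  if (gapless) out$sequence <- gsub("-", "", out$aligned, fixed = TRUE)
  out
}

# ---- pairwise alignment identity -------------------------------------------
# Scoring fixed at match=1, mismatch=0, gap open/extend=0 (both global and
# local), ties broken match > diagonal > up > left, so identity values are
# bit-reproducible. With a zero gap penalty the row recursion
# H[i,j] = max(H[i-1,j-1]+s, H[i-1,j], H[i,j-1]) vectorises as a cummax.

.nw_matrix <- function(a, b, local = FALSE) {
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    s <- as.numeric(a[i] == b)
    tmp <- pmax(H[i, 1:m] + s, H[i, 2:(m + 1)])
    if (local) tmp <- pmax(tmp, 0)
    H[i + 1, 2:(m + 1)] <- cummax(tmp)
  }
  H
}

# traceback from (i, j); returns c(matches, alignment_length)
.traceback <- function(H, a, b, i, j, local = FALSE) {
  matches <- 0L; len <- 0L
  while (i > 0 && j > 0) {
    if (local && H[i + 1, j + 1] == 0) break
    diag_sc <- H[i, j] + (a[i] == b[j])
    if (diag_sc == H[i + 1, j + 1] && a[i] == b[j]) {
      matches <- matches + 1L; len <- len + 1L; i <- i - 1L; j <- j - 1L
    } else if (diag_sc == H[i + 1, j + 1]) {
      len <- len + 1L; i <- i - 1L; j <- j - 1L
    } else if (H[i, j + 1] == H[i + 1, j + 1]) {
      len <- len + 1L; i <- i - 1L
    } else {
      len <- len + 1L; j <- j - 1L
    }
  }
  if (!local) len <- len + i + j    # leading gaps of the global alignment
  c(matches = matches, length = len)
}

.seq_chars <- function(x) {
  if (length(x) == 1 && is.character(x)) strsplit(x, "")[[1]] else as.character(x)
}

#' Global alignment identity
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0, gap
#' open/extend = 0; identity is 100 * identical aligned pairs / alignment
#' length (gap columns included in the length).
#'
#' @param a,b Nonempty residue strings (or character vectors).
#' @return Identity percentage in `[0, 100]`, with the alignment's match
#'   count and length as attributes.
#' @export
global_identity <- function(a, b) {
  a <- .seq_chars(a); b <- .seq_chars(b)
  if (length(a) == 0 || length(b) == 0) stop("empty sequence")
  H <- .nw_matrix(a, b, local = FALSE)
  tb <- .traceback(H, a, b, length(a), length(b), local = FALSE)
  structure(100 * tb["matches"] / tb["length"], names = NULL,
            matches = unname(tb["matches"]), alignment_length = unname(tb["length"]))
}

#' Local alignment identity
#'
#' Smith-Waterman local alignment under the same scoring; identity is
#' computed over the best local alignment's length. When no residue matches
#' at all the alignment is empty and 0 is returned.
#'
#' @param a,b Nonempty residue strings (or character vectors).
#' @return Identity percentage in `[0, 100]` (attributes as in
#'   [global_identity()]).
#' @export
local_identity <- function(a, b) {
  a <- .seq_chars(a); b <- .seq_chars(b)
  if (length(a) == 0 || length(b) == 0) stop("empty sequence")
  H <- .nw_matrix(a, b, local = TRUE)
  best <- which(H == max(H), arr.ind = TRUE)
  if (max(H) == 0)
    return(structure(0, matches = 0L, alignment_length = 0L))
  # first maximal cell in row-major order: smallest i, then smallest j
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  tb <- .traceback(H, a, b, best[1] - 1L, best[2] - 1L, local = TRUE)
  structure(100 * tb["matches"] / tb["length"], names = NULL,
            matches = unname(tb["matches"]), alignment_length = unname(tb["length"]))
}

#' Generate and score variants around a reference sequence
#'
#' Samples the latent neighbourhood of a reference sequence, decodes each
#' point, predicts fitness with the Gaussian process, and scores global and
#' local identity of each gap-stripped variant against the gap-stripped
#' reference.
#'
#' @param model Trained `vae_params`.
#' @param gp Fitted `gp_model` on the same latent space.
#' @param ref_row Integer-coded reference sequence (length L, codes 0..20).
#' @param n Number of variants.
#' @param scale Sampling radius multiplier (see [sample_around()]).
#' @param seed Seed.
#' @return Data frame (one `variant_record` per row): `id`, `sequence`,
#'   `aligned`, `predicted_fitness`, `global_identity`, `local_identity`.
#' @export
generate_variants <- function(model, gp, ref_row, n = 100L, scale = 1,
                              seed = 42L) {
  ref_oh <- encode_onehot(ref_row)
  enc <- vae_encode(ref_oh, model)
  Z <- sample_around(as.numeric(enc$mu), as.numeric(enc$log_var), n, scale, seed)
  vars <- realize_sequences(Z, model)
  pred <- gp_predict(gp, t(Z))
  ref_seq <- gsub("-", "", .codes_to_string(ref_row), fixed = TRUE)
  gi <- li <- numeric(n)
  for (i in seq_len(n)) {
    s <- vars$sequence[i]
    if (nchar(s) == 0) { gi[i] <- 0; li[i] <- 0; next }
    gi[i] <- global_identity(s, ref_seq)
    li[i] <- local_identity(s, ref_seq)
  }
  data.frame(id = vars$id, sequence = vars$sequence, aligned = vars$aligned,
             predicted_fitness = pred$mean, predicted_sd = sqrt(pred$var),
             global_identity = gi, local_identity = li)
}

#' Screen variants by a strict predicted-fitness window
#'
#' Pure filter keeping exactly the records with
#' `lower < predicted_fitness < upper` (strict on both sides), preserving
#' order. The screening used for thermostable cytochrome candidates keeps
#' predictions above the best natural T50 (69.7 degrees C) and below 72.
#'
#' @param variants Data frame with a `predicted_fitness` column (as from
#'   [generate_variants()]).
#' @param lower,upper Window bounds, `lower < upper`.
#' @return The surviving rows, with a `summary` attribute listing `n`,
#'   `mean_global_identity`, `max_global_identity` (when identity columns
#'   are present).
#' @export
screen_variants <- function(variants, lower, upper) {
  stopifnot(is.data.frame(variants), lower < upper)
  keep <- variants$predicted_fitness > lower & variants$predicted_fitness < upper
  out <- variants[keep, , drop = FALSE]
  summ <- list(n = nrow(out))
  if ("global_identity" %in% names(out) && nrow(out) > 0) {
    summ$mean_global_identity <- mean(out$global_identity)
    summ$max_global_identity <- max(out$global_identity)
  }
  attr(out, "summary") <- summ
  out
}

#' Write variants to FASTA and a TSV report
#'
#' @param variants Data frame from [generate_variants()].
#' @param fasta_path,report_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_variants <- function(variants, fasta_path = NULL, report_path = NULL) {
  if (!is.null(fasta_path)) {
    set <- Biostrings::BStringSet(variants$sequence)
    names(set) <- variants$id
    Biostrings::writeXStringSet(set, fasta_path)
  }
  if (!is.null(report_path)) {
    cols <- intersect(c("id", "predicted_fitness", "predicted_sd",
                        "global_identity", "local_identity"), names(variants))
    utils::write.table(variants[, cols], report_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta = fasta_path, report = report_path))
}
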