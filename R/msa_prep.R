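#' Read an aligned FASTA file
#'
#' Reads an aligned protein family. All entries must have the same number of
#' alignment columns; `.` and `-` are both accepted as gap characters.
#'
#' @param path Path to a FASTA file.
#' @return A `raw_family` object: list with `ids` (character), `sequences`
#'   (character, uppercased) and `source_length` (alignment columns, `NA`
#'   for an empty file).
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(new_raw_family(character(), character()))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("FASTA file contains no records: ", path, call. = FALSE)
    return(new_raw_family(character(), character()))
  }
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1L) {
    stop("sequences are not aligned: lengths ",
         paste(sort(unique(w)), collapse = ", "))
  }
  new_raw_family(names(set), toupper(as.character(set)))
}

#' Construct a raw (string-level) protein family
#'
#' @param ids Character vector of sequence identifiers.
#' @param sequences Character vector of residue strings (may contain `.`/`-`).
#' @return A `raw_family` object.
#' @export
new_raw_family <- function(ids, sequences) {
  stopifnot(length(ids) == length(sequences))
  sequences <- as.character(sequences)
  lens <- unique(nchar(sequences))
  structure(
    list(ids = as.character(ids), sequences = sequences,
         source_length = if (length(lens) == 1L) lens else NA_integer_),
    class = "raw_family"
  )
}

#' @export
print.raw_family <- function(x, ...) {
  cat(sprintf("raw_family: %d sequences, alignment length %s\n",
              length(x$ids),
              ifelse(is.na(x$source_length), "ragged", x$source_length)))
  invisible(x)
}

#' @export
length.raw_family <- function(x) length(x$ids)

.subset_raw <- function(fam, keep) new_raw_family(fam$ids[keep], fam$sequences[keep])

#' Remove sequences with too many gaps
#'
#' Drops every sequence whose gap fraction (count of `.` or `-` over the
#' alignment length) exceeds `max_frac`; the default threshold is 20%.
#' Order of the survivors is preserved; surviving sequences are
#' untouched.
#'
#' @param fam A `raw_family` of aligned (equal-length) sequences.
#' @param max_frac Maximum tolerated gap fraction in `[0, 1]`.
#' @return The filtered `raw_family`.
#' @export
filter_by_gap_fraction <- function(fam, max_frac = 0.2) {
  stopifnot(inherits(fam, "raw_family"), max_frac >= 0, max_frac <= 1)
  if (length(fam) == 0) return(fam)
  if (is.na(fam$source_length)) stop("sequences must be aligned (equal length)")
  gap_n <- vapply(gregexpr("[.-]", fam$sequences), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  keep <- gap_n / fam$source_length <= max_frac
  if (!any(keep)) warning("gap filter removed every sequence", call. = FALSE)
  .subset_raw(fam, keep)
}

#' Remove duplicate sequences
#'
#' Keeps the first occurrence of each distinct residue string; later exact
#' duplicates are dropped (ids of survivors are the first-seen ids).
#'
#' @param fam A `raw_family`.
#' @return The deduplicated `raw_family`.
#' @export
deduplicate <- function(fam) {
  stopifnot(inherits(fam, "raw_family"))
  .subset_raw(fam, !duplicated(fam$sequences))
}

#' Strip gap characters from every sequence
#'
#' Removes all `.` and `-` characters. The result is generally no longer an
#' alignment (lengths may differ); realignment is delegated to external MSA
#' tools.
#'
#' @param fam A `raw_family`.
#' @return A `raw_family` of ungapped sequences.
#' @export
strip_gap_sites <- function(fam) {
  stopifnot(inherits(fam, "raw_family"))
  out <- gsub("[.-]", "", fam$sequences)
  if (any(nchar(out) == 0) && length(out) > 0)
    warning("gap stripping produced empty sequence(s)", call. = FALSE)
  new_raw_family(fam$ids, out)
}

#' Build the numeric aligned-family representation
#'
#' Converts a cleaned, aligned `raw_family` into the integer-coded matrix
#' form used by the model: an N x L grid with entries 0..20 (gap = 0, amino
#' acids 1..20 per [protein_alphabet()]), plus position-based sequence
#' weights.
#'
#' @param fam A `raw_family` with equal-length sequences.
#' @param weights Optional numeric vector of per-sequence weights; computed
#'   with [position_weights()] when `NULL`.
#' @return An `aligned_family`: list with `ids`, `matrix` (N x L integer),
#'   `L`, and `weights` (positive, summing to N).
#' @export
as_aligned_family <- function(fam, weights = NULL) {
  stopifnot(inherits(fam, "raw_family"))
  if (length(fam) == 0) stop("cannot build an aligned family from 0 sequences")
  if (is.na(fam$source_length)) stop("sequences must be aligned (equal length)")
  chars <- matrix(unlist(strsplit(fam$sequences, "")), nrow = length(fam),
                  byrow = TRUE)
  m <- matrix(.chars_to_codes(as.vector(chars)), nrow = length(fam))
  rownames(m) <- fam$ids
  af <- structure(
    list(ids = fam$ids, matrix = m, L = ncol(m), weights = NULL),
    class = "aligned_family"
  )
  af$weights <- if (is.null(weights)) position_weights(af) else weights
  stopifnot(all(af$weights > 0), all(is.finite(af$weights)))
  af
}

#' @export
print.aligned_family <- function(x, ...) {
  cat(sprintf("aligned_family: %d sequences x %d columns\n",
              nrow(x$matrix), x$L))
  invisible(x)
}

#' Position-based sequence weights
#'
#' Henikoff & Henikoff (1994) position-based weighting: in a column with r
#' distinct symbols, a sequence carrying a symbol that occurs m times in that
#' column contributes 1/(r*m); a sequence's raw weight is the mean of its
#' contributions over columns, and weights are normalised to sum to N. Gaps
#' count as a 21st symbol type. Overrepresented near-duplicate sequences are
#' down-weighted, diverse ones up-weighted.
#'
#' @param fam An `aligned_family` (its `weights` field is ignored).
#' @return Numeric vector of N strictly positive weights summing to N.
#' @export
position_weights <- function(fam) {
  m <- fam$matrix
  n <- nrow(m)
  contrib <- matrix(0, n, ncol(m))
  for (j in seq_len(ncol(m))) {
    tab <- tabulate(m[, j] + 1L, nbins = 21L)
    r <- sum(tab > 0)
    contrib[, j] <- 1 / (r * tab[m[, j] + 1L])
  }
  raw <- rowMeans(contrib)
  raw * n / sum(raw)
}

#' One-hot encode an integer-coded sequence
#'
#' @param row Integer vector with entries in 0..20.
#' @param alphabet A [protein_alphabet()] (defines the 21 rows).
#' @return A 21 x L binary matrix; each column sums to 1, with row k+1 set
#'   where the residue code is k.
#' @export
encode_onehot <- function(row, alphabet = protein_alphabet()) {
  row <- as.integer(row)
  if (any(row < 0 | row > 20)) stop("residue codes must lie in 0..20")
  g <- matrix(0, alphabet$n, length(row))
  g[cbind(row + 1L, seq_along(row))] <- 1
  rownames(g) <- alphabet$symbols
  g
}

#' Decode a one-hot (or probability) grid back to residue codes
#'
#' @param grid A 21 x L numeric matrix; the argmax of each column is taken.
#' @return Integer vector of codes 0..20.
#' @export
decode_onehot <- function(grid) {
  stopifnot(nrow(grid) == 21)
  as.integer(max.col(t(grid), ties.method = "first") - 1L)
}

# one-hot tensor 21 x L x N for a whole family
.family_onehot <- function(fam) {
  m <- fam$matrix
  arr <- array(0, dim = c(21L, ncol(m), nrow(m)))
  for (i in seq_len(nrow(m)))
    arr[, , i] <- encode_onehot(m[i, ])
  arr
}

#' Write a family to aligned FASTA
#'
#' @param fam A `raw_family` or `aligned_family`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(fam, path) {
  if (inherits(fam, "aligned_family")) {
    seqs <- apply(fam$matrix, 1, .codes_to_string)
    fam <- new_raw_family(fam$ids, seqs)
  }
  set <- Biostrings::BStringSet(fam$sequences)
  names(set) <- fam$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write per-sequence weights as a two-column TSV
#'
#' @param fam An `aligned_family`.
#' @param path Output file path (columns `id`, `weight`).
#' @return `path`, invisibly.
#' @export
write_weights_tsv <- function(fam, path) {
  utils::write.table(
    data.frame(id = fam$ids, weight = fam$weights),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Clean an aligned family (gap filter then deduplication)
#'
#' Applies the family cleaning rules to an aligned `raw_family`: drop
#' sequences whose gap fraction exceeds `max_gap_frac` (computed on the
#' original aligned rows, where gaps are still visible), then drop exact
#' duplicates. The result stays aligned.
#'
#' @param fam A `raw_family` of aligned sequences.
#' @param max_gap_frac Gap-fraction threshold (default 0.2).
#' @return The cleaned `raw_family`.
#' @export
clean_family <- function(fam, max_gap_frac = 0.2) {
  deduplicate(filter_by_gap_fraction(fam, max_gap_frac))
}
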