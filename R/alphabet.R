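#' Protein alphabet used throughout the package
#'
#' The 21-token alphabet encoding aligned protein sequences: the gap symbol
#' at integer code 0 followed by the 20 standard amino acids in alphabetical
#' one-letter-code order (`ACDEFGHIKLMNPQRSTVWY`) at codes 1..20. Both `-`
#' and `.` are read as gaps; ambiguity/nonstandard letters (B, J, O, U, X, Z)
#' are mapped to the gap code with a warning, since the 21-state model has no
#' "unknown" slot.
#'
#' @return A list with components `symbols` (character vector of length 21,
#'   gap first), `index_of` (named integer vector mapping token to code
#'   0..20) and `n` (21).
#' @examples
#' ab <- protein_alphabet()
#' ab$index_of[["A"]]  # 1
#' ab$symbols[1]       # "-"
#' @export
protein_alphabet <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  symbols <- c("-", aa)
  index_of <- stats::setNames(seq_along(symbols) - 1L, symbols)
  list(symbols = symbols, index_of = index_of, n = length(symbols))
}

# Residue characters -> integer codes 0..20. '.' and '-' are gaps; unknown
# letters fall back to gap with one warning per call.
.chars_to_codes <- function(chars, alphabet = protein_alphabet()) {
  chars[chars == "."] <- "-"
  chars <- toupper(chars)
  codes <- alphabet$index_of[chars]
  bad <- is.na(codes)
  if (any(bad)) {
    warning(sprintf(
      "%d nonstandard residue character(s) (%s) mapped to gap",
      sum(bad), paste(unique(chars[bad]), collapse = ",")
    ), call. = FALSE)
    codes[bad] <- 0L
  }
  unname(codes)
}

.codes_to_string <- function(codes, alphabet = protein_alphabet()) {
  paste(alphabet$symbols[codes + 1L], collapse = "")
}
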