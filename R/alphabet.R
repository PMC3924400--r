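#' Sequence alphabets
#'
#' An alphabet maps each residue symbol to an integer code in
#' `[0, size)`; all distance computations operate on these codes.
#' [dna_alphabet()] is the 4-letter DNA alphabet `ACGT` and
#' [protein_alphabet()] the 20 standard amino acids.
#'
#' @param symbols Character vector of distinct single characters, in code
#'   order (code 0 first). Lower-case input is upper-cased.
#' @param name Identifier for the alphabet.
#' @return An object of class `motif_alphabet` with fields `name`,
#'   `symbols` and `size`.
#' @examples
#' make_alphabet(c("0", "1"), "binary")
#' dna_alphabet()$size
#' @export
make_alphabet <- function(symbols, name = "custom") {
  symbols <- toupper(as.character(symbols))
  if (any(nchar(symbols) != 1L)) stop("alphabet symbols must be single characters")
  if (anyDuplicated(symbols)) stop("alphabet symbols must be distinct")
  if (length(symbols) < 2L) stop("an alphabet needs at least 2 symbols")
  structure(
    list(name = name, symbols = symbols, size = length(symbols)),
    class = "motif_alphabet"
  )
}

#' @rdname make_alphabet
#' @export
dna_alphabet <- function() make_alphabet(c("A", "C", "G", "T"), "dna")

#' @rdname make_alphabet
#' @export
protein_alphabet <- function() {
  make_alphabet(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "protein")
}

#' Resolve an alphabet specification
#'
#' Accepts a `motif_alphabet` object or one of the strings `"dna"`,
#' `"protein"` or `"custom:<symbols>"` (e.g. `"custom:ACGTU"`).
#'
#' @param x Alphabet object or specification string.
#' @return A `motif_alphabet`.
#' @export
as_alphabet <- function(x) {
  if (inherits(x, "motif_alphabet")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x == "dna") return(dna_alphabet())
    if (x == "protein") return(protein_alphabet())
    if (startsWith(x, "custom:")) {
      return(make_alphabet(strsplit(sub("^custom:", "", x), "")[[1L]]))
    }
  }
  stop("unknown alphabet specification; use 'dna', 'protein' or 'custom:<symbols>'")
}

#' @export
print.motif_alphabet <- function(x, ...) {
  cat(sprintf("<motif_alphabet> %s: {%s} (size %d)\n",
              x$name, paste(x$symbols, collapse = ""), x$size))
  invisible(x)
}

# ---- internal encoding helpers ------------------------------------------

# string -> 0-based integer codes; stops at the first unknown character
encode_seq <- function(s, alphabet) {
  chars <- strsplit(s, "")[[1L]]
  codes <- match(chars, alphabet$symbols) - 1L
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("character '%s' at position %d is not in alphabet '%s'",
                 chars[bad], bad, alphabet$name))
  }
  codes
}

decode_codes <- function(codes, alphabet) {
  paste(alphabet$symbols[codes + 1L], collapse = "")
}

# character vector of equal-length l-mers -> k x l code matrix
encode_lmers <- function(x, alphabet) {
  l <- unique(nchar(x))
  if (length(l) != 1L) stop("l-mers must have equal lengths")
  do.call(rbind, lapply(x, encode_seq, alphabet = alphabet))
}

decode_lmer_matrix <- function(m, alphabet) {
  if (nrow(m) == 0L) return(character(0))
  apply(m, 1L, decode_codes, alphabet = alphabet)
}

# infer a code order from observed characters (for string-level utilities
# that take no explicit alphabet); sorted so code order is lexicographic
alphabet_from_strings <- function(x) {
  syms <- sort(unique(unlist(strsplit(toupper(x), ""))))
  if (length(syms) < 2L) syms <- unique(c(syms, "A", "B"))[1:2]
  make_alphabet(syms, "inferred")
}

resolve_alphabet <- function(alphabet, strings) {
  if (is.null(alphabet)) alphabet_from_strings(strings) else as_alphabet(alphabet)
}
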