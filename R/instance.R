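#' Motif search instances
#'
#' An instance is an ordered set of `n` sequences over a common alphabet.
#' Sequences may have unequal lengths; at search time every sequence must be
#' at least `l` long.
#'
#' @param sequences Character vector of sequences (upper-cased on input).
#'   Names, if present, are kept as record identifiers.
#' @param alphabet Alphabet object or specification (see [as_alphabet()]).
#' @return An object of class `motif_instance` with fields `sequences`
#'   (named character vector), `alphabet`, `n` and `lengths`.
#' @examples
#' motif_instance(c("ACGT", "GGCC"))
#' @export
motif_instance <- function(sequences, alphabet = dna_alphabet()) {
  alphabet <- as_alphabet(alphabet)
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 1L) stop("an instance needs at least one sequence")
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  for (i in seq_along(sequences)) {
    chars <- strsplit(sequences[i], "")[[1L]]
    bad <- which(!(chars %in% alphabet$symbols))
    if (length(bad)) {
      stop(sprintf("record %d ('%s'): character '%s' at position %d is not in alphabet '%s'",
                   i, ids[i], chars[bad[1L]], bad[1L], alphabet$name))
    }
  }
  structure(
    list(sequences = setNames(sequences, ids), alphabet = alphabet,
         n = length(sequences), lengths = nchar(sequences)),
    class = "motif_instance"
  )
}

#' @export
print.motif_instance <- function(x, ...) {
  cat(sprintf("<motif_instance> %d sequence(s) over '%s', lengths %s\n",
              x$n, x$alphabet$name,
              if (length(unique(x$lengths)) == 1L) as.character(x$lengths[1L])
              else paste0("[", min(x$lengths), ", ", max(x$lengths), "]")))
  invisible(x)
}

# encoded view: list of 0-based integer code vectors
encode_instance <- function(instance) {
  lapply(unname(instance$sequences), encode_seq, alphabet = instance$alphabet)
}

#' Read a multi-FASTA file as a motif search instance
#'
#' Records are upper-cased before validation. In strict mode any character
#' outside the alphabet is an error naming the record and position;
#' otherwise the offending sequence is dropped with a warning. Unknown
#' residues (`N`, `X`, IUPAC ambiguity codes) are never interpreted: their
#' Hamming semantics is undefined here.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Alphabet object or specification.
#' @param strict If `TRUE` (default) out-of-alphabet characters are an
#'   error; if `FALSE` such records are dropped with a warning.
#' @return A [motif_instance()].
#' @export
read_fasta <- function(path, alphabet = dna_alphabet(), strict = TRUE) {
  alphabet <- as_alphabet(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in '%s'", path))
  seqs <- toupper(as.character(set))
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1L]]
    bad <- which(!(chars %in% alphabet$symbols))
    if (length(bad)) {
      if (strict) {
        stop(sprintf("record %d ('%s'): character '%s' at position %d is not in alphabet '%s'",
                     i, names(seqs)[i], chars[bad[1L]], bad[1L], alphabet$name))
      }
      warning(sprintf("dropping record %d ('%s'): out-of-alphabet character at position %d",
                      i, names(seqs)[i], bad[1L]))
      keep[i] <- FALSE
    }
  }
  seqs <- seqs[keep]
  if (length(seqs) == 0L) stop("no valid records left after filtering")
  motif_instance(seqs, alphabet)
}

#' Write a motif search instance as multi-FASTA
#'
#' Round-trip identity: re-reading the file reproduces the sequences and
#' their order.
#'
#' @param instance A [motif_instance()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(instance, path) {
  stopifnot(inherits(instance, "motif_instance"))
  if (instance$n < 1L) stop("cannot write an empty instance")
  set <- Biostrings::BStringSet(instance$sequences)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
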