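#' Hamming distance between equal-length strings
#'
#' @param u,v Strings of equal length.
#' @return Integer count of mismatching positions.
#' @examples
#' hamming_distance("ACGT", "ACGA")
#' @export
hamming_distance <- function(u, v) {
  if (nchar(u) != nchar(v)) stop("hamming distance requires equal lengths")
  sum(utf8ToInt(toupper(u)) != utf8ToInt(toupper(v)))
}

#' Consensus total distance and consensus string
#'
#' For a set `T` of equal-length strings the consensus total distance is
#' the columnwise sum of `|T|` minus the maximum symbol frequency. It is
#' the minimum over all strings `M` of the total Hamming distance from `M`
#' to the members of `T`, attained by any columnwise-majority string; for
#' two strings it equals their Hamming distance. Ties in
#' [consensus_string()] go to the lowest symbol code, fixed for
#' reproducibility (only the distance value matters for pruning).
#'
#' @param T Character vector of equal-length strings (at least one).
#' @param alphabet Alphabet object or specification; `NULL` (default)
#'   infers an alphabet from the observed characters in code order.
#' @return [consensus_total_distance()]: an integer;
#'   [consensus_string()]: a string.
#' @examples
#' consensus_total_distance(c("AAA", "AAC", "ACC"))
#' consensus_string(c("AAA", "AAC", "ACC"))
#' @export
consensus_total_distance <- function(T, alphabet = NULL) {
  if (length(T) < 1L) stop("T must contain at least one string")
  alphabet <- resolve_alphabet(alphabet, T)
  cpp_consensus_total_distance(encode_lmers(toupper(T), alphabet), alphabet$size)
}

#' @rdname consensus_total_distance
#' @export
consensus_string <- function(T, alphabet = NULL) {
  if (length(T) < 1L) stop("T must contain at least one string")
  alphabet <- resolve_alphabet(alphabet, T)
  decode_codes(cpp_consensus_string(encode_lmers(toupper(T), alphabet),
                                    alphabet$size), alphabet)
}

#' Packed l-mer table
#'
#' Packs every l-length window of every sequence into 16-bit chunks of
#' `chunk_width` symbols so that one XOR plus one group count scores a whole
#' chunk of the Hamming distance. Overlapping windows share their packed
#' representation (only one chunk is stored per start position), so storage
#' is linear in total sequence length. For DNA (2 bits/symbol) the chunk
#' width is 8; wider alphabets pack fewer symbols per chunk. Packing is a
#' pure optimization: [packed_distance()] always equals
#' [hamming_distance()] on the corresponding windows.
#'
#' @param instance A [motif_instance()].
#' @param l Window length.
#' @return An object of class `packed_lmer_table`.
#' @export
pack_all_lmers <- function(instance, l) {
  stopifnot(inherits(instance, "motif_instance"))
  if (any(instance$lengths < l)) stop("every sequence must be at least l long")
  codes <- encode_instance(instance)
  tab <- cpp_pack_all_lmers(codes, l, instance$alphabet$size)
  structure(
    list(l = l, chunk_width = tab$chunk_width, bits = tab$bits,
         packed = tab$packed, codes = codes, alphabet = instance$alphabet,
         lengths = instance$lengths),
    class = "packed_lmer_table"
  )
}

#' @export
print.packed_lmer_table <- function(x, ...) {
  cat(sprintf("<packed_lmer_table> l=%d, %d symbols per 16-bit chunk, %d sequence(s)\n",
              x$l, x$chunk_width, length(x$codes)))
  invisible(x)
}

#' Hamming distance between two packed windows
#'
#' @param table A [pack_all_lmers()] table.
#' @param a,b Window references: integer vectors `c(seq_index, start)`,
#'   1-based.
#' @return The Hamming distance of the two windows.
#' @export
packed_distance <- function(table, a, b) {
  stopifnot(inherits(table, "packed_lmer_table"))
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != 2L || length(b) != 2L) stop("window references are c(seq_index, start)")
  ns <- length(table$codes)
  if (a[1L] < 1L || a[1L] > ns || b[1L] < 1L || b[1L] > ns)
    stop("sequence index out of range")
  cpp_packed_distance(table$packed, table$codes, table$l, table$chunk_width,
                      table$bits, a[1L] - 1L, a[2L] - 1L, b[1L] - 1L, b[2L] - 1L)
}

#' Precomputed pair-compatibility flags
#'
#' For every pair of windows in *distinct* sequences, one boolean recording
#' whether their Hamming distance is at most `threshold` (the search uses
#' `2d`). Same-sequence entries are `NA`: the search never compares windows
#' of the same sequence.
#'
#' @param instance A [motif_instance()].
#' @param l Window length.
#' @param threshold Distance threshold (the search uses `2 * d`).
#' @return An object of class `pair_compatibility`: a logical matrix
#'   `flags` over global window indices plus a `window_map` data frame
#'   (`seq_index`, `start`, 1-based) and the `threshold`.
#' @export
precompute_pair_flags <- function(instance, l, threshold) {
  stopifnot(inherits(instance, "motif_instance"))
  if (threshold < 0) stop("threshold must be non-negative")
  if (any(instance$lengths < l)) stop("every sequence must be at least l long")
  codes <- encode_instance(instance)
  nwin <- instance$lengths - l + 1L
  seq_of <- rep(seq_along(codes), nwin)
  start_of <- unlist(lapply(nwin, seq_len))
  tot <- sum(nwin)
  # window code matrix, one row per window
  wm <- matrix(0L, tot, l)
  r <- 0L
  for (i in seq_along(codes)) {
    for (j in seq_len(nwin[i])) {
      r <- r + 1L
      wm[r, ] <- codes[[i]][j:(j + l - 1L)]
    }
  }
  mism <- matrix(0L, tot, tot)
  for (c in seq_len(l)) {
    mism <- mism + outer(wm[, c], wm[, c], "!=")
  }
  flags <- mism <= threshold
  same <- outer(seq_of, seq_of, "==")
  flags[same] <- NA
  structure(
    list(threshold = threshold, flags = flags,
         window_map = data.frame(seq_index = seq_of, start = start_of)),
    class = "pair_compatibility"
  )
}

#' @export
print.pair_compatibility <- function(x, ...) {
  cat(sprintf("<pair_compatibility> %d windows, threshold %d\n",
              nrow(x$flags), x$threshold))
  invisible(x)
}
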