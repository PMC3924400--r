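#' Generate a planted (l,d) instance
#'
#' Simulates the standard evaluation model for planted motif search:
#' `n` i.i.d.-uniform sequences of length `m`, one uniformly random l-mer
#' motif, and in each sequence a mutated copy of the motif overwriting a
#' uniformly chosen window. In `"exact"` mode every copy is substituted in
#' exactly `d` distinct positions (each with a uniformly chosen *different*
#' symbol); in `"at_most"` mode the number of substitutions is uniform on
#' `{0, ..., d}`. Defaults (`n = 20`, `m = 600`) are the standard benchmark
#' shape for this problem.
#'
#' @param n Number of sequences.
#' @param m Sequence length.
#' @param l Motif length (`l <= m`).
#' @param d Maximum substitutions per planted copy (`d <= l`).
#' @param alphabet Alphabet object or specification.
#' @param seed Optional integer seed; identical seeds reproduce identical
#'   instances, and the caller's RNG state is left untouched.
#' @param mutation_mode `"exact"` (default) or `"at_most"`.
#' @return A list with elements `instance` (a [motif_instance()]) and
#'   `plant` (class `plant_record`: `motif`, `positions` (1-based window
#'   starts), `mutated_copies`, `distances`).
#' @examples
#' gp <- generate_planted_instance(5, 40, 8, 2, seed = 1)
#' gp$plant$motif
#' @export
generate_planted_instance <- function(n = 20, m = 600, l, d,
                                      alphabet = dna_alphabet(), seed = NULL,
                                      mutation_mode = c("exact", "at_most")) {
  mutation_mode <- match.arg(mutation_mode)
  alphabet <- as_alphabet(alphabet)
  if (n < 1L) stop("n must be at least 1")
  if (l > m) stop("l must not exceed m")
  if (d > l) stop("d must not exceed l")
  if (d < 0L) stop("d must be non-negative")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  syms <- alphabet$symbols
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(syms, m, replace = TRUE), collapse = ""), character(1))
  motif_chars <- sample(syms, l, replace = TRUE)
  motif <- paste(motif_chars, collapse = "")
  positions <- integer(n)
  copies <- character(n)
  dists <- integer(n)
  for (i in seq_len(n)) {
    k <- if (mutation_mode == "exact") d else sample(0:d, 1L)
    copy <- motif_chars
    if (k > 0L) {
      at <- sample.int(l, k)
      for (p in at) {
        others <- syms[syms != copy[p]]
        copy[p] <- others[sample.int(length(others), 1L)]
      }
    }
    j <- sample.int(m - l + 1L, 1L)
    positions[i] <- j
    copies[i] <- paste(copy, collapse = "")
    dists[i] <- sum(copy != motif_chars)
    seqs[i] <- paste0(substr(seqs[i], 1L, j - 1L), copies[i],
                      substr(seqs[i], j + l, m))
  }
  plant <- structure(
    list(motif = motif, positions = positions, mutated_copies = copies,
         distances = dists, l = l, d = d),
    class = "plant_record"
  )
  list(instance = motif_instance(seqs, alphabet), plant = plant)
}

#' @export
print.plant_record <- function(x, ...) {
  cat(sprintf("<plant_record> motif %s planted in %d sequence(s), distances %s\n",
              x$motif, length(x$positions),
              paste(range(x$distances), collapse = "..")))
  invisible(x)
}

#' Write / read a plant record sidecar file
#'
#' Tab-separated interchange format: line 1 holds the planted motif, then
#' one line per sequence with the 0-based sequence index, the 0-based plant
#' offset and the mutated copy actually written into that sequence.
#'
#' @param plant A `plant_record` (see [generate_planted_instance()]).
#' @param path File path.
#' @return `path` (write) or a `plant_record` (read).
#' @export
write_plant_record <- function(plant, path) {
  stopifnot(inherits(plant, "plant_record"))
  lines <- c(plant$motif,
             sprintf("%d\t%d\t%s", seq_along(plant$positions) - 1L,
                     plant$positions - 1L, plant$mutated_copies))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_plant_record
#' @export
read_plant_record <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed plant record file")
  motif <- lines[1L]
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("malformed plant record line")
  copies <- vapply(parts, `[[`, character(1), 3L)
  structure(
    list(motif = motif,
         positions = vapply(parts, function(p) as.integer(p[[2L]]), integer(1)) + 1L,
         mutated_copies = copies,
         distances = vapply(copies, function(cp) hamming_distance(cp, motif),
                            integer(1), USE.NAMES = FALSE),
         l = nchar(motif), d = NA_integer_),
    class = "plant_record"
  )
}
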