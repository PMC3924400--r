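#' Brute-force reference motif search
#'
#' Independent reference for [pms8_search()]: enumerates the d-ball of
#' every window of the first sequence (anchoring on the first sequence is
#' what keeps the reference tractable — every motif must be within `d` of
#' some first-sequence window) and verifies each candidate against all
#' sequences by direct scanning. Shares no pruning logic with the main
#' search beyond the Hamming distance itself.
#'
#' @param instance A [motif_instance()].
#' @param l Motif length.
#' @param d Distance budget.
#' @param max_candidates Scale guard: error out if the candidate count
#'   (first-sequence windows times ball size) would exceed this.
#' @return A `motif_result` (without positions).
#' @export
brute_force_search <- function(instance, l, d, max_candidates = 5e6) {
  stopifnot(inherits(instance, "motif_instance"))
  if (any(instance$lengths < l)) stop("every sequence must be at least l long")
  if (d > l || d < 0) stop("d must be in [0, l]")
  nb <- neighborhood_size(instance$alphabet$size, l, d)
  n_cand <- (instance$lengths[1L] - l + 1) * nb
  if (n_cand > max_candidates) {
    stop(sprintf("brute force would enumerate ~%.2g candidates; reduce l or d",
                 n_cand))
  }
  codes <- encode_instance(instance)
  mm <- cpp_brute_force(codes, l, d, instance$alphabet$size)
  build_motif_result(mm, instance, l, d,
                     stats = list(candidates_bound = n_cand))
}

#' Exhaustive common-neighbor existence
#'
#' Scans all `sigma^l` strings; `TRUE` iff one meets every budget. The
#' reference oracle for [triple_condition()] and
#' [tuple_necessary_condition()].
#'
#' @param T Character vector of equal-length l-mers.
#' @param budgets Integer vector, one budget per member.
#' @param alphabet Alphabet object or specification; `NULL` infers one
#'   from the observed characters.
#' @return Logical.
#' @examples
#' exists_common_neighbor_exhaustive(c("AA", "CC", "GG"), c(1, 1, 1),
#'                                   alphabet = "dna")
#' @export
exists_common_neighbor_exhaustive <- function(T, budgets, alphabet = NULL) {
  if (length(T) < 1L) stop("T must contain at least one l-mer")
  if (length(budgets) != length(T)) stop("one budget per tuple member required")
  strings <- toupper(T)
  alphabet <- resolve_alphabet(alphabet, strings)
  cpp_exists_common_neighbor(encode_lmers(strings, alphabet),
                             as.integer(budgets), alphabet$size)
}
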