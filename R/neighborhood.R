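#' Enumerate the common d-neighborhood of a tuple of l-mers
#'
#' Emits exactly the set of l-mers `M` with `H(M, T[i]) <= budgets[i]` for
#' every member, each once, in lexicographic order of symbol codes. The
#' enumeration walks the tree of all l-mers depth first and prunes a branch
#' as soon as one of three sound conditions proves no completion can meet
#' the budgets: a member's partial distance exceeds its budget; the summed
#' partial distances plus the consensus total distance of the remaining
#' columns exceed the total budget; or, for some pair of members, the
#' partial distances plus their remaining-column Hamming distance exceed
#' the summed pair budgets. With `prune = FALSE` the full tree is traversed
#' and filtered at the leaves (for testing; identical output).
#'
#' @param T Character vector of equal-length l-mers (at least one).
#' @param budgets Integer vector, one non-negative budget per member.
#' @param alphabet Alphabet object or specification (default DNA).
#' @param prune Apply the pruning rules (default `TRUE`).
#' @return Character vector of neighborhood members, sorted in code order.
#' @examples
#' length(generate_common_neighborhood("AAAA", 1))            # 13
#' generate_common_neighborhood(c("AAAA", "TTTT"), c(2, 2))   # 6 members
#' @export
generate_common_neighborhood <- function(T, budgets, alphabet = dna_alphabet(),
                                         prune = TRUE) {
  if (length(T) < 1L) stop("T must contain at least one l-mer")
  if (length(budgets) == 1L && length(T) > 1L)
    budgets <- rep(budgets, length(T))
  if (length(budgets) != length(T)) stop("one budget per tuple member required")
  if (any(budgets < 0)) stop("budgets must be non-negative")
  alphabet <- as_alphabet(alphabet)
  m <- encode_lmers(toupper(T), alphabet)
  res <- cpp_generate_common_neighborhood(m, as.integer(budgets),
                                          alphabet$size, prune)
  decode_lmer_matrix(res, alphabet)
}
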