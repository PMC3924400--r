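#' Pairwise common-neighbor condition
#'
#' Two l-mers `a` and `b` have a common neighbor `M` with
#' `H(a, M) <= da` and `H(b, M) <= db` if and only if
#' `H(a, b) <= da + db`. The condition is exact (necessary and
#' sufficient) for pairs.
#'
#' @param a,b Equal-length strings.
#' @param da,db Non-negative distance budgets.
#' @return Logical.
#' @examples
#' pair_condition("AAAA", "TTTT", 2, 2)
#' @export
pair_condition <- function(a, b, da, db) {
  hamming_distance(a, b) <= da + db
}

#' Column types of a 3-tuple
#'
#' Classifies each column of three equal-length l-mers: `n0` all equal,
#' `n1` first differs from the other two (which agree), `n2` second
#' differs, `n3` third differs, `n4` all distinct. These counts drive the
#' constructive proof behind [construct_common_neighbor()]. For binary
#' alphabets `n4` is always 0.
#'
#' @param t1,t2,t3 Equal-length strings.
#' @return Named integer vector `c(n0, n1, n2, n3, n4)` summing to `l`.
#' @examples
#' column_type_counts("AAAA", "AACA", "AAAC")
#' @export
column_type_counts <- function(t1, t2, t3) {
  strings <- toupper(c(t1, t2, t3))
  alphabet <- alphabet_from_strings(strings)
  m <- encode_lmers(strings, alphabet)
  setNames(cpp_column_type_counts(m[1L, ], m[2L, ], m[3L, ]),
           c("n0", "n1", "n2", "n3", "n4"))
}

#' Triple common-neighbor condition (necessary and sufficient)
#'
#' Three l-mers have a common neighbor within budgets `(d1, d2, d3)` if and
#' only if every pairwise Hamming distance is within the summed pair
#' budgets and the consensus total distance of the triple is within the
#' total budget. [construct_common_neighbor()] returns an explicit witness
#' whenever the condition holds, and `NULL` exactly when it fails.
#'
#' @param t1,t2,t3 Equal-length strings.
#' @param budgets Integer vector of three non-negative budgets.
#' @return [triple_condition()]: logical. [construct_common_neighbor()]:
#'   a witness string or `NULL`.
#' @examples
#' triple_condition("AA", "CC", "GG", c(1, 1, 1))       # FALSE
#' construct_common_neighbor("AAAA", "AACC", "CCAA", c(2, 2, 2))
#' @export
triple_condition <- function(t1, t2, t3, budgets) {
  stopifnot(length(budgets) == 3L)
  strings <- toupper(c(t1, t2, t3))
  alphabet <- alphabet_from_strings(strings)
  m <- encode_lmers(strings, alphabet)
  cpp_triple_condition(m[1L, ], m[2L, ], m[3L, ], as.integer(budgets))
}

#' @rdname triple_condition
#' @export
construct_common_neighbor <- function(t1, t2, t3, budgets) {
  stopifnot(length(budgets) == 3L)
  strings <- toupper(c(t1, t2, t3))
  alphabet <- alphabet_from_strings(strings)
  m <- encode_lmers(strings, alphabet)
  res <- cpp_construct_common_neighbor(m[1L, ], m[2L, ], m[3L, ],
                                       as.integer(budgets))
  if (is.null(res)) NULL else decode_codes(res, alphabet)
}

#' Tuple necessary condition (consensus-distance bound)
#'
#' For any tuple `T` with per-member budgets, a common neighbor can exist
#' only if the consensus total distance of `T` is at most the summed
#' budgets. `FALSE` is conclusive (no common neighbor); `TRUE` is
#' non-conclusive for tuples of 4 or more.
#'
#' @param T Character vector of equal-length strings.
#' @param budgets Integer vector, one non-negative budget per member.
#' @return Logical.
#' @examples
#' tuple_necessary_condition(c("AA", "CC", "GG", "TT"), c(1, 1, 1, 1))
#' @export
tuple_necessary_condition <- function(T, budgets) {
  if (length(T) < 1L) stop("T must contain at least one string")
  if (length(budgets) != length(T)) stop("one budget per tuple member required")
  strings <- toupper(T)
  alphabet <- alphabet_from_strings(strings)
  cpp_tuple_condition(encode_lmers(strings, alphabet), as.integer(budgets),
                      alphabet$size)
}
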