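#' Search parameters
#'
#' Tuning knobs for [pms8_search()]. None of them affects the result set —
#' only how the work is split between the sample-driven part (stack
#' construction with candidate filtering) and the pattern-driven part
#' (neighborhood enumeration), and which speedup structures are built.
#'
#' @param threshold_t `"auto"` (default, see [choose_threshold_t()]) or an
#'   explicit stack depth at which the search switches from filtering to
#'   neighborhood generation.
#' @param n_prime `"auto"` (default, see [choose_n_prime()]) or an explicit
#'   number of sequences to search over; candidate motifs are then verified
#'   against the held-out sequences.
#' @param sort_rows Reorder candidate rows by ascending size after each
#'   filtering step.
#' @param pair_table Precompute the `H <= 2d` flag for every cross-sequence
#'   window pair.
#' @param packing Use the packed l-mer table for Hamming distances.
#' @param minimal_filter Use the literal minimal filter (pair bound with
#'   the new stack top, plus the exact triple test right after the second
#'   push) instead of the default stronger filter, which additionally runs
#'   the triple test against every stack item and the consensus-distance
#'   bound on the whole stack.
#' @param workers Number of worker processes (1 = serial).
#' @return A list of class `pms8_params`.
#' @export
pms8_params <- function(threshold_t = "auto", n_prime = "auto",
                        sort_rows = TRUE, pair_table = TRUE, packing = TRUE,
                        minimal_filter = FALSE, workers = 1L) {
  structure(
    list(threshold_t = threshold_t, n_prime = n_prime,
         sort_rows = isTRUE(sort_rows), pair_table = isTRUE(pair_table),
         packing = isTRUE(packing), minimal_filter = isTRUE(minimal_filter),
         workers = as.integer(workers)),
    class = "pms8_params"
  )
}

#' Default stack-depth threshold
#'
#' Heuristic depth at which the search switches from the sample-driven to
#' the pattern-driven phase:
#' `t = max(2, floor((2 (d + 1) ln(sigma) - ln(m)) / ln(sigma)))`.
#' It grows with `d` and the alphabet size (to avoid huge neighborhoods)
#' and shrinks with `m` (to avoid over-filtering). Purely a performance
#' knob: the motif set is identical for any valid `t`.
#'
#' @param m Sequence length (the longest, for ragged instances).
#' @param d Distance budget.
#' @param sigma Alphabet size.
#' @return An integer `>= 2`.
#' @export
choose_threshold_t <- function(m, d, sigma) {
  stopifnot(m > 0, sigma >= 2, d >= 0)
  max(2L, as.integer(floor((2 * (d + 1) * log(sigma) - log(m)) / log(sigma))))
}

#' Default subset size n'
#'
#' Number of sequences the search runs over before verifying candidates
#' against the rest: `n' = clamp(floor(t + n/4 - ln(t)), t, n)`. Like the
#' threshold, this only trades work between phases; the output is
#' invariant to any valid choice.
#'
#' @param n Number of sequences.
#' @param t Stack-depth threshold.
#' @return An integer in `[min(t, n), n]`.
#' @export
choose_n_prime <- function(n, t) {
  stopifnot(n >= 1, t >= 1)
  np <- as.integer(floor(t + n / 4 - log(t)))
  max(min(t, n), min(np, n))
}

resolve_params <- function(instance, l, d, params) {
  n <- instance$n
  sigma <- instance$alphabet$size
  t <- params$threshold_t
  if (identical(t, "auto")) t <- choose_threshold_t(max(instance$lengths), d, sigma)
  t <- as.integer(max(1L, min(t, n)))
  if (n >= 2L) t <- max(2L, t)
  np <- params$n_prime
  if (identical(np, "auto")) np <- choose_n_prime(n, t)
  np <- as.integer(max(t, min(np, n)))
  list(t = t, n_prime = np)
}

#' Exact planted (l,d)-motif search
#'
#' Reports every l-mer that occurs within Hamming distance `d` of at least
#' one window in each sequence of the instance — the exact motif set, equal
#' to what a brute-force scan would produce ([brute_force_search()]).
#'
#' The search keeps a matrix of candidate windows per sequence and grows a
#' stack of l-mers from distinct sequences. After each push the candidate
#' rows are filtered in place (pair bound at `2d`, the exact triple
#' condition, and the consensus-distance bound); an emptied row triggers
#' backtracking. Once the stack reaches the threshold depth the common
#' d-neighborhood of the stack is enumerated and every neighbor verified
#' against the remaining sequences.
#'
#' @param instance A [motif_instance()].
#' @param l Motif length.
#' @param d Distance budget (`0 <= d <= l`).
#' @param params A [pms8_params()] object.
#' @param positions Also report, per motif and sequence, the 1-based start
#'   of the first window within distance `d`.
#' @return An object of class `motif_result`: sorted unique `motifs`,
#'   optional `positions` matrix, and search `stats` (tuples explored,
#'   neighborhoods generated, candidates verified).
#' @examples
#' gp <- generate_planted_instance(5, 40, 8, 2, seed = 1)
#' res <- pms8_search(gp$instance, 8, 2)
#' gp$plant$motif %in% res$motifs
#' @export
pms8_search <- function(instance, l, d, params = pms8_params(),
                        positions = FALSE) {
  stopifnot(inherits(instance, "motif_instance"))
  if (any(instance$lengths < l))
    stop("every sequence must be at least l long")
  if (d > l) stop("d must not exceed l")
  if (d < 0) stop("d must be non-negative")
  if (l < 1) stop("l must be positive")
  if (params$workers > 1L) {
    return(run_parallel_search(instance, l, d, params,
                               workers = params$workers,
                               positions = positions))
  }
  rp <- resolve_params(instance, l, d, params)
  codes <- encode_instance(instance)
  raw <- cpp_pms8_search(codes, l, d, instance$alphabet$size,
                         rp$t, rp$n_prime,
                         params$sort_rows, params$pair_table, params$packing,
                         params$minimal_filter,
                         seq_len(instance$lengths[1L] - l + 1L) - 1L)
  build_motif_result(raw$motifs, instance, l, d,
                     stats = list(
                       tuples_explored = raw$tuples_explored,
                       neighborhoods_generated = raw$neighborhoods_generated,
                       candidates_verified = raw$candidates_verified,
                       threshold_t = rp$t, n_prime = rp$n_prime),
                     positions = positions)
}

build_motif_result <- function(motif_matrix, instance, l, d, stats,
                               positions = FALSE) {
  motifs <- decode_lmer_matrix(motif_matrix, instance$alphabet)
  motifs <- sort(unique(motifs))
  pos <- NULL
  if (positions && length(motifs)) {
    pos <- t(vapply(motifs, motif_witness_positions, integer(instance$n),
                    instance = instance, d = d))
    colnames(pos) <- names(instance$sequences)
  }
  structure(
    list(motifs = motifs, positions = pos, stats = stats, l = l, d = d),
    class = "motif_result"
  )
}

# first 1-based window start within distance d, per sequence
motif_witness_positions <- function(motif, instance, d) {
  l <- nchar(motif)
  vapply(seq_len(instance$n), function(i) {
    s <- instance$sequences[[i]]
    for (off in seq_len(nchar(s) - l + 1L)) {
      if (hamming_distance(substr(s, off, off + l - 1L), motif) <= d)
        return(off)
    }
    NA_integer_
  }, integer(1))
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("<motif_result> (l=%d, d=%d): %d motif(s)\n", x$l, x$d,
              length(x$motifs)))
  if (length(x$motifs)) {
    shown <- head(x$motifs, 10L)
    cat(paste0("  ", shown, collapse = "\n"), "\n")
    if (length(x$motifs) > 10L) cat(sprintf("  ... and %d more\n",
                                            length(x$motifs) - 10L))
  }
  invisible(x)
}

#' Verify a candidate motif against an instance
#'
#' `TRUE` iff every sequence with index `>= from_row` contains a window
#' within distance `d` of `motif`. `from_row > 1` supports the n'-subset
#' speedup, where candidates found on a subset are checked against the
#' held-out sequences only.
#'
#' @param motif Candidate l-mer (string).
#' @param instance A [motif_instance()].
#' @param d Distance budget.
#' @param from_row First sequence index to check (1-based; default all).
#' @return Logical.
#' @export
verify_motif <- function(motif, instance, d, from_row = 1L) {
  stopifnot(inherits(instance, "motif_instance"))
  codes <- encode_instance(instance)
  m <- encode_seq(toupper(motif), instance$alphabet)
  cpp_verify_motif(m, codes, as.integer(d), as.integer(from_row) - 1L)
}

#' Filter a candidate row against the search stack
#'
#' Reference implementation of the per-push row filter: a window `u`
#' survives iff it is within `2d` of the newly pushed l-mer, passes the
#' exact triple condition with every l-mer already below the top of the
#' stack, and the stack plus `u` passes the consensus-distance bound. The
#' filter is sound: it never removes a window that extends to a motif
#' witness tuple (tested via output invariance).
#'
#' @param row Character vector of candidate l-mers.
#' @param new_lmer The l-mer just pushed on the stack.
#' @param stack_lmers Character vector of l-mers already on the stack
#'   (below the new one), possibly empty.
#' @param d Distance budget.
#' @return The surviving subset of `row`, in order.
#' @export
filter_row <- function(row, new_lmer, stack_lmers = character(0), d) {
  keep <- vapply(row, function(u) {
    if (!pair_condition(u, new_lmer, d, d)) return(FALSE)
    for (s in stack_lmers) {
      if (!triple_condition(s, new_lmer, u, c(d, d, d))) return(FALSE)
    }
    tuple_necessary_condition(c(stack_lmers, new_lmer, u),
                              rep(d, length(stack_lmers) + 2L))
  }, logical(1), USE.NAMES = FALSE)
  row[keep]
}

#' Row processing order by size
#'
#' Stable permutation ordering candidate rows by ascending current size;
#' processing small rows first shrinks the branching factor where filtering
#' is most expensive. Enabling or disabling the reorder never changes the
#' motif set.
#'
#' @param sizes Integer vector of current row sizes.
#' @return An integer permutation (1-based).
#' @examples
#' sort_rows_by_size(c(5, 2, 9))  # 2 1 3
#' @export
sort_rows_by_size <- function(sizes) {
  order(sizes)  # base order is stable for ties
}
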