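#' Size of a Hamming ball of l-mers
#'
#' Number of l-mers within distance `d` of a fixed l-mer over an alphabet
#' of size `sigma`: `sum_{i=0}^{d} C(l, i) (sigma - 1)^i`.
#'
#' @param sigma Alphabet size (`>= 2`).
#' @param l l-mer length.
#' @param d Radius (`0 <= d <= l`).
#' @return The neighborhood size (numeric; exact for the supported range).
#' @examples
#' neighborhood_size(4, 4, 1)    # 13
#' neighborhood_size(4, 13, 4)   # 66379
#' @export
neighborhood_size <- function(sigma, l, d) {
  stopifnot(sigma >= 2, l >= 1)
  if (d < 0 || d > l) stop("d must be in [0, l]")
  i <- 0:d
  sum(choose(l, i) * (sigma - 1)^i)
}

#' Closed-form expectation model for spurious motifs
#'
#' Chain of quantities for an instance of `n` i.i.d.-uniform strings of
#' length `m`: the neighborhood size `N`, the probability
#' `p = N / sigma^l` that a fixed l-mer is a d-neighbor of a random l-mer,
#' the probability `q = 1 - (1 - p)^(m - l + 1)` of at least one neighbor
#' among a string's windows, and the expected number of chance motifs
#' `E = sigma^l * q^n`. `E` is computed in log space: `q^n` can be of
#' order `1e-25` and would otherwise underflow prematurely.
#'
#' @param n Number of strings.
#' @param m String length.
#' @param l Motif length (`l <= m`).
#' @param d Distance budget (`d <= l`).
#' @param sigma Alphabet size.
#' @return [expectation_model()]: list with `N`, `p`, `q`, `E`.
#'   [expected_spurious_motifs()]: the expectation `E` alone.
#' @examples
#' expected_spurious_motifs(20, 600, 13, 4, 4)   # about 5.2
#' @export
expectation_model <- function(n, m, l, d, sigma = 4) {
  stopifnot(n >= 1, sigma >= 2)
  if (l > m) stop("l must not exceed m")
  if (d < 0 || d > l) stop("d must be in [0, l]")
  N <- neighborhood_size(sigma, l, d)
  log_p <- log(N) - l * log(sigma)
  p <- exp(log_p)
  if (p >= 1) {
    q <- 1
    log_q <- 0
  } else {
    # q = 1 - (1 - p)^(m - l + 1), stable for tiny p
    q <- -expm1((m - l + 1) * log1p(-p))
    log_q <- log(q)
  }
  log_E <- l * log(sigma) + n * log_q
  list(N = N, p = p, q = q, E = exp(log_E))
}

#' @rdname expectation_model
#' @export
expected_spurious_motifs <- function(n, m, l, d, sigma = 4) {
  expectation_model(n, m, l, d, sigma)$E
}

#' Smallest challenging distance for a motif length
#'
#' The challenging instance for a given `l` is the smallest `d` for which
#' the expected number of length-`l` motifs occurring by random chance in
#' the instance is at least 1. For the standard 20 x 600 DNA shape this
#' gives the classical series (13,4), (15,5), ...
#'
#' @param l Motif length.
#' @param n,m Instance shape (defaults: the standard benchmark 20 x 600).
#' @param sigma Alphabet size (default DNA).
#' @return The smallest qualifying `d` (at most `l`: at `d = l` every
#'   l-mer matches everywhere and `E = sigma^l`).
#' @examples
#' smallest_challenging_d(13)   # 4
#' smallest_challenging_d(15)   # 5
#' @export
smallest_challenging_d <- function(l, n = 20, m = 600, sigma = 4) {
  stopifnot(l >= 1)
  for (d in 0:l) {
    if (expected_spurious_motifs(n, m, l, d, sigma) >= 1) return(d)
  }
  l
}
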