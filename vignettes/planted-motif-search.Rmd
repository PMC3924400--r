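---
title: "Exact planted (l,d)-motif search: model, pruning mathematics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact planted (l,d)-motif search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pms8)
```

## The problem and its instance model

Planted (l,d)-motif search takes n sequences over an alphabet Σ and reports
every l-mer M that occurs in each sequence with at most d mismatches. A
motif here is a *pattern*, not necessarily a substring of any sequence: M
qualifies as soon as each sequence contains some window u with Hamming
distance H(M, u) ≤ d.

Solvers for this problem are evaluated on synthetic *planted* instances:
n i.i.d.-uniform strings of length m, one random l-mer chosen as the motif,
and a mutated copy of it overwritten at a random position of each string.
`generate_planted_instance()` reproduces this model with the standard
benchmark shape (n = 20, m = 600, DNA) as its default. Two mutation
conventions are offered. The planting model is usually stated as "modified
in at most d positions"; the default here mutates **exactly** d distinct
positions (each to a uniformly chosen different symbol), the fixed-mismatch
convention that maximizes instance difficulty, with `mutation_mode =
"at_most"` (mutation count uniform on 0..d) as the literal alternative.
Either way every planted copy is within distance d of the motif, so the
plant is a valid motif by construction — the basis of the plant-recovery
tests.

What the generator does *not* emulate about real regulatory sequence:
composition bias (GC content, repeats), positional preference of sites,
correlated mutations between binding sites, or multiple distinct motifs.
Passing the planted-recovery and exactness tests therefore demonstrates
algorithmic correctness on the i.i.d. model, not biological sensitivity on
genomic data; because the search is exact for *any* input, correctness
transfers, but runtimes on low-complexity real sequence can be worse than
the i.i.d. benchmarks suggest.

## Chance motifs and challenging instances

With everything uniform and independent, the number of spurious motifs has
a closed-form expectation. A fixed l-mer has
N = Σ_{i=0}^{d} C(l,i)(|Σ|−1)^i neighbors within distance d, so a random
window matches it with probability p = N/|Σ|^l, a random string of length m
contains a match with probability q = 1 − (1 − p)^(m−l+1), and the expected
motif count is E = |Σ|^l · q^n. `expectation_model()` evaluates this chain;
E is computed in log space because q^n underflows double precision already
at moderate d (q^20 ≈ 1e-25 at (13,3)). The instance (l,d) is *challenging*
when d is the smallest integer with E ≥ 1 (`smallest_challenging_d()`);
for the 20 × 600 DNA shape this yields the canonical series (13,4), (15,5).
For l = 17 the strict formula chain lands marginally below 1 at d = 6, so
the scan is kept strictly faithful to the formula rather than to the
convention-dependent tail of the canonical list; the l = 13 and l = 15
anchors are robust to this choice.

## Pruning mathematics

Three exact facts drive the search.

**Pairs.** l-mers a, b have a common neighbor within budgets (d_a, d_b) iff
H(a, b) ≤ d_a + d_b.

**Any tuple (necessary).** The *consensus total distance* C(T) — per
column, |T| minus the majority count, summed — is the minimum achievable
total distance from any single string to all of T (attained by a
columnwise-majority string; ties in `consensus_string()` go to the lowest
symbol code, which is correctness-neutral because only the distance value
feeds the pruning). Hence a common neighbor within budgets d_1..d_k
requires C(T) ≤ Σ d_i (`tuple_necessary_condition()`).

**Triples (necessary and sufficient).** For three l-mers the pair bounds on
all three pairs *plus* C(T) ≤ d_1 + d_2 + d_3 are also sufficient.
`construct_common_neighbor()` builds an explicit witness, following the
constructive case analysis over column types N0–N4 (all agree; exactly one
member differs; all distinct). Two choices in that construction are
underdetermined and are fixed for determinism: when some member i has at
least d_i columns of its own type, the **leftmost** d_i such columns are
repaired; otherwise the all-distinct columns are allocated to members in
order 1, 2, 3, again leftmost first, with unassigned N4 columns defaulting
to the first member's symbol. Any valid choice would do; the implementation
relies only on the verified postcondition H(M, t_i) ≤ d_i, which the test
suite checks against exhaustive enumeration (all 64³ DNA triples at l = 3
with every budget vector in {0..3}³, plus 10⁵ random triples at l ∈ 4..8).

## Neighborhood enumeration

`generate_common_neighborhood()` walks the Σ^l tree depth first, visiting
children in symbol-code order (output is therefore sorted and
duplicate-free). A node at depth k with partial distances h_i is cut when
any of three sound rules fires:

1. h_i > d_i for some member (distances only grow);
2. Σ h_i + C(suffix of T) > Σ d_i — the tuple bound applied to the
   uncommitted columns;
3. h_i + h_j + H(suffix of T_i, suffix of T_j) > d_i + d_j for some pair —
   the pair bound on the uncommitted columns.

Suffix consensus distances and pairwise suffix distances are precomputed
once per tuple in O(l·|T|²), so each node check is O(|T|²). Rules 2 and 3
instantiate the pruning conditions above on the remaining columns and can
never cut a subtree containing a valid neighbor; the suite verifies the
enumeration against brute-force filtering of all |Σ|^l strings and against
the unpruned traversal (`prune = FALSE`).

## The search proper

The engine keeps the candidate matrix R (row i = surviving windows of
sequence i) in a single buffer: filtering moves survivors to the row
prefix, and only the row sizes are stacked, so backtracking is a size
restore and the memory for all snapshots is that of one matrix. The first
sequence always anchors the stack — this is also the parallel decomposition
(one job per first-sequence window). Subsequent rows are consumed smallest
first (`sort_rows = TRUE`), which shrinks the branching factor where
filtering is most expensive.

On each push of x the unconsumed rows are filtered. The default filter
keeps u only if it passes the pair bound with x, the exact triple test with
**every** stack item, and the consensus bound on the whole stack plus u.
This is strictly stronger than the minimal filter the algorithm needs
(pair bound with the top plus the triple test right after the second push,
`minimal_filter = TRUE`) and still sound, since every condition is
necessary for u to extend the stack to a motif witness. Both variants are
exposed and the suite checks they produce identical motif sets.

When the stack reaches depth min(t, n′) the common neighborhood of the
stack is generated with uniform budgets d and each neighbor M is verified:
against the *filtered* rows for unconsumed active sequences — sound because
any witness u of a common neighbor M of the stack satisfies every filter
condition (M itself certifies the pair, triple and consensus bounds) — and
against the full sequences for the n − n′ held-out ones.

## Tunable parameters

- **t** (stack depth threshold): switch point between the sample-driven and
  pattern-driven phases. Default
  t = max(2, ⌊(2(d+1)·ln σ − ln m)/ln σ⌋), clamped to [2, n]: deeper stacks
  for larger d and σ (neighborhoods explode exponentially in the remaining
  budget), shallower for longer sequences (filtering cost grows with m).
  The printed source for this heuristic is typographically ambiguous; this
  realization (natural logs, floor) reproduces its stated monotonicities
  and is exposed as an override (`threshold_t`), with correctness
  independent of the value — only runtime moves.
- **n′** (subset size): search runs on the first n′ sequences, candidates
  are verified on the rest. Default n′ = clamp(⌊t + n/4 − ln t⌋, t, n),
  same caveat and same invariance.
- **Toggles** `sort_rows`, `pair_table`, `packing`, `minimal_filter`: pure
  speedups. Packing stores ⌊16/⌈log₂ σ⌉⌋ symbols per 16-bit chunk (8 for
  DNA, 3 for protein) and scores a chunk per XOR via a 65536-entry group
  count table; overlapping windows share chunks, keeping the table linear
  in total sequence length. The pair table stores the H ≤ 2d bit for every
  cross-sequence window pair (same-sequence pairs are never compared).
- **workers**: forked processes over a dynamic work queue
  (`parallel::mclapply(mc.preschedule = FALSE)`); dynamic dispatch matters
  because per-window subproblem runtimes vary by orders of magnitude.
  Results are sorted and deduplicated, so output is independent of
  completion order and worker count.

## Numerical and degenerate-input choices

- Coordinates are 1-based inside R (window starts, witness positions); the
  plant sidecar file and the CLI `--positions` output use 0-based offsets
  as their interchange convention.
- d = 0 runs through the same code path and degenerates to exact common
  substring search; n = 1 degenerates to a single-window neighborhood
  union.
- Unequal sequence lengths are accepted; the threshold heuristic uses the
  maximum length.
- Out-of-alphabet residues (N, X, IUPAC codes) are rejected in strict mode
  and dropped with a warning otherwise — their Hamming semantics is
  undefined and silently scoring them would corrupt distances.
- The brute-force reference anchors on the first sequence (union of d-balls
  of its windows) rather than scanning all |Σ|^l patterns; this keeps it
  usable at moderate scale while remaining an independent code path — it
  shares nothing with the engine beyond the Hamming distance itself.

## Problem sizes used by the test suite

The suite verifies exactness (search ≡ brute force) on 50 randomized
instances with n ∈ [3,10], m ∈ [20,60], l ∈ [4,8], d ∈ [0,2] over DNA and a
5-letter alphabet; triple-test exactness exhaustively at l = 3 and on 10⁵
random triples up to l = 8; configuration invariance across all 2⁴ toggle
combinations, t ∈ {2,3,4}, the full n′ range and 1–4 workers on a planted
(7,2) instance; and plant recovery on a planted (13,4) instance with
n = 20, m = 200 — the full m = 600 benchmark solves in a few minutes on one
core and is exercised outside the default suite. These sizes were chosen so
the whole suite runs comfortably on a laptop core while still covering the
regimes where the pruning conditions actually bind.

## Known limitations

- Quorum variants (motifs present in only q < n sequences) are not
  supported; every sequence must contain a match.
- Single forward strand; no reverse-complement matching.
- The expectation model assumes i.i.d. uniform backgrounds; it will
  misestimate spurious counts on biased real sequence.
- The parallel driver is same-host (forked processes); distributed
  execution is out of scope.
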