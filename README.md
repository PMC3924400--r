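# pms8

Exact planted (l,d)-motif search for DNA and protein sequences.

## The problem

Given n sequences over an alphabet Σ and two integers l and d, the planted
(l,d)-motif search (PMS) problem asks for **every** l-mer M that occurs in
each sequence with at most d mismatches — i.e. every sequence has a window u
of length l with Hamming distance H(M, u) ≤ d. PMS is a standard abstraction
of transcription-factor binding-site discovery and is NP-complete; exact
solvers are judged on *challenging* instances: for a given l, the smallest d
at which the expected number of chance motifs in the standard benchmark
(20 i.i.d. DNA strings of length 600) reaches 1, giving the classical series
(13,4), (15,5), (17,6), ...

## The algorithm

`pms8_search()` implements the PMS8 strategy, a hybrid of sample-driven and
pattern-driven search:

- A matrix R holds the candidate windows of each sequence. The search grows
  a stack of l-mers r_1, r_2, ... from distinct sequences; after each push
  every remaining row is filtered **in place** (all matrix snapshots share
  one buffer; only row sizes are stacked).
- Filtering uses three sound conditions: the pair bound H(u, x) ≤ 2d; the
  exact triple test — three l-mers have a common d-neighbor **iff**
  C(T_i, T_j) ≤ d_i + d_j for all pairs and C(T) ≤ d_1 + d_2 + d_3, where
  C(T) is the *consensus total distance* (columnwise sum of |T| minus the
  majority count) — with a constructive witness
  (`construct_common_neighbor()`); and the consensus-distance bound
  C(T) ≤ Σ d_i for the whole stack (necessary for any tuple size).
- Once the stack reaches a threshold depth t, the common d-neighborhood of
  the stack is enumerated by a pruned depth-first walk of the Σ^l tree
  (`generate_common_neighborhood()`) and every neighbor is verified against
  the remaining sequences (`verify_motif()`).
- Speedups: rows reordered by size after filtering, packed l-mer chunks
  scoring 8 DNA symbols per 16-bit XOR, a precomputed ≤ 2d pair table, and
  an n′-subset scheme (search n′ < n sequences, verify candidates on the
  rest). All of them — and the threshold t, n′ and the worker count — leave
  the motif set provably unchanged.

A closed-form expectation model (`expected_spurious_motifs()`,
`smallest_challenging_d()`) quantifies how many motifs arise by chance:
N = Σ_{i≤d} C(l,i)(|Σ|−1)^i, p = N/|Σ|^l, q = 1 − (1−p)^(m−l+1),
E = |Σ|^l · q^n.

## Worked example

```r
library(pms8)

# a planted benchmark-style instance: 20 DNA sequences, motif length 13,
# up to 4 substitutions per planted copy
gp <- generate_planted_instance(n = 20, m = 200, l = 13, d = 4, seed = 42)
gp$plant$motif
#> [1] "TAGGTGTCATTGT"

res <- pms8_search(gp$instance, l = 13, d = 4)
res
#> <motif_result> (l=13, d=4): 1 motif(s)
#>   TAGGTGTCATTGT
str(res$stats)
#> List of 5
#>  $ tuples_explored        : num 12711
#>  $ neighborhoods_generated: num 166
#>  $ candidates_verified    : num 115
#>  $ threshold_t            : int 6
#>  $ n_prime                : int 9

smallest_challenging_d(13)        # the classical challenging pair (13,4)
#> [1] 4
expected_spurious_motifs(20, 600, 13, 4)
#> [1] 5.232521
```

The single reported motif is exactly the planted one: at m = 200 the
expected chance-motif count is ≈ 3e-8, so anything beyond the plant would be
a surprise. At the full benchmark length m = 600 about 5.2 spurious motifs
are expected alongside the plant, and the search reports them too.

A command-line front end is provided as `exec/pms8`
(`pms8 search | generate | expect | challenging`), e.g.

```sh
Rscript exec/pms8 generate --n 20 --m 200 --l 13 --d 4 --seed 42 --output x.fa --motif-out x.tsv
Rscript exec/pms8 search --input x.fa --l 13 --d 4
```

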