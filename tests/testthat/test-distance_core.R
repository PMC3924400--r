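test_that("hamming distance matches its definition and is a metric", {
  expect_equal(hamming_distance("ACGT", "ACGT"), 0L)
  expect_equal(hamming_distance("AAAA", "TTTT"), 4L)
  expect_equal(hamming_distance("ACGT", "ACGA"), 1L)
  expect_error(hamming_distance("ACG", "ACGT"), "equal lengths")
  set.seed(1)
  for (i in 1:200) {
    l <- sample(1:12, 1)
    a <- random_lmer(l); b <- random_lmer(l); c <- random_lmer(l)
    expect_equal(hamming_distance(a, b), hamming_distance(b, a))
    expect_equal(hamming_distance(a, a), 0L)
    expect_lte(hamming_distance(a, c),
               hamming_distance(a, b) + hamming_distance(b, c))
  }
})

test_that("consensus total distance is the minimum total distance", {
  expect_equal(consensus_total_distance(c("AC", "AC", "AC")), 0L)
  # for two strings it equals their Hamming distance
  expect_equal(consensus_total_distance(c("AA", "CC")), 2L)
  expect_equal(consensus_total_distance(c("AAA", "AAC", "ACC")), 2L)
  # exhaustive: no string achieves a smaller total distance, and the
  # columnwise-majority string achieves exactly the consensus value
  set.seed(2)
  for (rep in 1:20) {
    l <- sample(2:4, 1)
    k <- sample(2:4, 1)
    T <- vapply(seq_len(k), function(i) random_lmer(l), character(1))
    cd <- consensus_total_distance(T, dna_alphabet())
    totals <- vapply(all_lmers(l), function(M)
      sum(vapply(T, hamming_distance, integer(1), u = M)), numeric(1))
    expect_equal(cd, min(totals))
    cons <- consensus_string(T, dna_alphabet())
    expect_equal(sum(vapply(T, hamming_distance, integer(1), u = cons)), cd)
  }
  expect_error(consensus_total_distance(c("AA", "AAA")), "equal lengths")
})

test_that("packed window distances agree exactly with character-wise ones", {
  set.seed(3)
  inst <- random_instance(20, 60)
  tab <- pack_all_lmers(inst, 13)
  expect_equal(tab$chunk_width, 8L)  # DNA: 8 symbols per 16-bit chunk
  for (i in 1:1000) {
    a <- c(sample(20, 1), sample(60 - 13 + 1, 1))
    b <- c(sample(20, 1), sample(60 - 13 + 1, 1))
    expect_equal(
      packed_distance(tab, a, b),
      hamming_distance(substr(inst$sequences[[a[1]]], a[2], a[2] + 12),
                       substr(inst$sequences[[b[1]]], b[2], b[2] + 12)))
  }
  # single-window edge case and round trip through the code table
  one <- motif_instance("ACGT")
  t1 <- pack_all_lmers(one, 4)
  expect_equal(packed_distance(t1, c(1, 1), c(1, 1)), 0L)
  expect_error(packed_distance(t1, c(1, 2), c(1, 1)), "out of range")
  # protein alphabet packs fewer symbols per chunk but stays exact
  prot <- motif_instance(c("ACDEFGHIKL", "MNPQRSTVWY"), protein_alphabet())
  tp <- pack_all_lmers(prot, 7)
  expect_lt(tp$chunk_width, 8L)
  expect_equal(packed_distance(tp, c(1, 1), c(2, 1)),
               hamming_distance("ACDEFGH", "MNPQRST"))
})

test_that("pair-compatibility flags agree with direct evaluation", {
  set.seed(4)
  inst <- random_instance(5, 20)
  l <- 6
  flags <- precompute_pair_flags(inst, l, 4)
  wm <- flags$window_map
  for (a in seq_len(nrow(wm))) {
    for (b in seq_len(nrow(wm))) {
      if (wm$seq_index[a] == wm$seq_index[b]) {
        expect_true(is.na(flags$flags[a, b]))
      } else {
        da <- hamming_distance(
          substr(inst$sequences[[wm$seq_index[a]]], wm$start[a], wm$start[a] + l - 1),
          substr(inst$sequences[[wm$seq_index[b]]], wm$start[b], wm$start[b] + l - 1))
        expect_equal(flags$flags[a, b], da <= 4)
      }
    }
  }
  expect_identical(flags$flags, t(flags$flags))
  # threshold l keeps every cross-sequence pair; threshold 0 only identical windows
  all_true <- precompute_pair_flags(inst, l, l)$flags
  expect_true(all(all_true[!is.na(all_true)]))
})
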