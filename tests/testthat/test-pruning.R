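test_that("pair condition is exact for two l-mers", {
  expect_true(pair_condition("AAAA", "TTTT", 2, 2))
  expect_false(pair_condition("AAAA", "TTTT", 1, 1))
  expect_true(pair_condition("ACGT", "ACGT", 0, 0))
  # exactness against the exhaustive oracle on random pairs
  set.seed(5)
  for (i in 1:50) {
    l <- sample(2:5, 1)
    a <- random_lmer(l); b <- random_lmer(l)
    da <- sample(0:l, 1); db <- sample(0:l, 1)
    expect_equal(pair_condition(a, b, da, db),
                 exists_common_neighbor_exhaustive(c(a, b), c(da, db),
                                                   alphabet = "dna"))
  }
})

test_that("column types classify 3-tuples per definition", {
  expect_equal(unname(column_type_counts("AAAA", "AACA", "AAAC")),
               c(2L, 0L, 1L, 1L, 0L))
  expect_equal(unname(column_type_counts("ACG", "ACG", "ACG")),
               c(3L, 0L, 0L, 0L, 0L))
  expect_equal(unname(column_type_counts("A", "C", "G")),
               c(0L, 0L, 0L, 0L, 1L))
  # counts always sum to l; binary alphabets admit no all-distinct column
  set.seed(6)
  bin <- make_alphabet(c("0", "1"))
  for (i in 1:20) {
    l <- sample(1:8, 1)
    tri <- vapply(1:3, function(j) random_lmer(l, bin), character(1))
    ct <- column_type_counts(tri[1], tri[2], tri[3])
    expect_equal(sum(ct), l)
    expect_equal(unname(ct["n4"]), 0L)
  }
})

test_that("triple condition equals exhaustive common-neighbor existence", {
  expect_false(triple_condition("AA", "CC", "GG", c(1, 1, 1)))
  expect_true(triple_condition("AAAA", "AACC", "CCAA", c(2, 2, 2)))
  expect_true(triple_condition("ACGT", "ACGT", "ACGT", c(0, 0, 0)))
  set.seed(7)
  for (i in 1:200) {
    l <- sample(2:5, 1)
    tri <- vapply(1:3, function(j) random_lmer(l), character(1))
    bud <- sample(0:l, 3, replace = TRUE)
    expect_equal(triple_condition(tri[1], tri[2], tri[3], bud),
                 exists_common_neighbor_exhaustive(tri, bud, alphabet = "dna"),
                 info = paste(c(tri, bud), collapse = " "))
  }
})

test_that("constructed witnesses meet every budget exactly when one exists", {
  expect_null(construct_common_neighbor("AA", "CC", "GG", c(1, 1, 1)))
  expect_equal(construct_common_neighbor("ACGT", "ACGT", "ACGT", c(0, 0, 0)),
               "ACGT")
  w <- construct_common_neighbor("AAAA", "CCAA", "CCAA", c(2, 2, 2))
  expect_lte(hamming_distance(w, "AAAA"), 2)
  expect_lte(hamming_distance(w, "CCAA"), 2)
  set.seed(8)
  for (i in 1:300) {
    l <- sample(2:7, 1)
    tri <- vapply(1:3, function(j) random_lmer(l), character(1))
    bud <- sample(0:l, 3, replace = TRUE)
    w <- construct_common_neighbor(tri[1], tri[2], tri[3], bud)
    if (triple_condition(tri[1], tri[2], tri[3], bud)) {
      expect_false(is.null(w))
      for (j in 1:3) expect_lte(hamming_distance(w, tri[j]), bud[j])
    } else {
      expect_null(w)
    }
  }
})

test_that("conditions are monotone in the budgets", {
  set.seed(9)
  for (i in 1:100) {
    l <- sample(2:6, 1)
    tri <- vapply(1:3, function(j) random_lmer(l), character(1))
    bud <- sample(0:(l - 1), 3, replace = TRUE)
    if (triple_condition(tri[1], tri[2], tri[3], bud)) {
      for (j in 1:3) {
        bigger <- bud
        bigger[j] <- bigger[j] + 1L
        expect_true(triple_condition(tri[1], tri[2], tri[3], bigger))
      }
    }
    if (pair_condition(tri[1], tri[2], bud[1], bud[2])) {
      expect_true(pair_condition(tri[1], tri[2], bud[1] + 1L, bud[2]))
    }
  }
})

test_that("tuple necessary condition never rules out a real neighbor", {
  expect_true(tuple_necessary_condition(rep("ACGT", 4), rep(0, 4)))
  expect_false(tuple_necessary_condition(c("AA", "CC", "GG", "TT"),
                                         c(1, 1, 1, 1)))
  expect_true(tuple_necessary_condition(c("AAAA", "TTTT", "CCCC"),
                                        c(4, 4, 4)))
  # soundness: whenever the bound says no, exhaustive search agrees
  set.seed(10)
  for (i in 1:100) {
    l <- sample(2:4, 1)
    k <- sample(2:5, 1)
    T <- vapply(seq_len(k), function(j) random_lmer(l), character(1))
    bud <- sample(0:2, k, replace = TRUE)
    if (!tuple_necessary_condition(T, bud)) {
      expect_false(exists_common_neighbor_exhaustive(T, bud, alphabet = "dna"))
    }
  }
})
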