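test_that("search equals the brute-force reference on random instances", {
  set.seed(13)
  for (i in 1:12) {
    alpha <- if (i %% 2) dna_alphabet() else toy5_alphabet()
    n <- sample(2:8, 1); l <- sample(4:7, 1)
    m <- sample(seq(l + 5, 50), 1); d <- sample(0:2, 1)
    inst <- random_instance(n, m, alpha)
    expect_identical(pms8_search(inst, l, d)$motifs,
                     brute_force_search(inst, l, d)$motifs,
                     info = sprintf("n=%d m=%d l=%d d=%d %s", n, m, l, d,
                                    alpha$name))
  }
})

test_that("a single-sequence search is the window-neighborhood union", {
  inst <- motif_instance("ACGT")
  res <- pms8_search(inst, 4, 1)
  expect_identical(res$motifs, sort(generate_common_neighborhood("ACGT", 1)))
  expect_length(res$motifs, 13L)
})

test_that("the planted motif is always recovered", {
  for (seed in 1:3) {
    gp <- generate_planted_instance(8, 60, 9, 2, seed = seed)
    res <- pms8_search(gp$instance, 9, 2)
    expect_true(gp$plant$motif %in% res$motifs)
  }
})

test_that("witness positions point at windows within distance d", {
  gp <- generate_planted_instance(6, 40, 7, 2, seed = 21)
  res <- pms8_search(gp$instance, 7, 2, positions = TRUE)
  expect_equal(dim(res$positions), c(length(res$motifs), 6L))
  for (r in seq_along(res$motifs)) {
    for (i in 1:6) {
      p <- res$positions[r, i]
      win <- substr(gp$instance$sequences[[i]], p, p + 6L)
      expect_lte(hamming_distance(win, res$motifs[r]), 2L)
    }
  }
})

test_that("invalid search shapes error out", {
  inst <- motif_instance(c("ACGTACGT", "ACG"))
  expect_error(pms8_search(inst, 5, 1), "at least l long")
  expect_error(pms8_search(motif_instance("ACGTACGT"), 5, 6), "d must not exceed l")
})

test_that("d = 0 degenerates to exact common-substring search", {
  inst <- motif_instance(c("AACGTT", "TTACGA", "GACGTC"))
  res <- pms8_search(inst, 3, 0)
  expect_identical(res$motifs, brute_force_search(inst, 3, 0)$motifs)
  expect_true("ACG" %in% res$motifs)
})

test_that("threshold heuristic is clamped and monotone as designed", {
  # values below 2 are clamped up
  expect_equal(choose_threshold_t(1e6, 0, 4), 2L)
  # grows with d, shrinks with m, grows with sigma
  for (d in 0:6) {
    expect_gte(choose_threshold_t(600, d + 1, 4), choose_threshold_t(600, d, 4))
  }
  for (m in c(100, 200, 400, 800)) {
    expect_lte(choose_threshold_t(2 * m, 5, 4), choose_threshold_t(m, 5, 4))
  }
  expect_gte(choose_threshold_t(600, 4, 20), choose_threshold_t(600, 4, 4))
})

test_that("subset-size heuristic follows the stated convention", {
  # floor(2 + 20/4 - ln 2) = 6
  expect_equal(choose_n_prime(20, 2), 6L)
  # t >= n clamps to n
  expect_equal(choose_n_prime(3, 5), 3L)
  expect_equal(choose_n_prime(4, 4), 4L)
})

test_that("verify_motif agrees with a direct scan and honors from_row", {
  set.seed(14)
  inst <- random_instance(5, 30)
  l <- 6; d <- 1
  scan <- function(M, from) {
    all(vapply(from:5, function(i) {
      s <- inst$sequences[[i]]
      any(vapply(seq_len(nchar(s) - l + 1), function(off)
        hamming_distance(substr(s, off, off + l - 1), M) <= d, logical(1)))
    }, logical(1)))
  }
  for (i in 1:40) {
    M <- random_lmer(l)
    expect_equal(verify_motif(M, inst, d), scan(M, 1))
    expect_equal(verify_motif(M, inst, d, from_row = 3), scan(M, 3))
  }
})

test_that("row filtering keeps exactly the compatible candidates", {
  d <- 1
  x <- "AAAAAA"
  row <- c("AAAAAA", "AAATTT", "TTTTTT", "AACAAA")
  # pair bound at 2d removes distance-3+ candidates
  kept <- filter_row(row, x, character(0), d)
  expect_identical(kept, c("AAAAAA", "AACAAA"))
  # an exact copy of a stack member always survives
  expect_true(x %in% filter_row(row, x, c("AAAAAC"), d))
  # the triple test drops a candidate that passes the pair bound but has no
  # common neighbor with the stack: pairwise distances are all 2 = 2d, yet
  # two all-distinct columns give consensus distance 4 > 3d
  kept2 <- filter_row(c("GGAA", "AAAA"), "AAAA", c("CCAA"), d)
  expect_identical(kept2, "AAAA")
})

test_that("row ordering by size is stable", {
  expect_equal(sort_rows_by_size(c(5, 2, 9)), c(2L, 1L, 3L))
  expect_equal(sort_rows_by_size(c(3, 3, 3)), c(1L, 2L, 3L))
  expect_equal(sort_rows_by_size(c(4, 1, 4, 1)), c(2L, 4L, 1L, 3L))
})

test_that("search statistics are reported", {
  gp <- generate_planted_instance(5, 30, 6, 1, seed = 2)
  res <- pms8_search(gp$instance, 6, 1)
  expect_gt(res$stats$tuples_explored, 0)
  expect_gte(res$stats$neighborhoods_generated, 1)
  expect_gte(res$stats$candidates_verified, length(res$motifs))
})
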