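test_that("alphabets validate their symbols and expose stable codes", {
  dna <- dna_alphabet()
  expect_equal(dna$size, 4L)
  expect_equal(dna$symbols, c("A", "C", "G", "T"))
  expect_equal(protein_alphabet()$size, 20L)
  expect_error(make_alphabet(c("A", "A")), "distinct")
  expect_error(make_alphabet("A"), "at least 2")
  expect_equal(as_alphabet("custom:acgtu")$symbols, c("A", "C", "G", "T", "U"))
  expect_error(as_alphabet("rna"), "unknown alphabet")
})

test_that("instances validate sequences against the alphabet", {
  inst <- motif_instance(c("ACGT", "GGCC"))
  expect_equal(inst$n, 2L)
  expect_equal(inst$lengths, c(4L, 4L))
  expect_equal(unname(inst$sequences[1L]), "ACGT")
  # case normalization
  expect_equal(unname(motif_instance("acgt")$sequences), "ACGT")
  # position of the offending character is reported
  expect_error(motif_instance("ACGN"), "position 4")
  # ragged lengths are accepted
  expect_equal(motif_instance(c("ACGTA", "ACG"))$lengths, c(5L, 3L))
})

test_that("FASTA round trip preserves sequences and order", {
  path <- withr::local_tempfile(fileext = ".fa")
  inst <- motif_instance(c(s1 = "ACGTACGT", s2 = "GGCCGGCC", s3 = "ACG"))
  write_fasta(inst, path)
  back <- read_fasta(path)
  expect_equal(unname(back$sequences), unname(inst$sequences))
  expect_equal(names(back$sequences), names(inst$sequences))
  # lower-case records are upper-cased on read
  writeLines(c(">r1", "acgt"), path)
  expect_equal(unname(read_fasta(path)$sequences), "ACGT")
})

test_that("strict mode rejects and non-strict mode drops bad records", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1", "ACGN", ">r2", "ACGT"), path)
  expect_error(read_fasta(path, strict = TRUE), "record 1.*position 4")
  expect_warning(inst <- read_fasta(path, strict = FALSE), "dropping record 1")
  expect_equal(inst$n, 1L)
  expect_equal(unname(inst$sequences), "ACGT")
  # an empty file is an error, as is writing an empty instance
  writeLines(character(0), path)
  expect_error(read_fasta(path), "no FASTA records")
})

test_that("generated planted instances honor the plant contract", {
  gp <- generate_planted_instance(20, 600, 13, 4, seed = 1)
  inst <- gp$instance
  plant <- gp$plant
  expect_equal(inst$n, 20L)
  expect_true(all(inst$lengths == 600L))
  expect_equal(nchar(plant$motif), 13L)
  for (i in seq_len(20L)) {
    win <- substr(inst$sequences[[i]], plant$positions[i],
                  plant$positions[i] + 12L)
    expect_equal(win, plant$mutated_copies[i])
    expect_lte(hamming_distance(win, plant$motif), 4L)
  }
  # exact mode substitutes exactly d distinct positions
  expect_true(all(plant$distances == 4L))
  # the plant is a motif of its own instance by construction
  expect_true(verify_motif(plant$motif, inst, 4))
})

test_that("d = 0 plants the motif verbatim in every sequence", {
  gp <- generate_planted_instance(3, 10, 5, 0, seed = 7)
  expect_true(all(vapply(gp$instance$sequences, grepl,
                         logical(1), pattern = gp$plant$motif, fixed = TRUE)))
  expect_true(all(gp$plant$distances == 0L))
})

test_that("at_most mode keeps mutation counts within d", {
  gp <- generate_planted_instance(50, 30, 8, 3, seed = 5,
                                  mutation_mode = "at_most")
  expect_true(all(gp$plant$distances <= 3L))
  # with 50 draws uniform on 0..3, not all counts should hit the maximum
  expect_true(any(gp$plant$distances < 3L))
})

test_that("generation is seed-deterministic and leaves the RNG state alone", {
  a <- generate_planted_instance(5, 50, 8, 2, seed = 11)
  b <- generate_planted_instance(5, 50, 8, 2, seed = 11)
  expect_identical(a$instance$sequences, b$instance$sequences)
  expect_identical(a$plant, b$plant)
  c <- generate_planted_instance(5, 50, 8, 2, seed = 12)
  expect_false(identical(a$instance$sequences, c$instance$sequences))
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_planted_instance(3, 20, 5, 1, seed = 99))
  expect_identical(runif(1), before)
})

test_that("plant record sidecar round-trips through the 0-based format", {
  gp <- generate_planted_instance(4, 30, 6, 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plant_record(gp$plant, path)
  lines <- readLines(path)
  expect_equal(lines[1L], gp$plant$motif)
  # offsets on disk are 0-based
  first <- strsplit(lines[2L], "\t")[[1L]]
  expect_equal(as.integer(first[2L]), gp$plant$positions[1L] - 1L)
  back <- read_plant_record(path)
  expect_equal(back$motif, gp$plant$motif)
  expect_equal(back$positions, gp$plant$positions)
  expect_equal(back$mutated_copies, unname(gp$plant$mutated_copies))
})

test_that("generator rejects impossible shapes", {
  expect_error(generate_planted_instance(3, 5, 8, 2), "l must not exceed m")
  expect_error(generate_planted_instance(3, 20, 8, 9), "d must not exceed l")
})
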