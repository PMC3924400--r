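# shared fixtures, built in code

toy5_alphabet <- function() make_alphabet(c("A", "B", "C", "D", "E"), "toy5")

random_instance <- function(n, m, alphabet = dna_alphabet()) {
  syms <- alphabet$symbols
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(syms, m, replace = TRUE), collapse = ""), character(1))
  motif_instance(seqs, alphabet)
}

random_lmer <- function(l, alphabet = dna_alphabet()) {
  paste(sample(alphabet$symbols, l, replace = TRUE), collapse = "")
}

# all sigma^l strings over an alphabet
all_lmers <- function(l, alphabet = dna_alphabet()) {
  out <- ""
  for (i in seq_len(l)) out <- as.vector(outer(out, alphabet$symbols, paste0))
  sort(out)
}
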