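# Shared fixtures. Everything is generated in code; small scales keep the
# suite fast while leaving the screening-scale paths to test-acceptance.R.

test_vocab <- function(n = 10, D = 64, seed = 1L) {
  v <- spa_vocabulary(D, seed = seed)
  for (i in seq_len(n)) add_pointer(v, paste0("X", i))
  v
}

# cached small lexicon shared across test files
small_lexicon <- local({
  lex <- NULL
  function() {
    if (is.null(lex)) {
      lex <<- generate_lexicon(n_entries = 40, n_superordinates = 10,
                               n_syllable_parts = 30, seed = 7L)
    }
    lex
  }
})

# brute-force cleanup, independent of cleanup_oracle's implementation
cleanup_bruteforce <- function(x, vocab, threshold = 0.3) {
  best <- NA_character_
  best_s <- -Inf
  for (nm in vocab_names(vocab)) {
    s <- sum(vocab_get(vocab, nm)$v * x)
    if (s > best_s) {
      best_s <- s
      best <- nm
    }
  }
  if (best_s >= threshold) best else NA_character_
}
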