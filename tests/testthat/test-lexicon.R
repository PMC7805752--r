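test_that("lexicon generation is deterministic and carries the fixtures", {
  lex <- small_lexicon()
  lex2 <- generate_lexicon(n_entries = 40, n_superordinates = 10,
                           n_syllable_parts = 30, seed = 7L)
  expect_identical(lex$entries, lex2$entries)
  expect_equal(vocab_matrix(lex$vocab_concept), vocab_matrix(lex2$vocab_concept))

  expect_equal(nrow(lex$entries), 40)
  fix <- c("C_Teller", "C_Hund", "C_Lampe", "C_Brief", "C_Apfel", "C_Hose",
           "C_Tisch", "C_Wiese", "C_Glas", "C_Baum",
           "C_Gras", "C_Mann", "C_Rad", "C_Schubkarre")
  expect_true(all(fix %in% lex$entries$concept))

  # fixture names and order are stable across seeds
  lex3 <- generate_lexicon(50, 12, 40, seed = 99L)
  expect_identical(utils::head(lex3$entries$concept, 14),
                   utils::head(lex$entries$concept, 14))

  expect_error(generate_lexicon(n_entries = 20), "at least 30")
})

test_that("lexicon structure is internally consistent", {
  lex <- small_lexicon()
  e <- lex$entries
  # 1:1:1 level correspondence by construction of the names
  expect_identical(sub("^C_", "", e$concept), sub("^W_", "", e$lemma))
  expect_identical(sub("^C_", "", e$concept), sub("^P_", "", e$phono))
  expect_true(all(e$category %in% lex$superordinates))
  # every relation endpoint exists
  known <- c(e$concept, lex$superordinates)
  expect_true(all(lex$relations$from %in% known))
  expect_true(all(lex$relations$to %in% known))
  # syllable decomposition draws 1-3 parts from the shared pool
  expect_true(all(lengths(e$syllables) %in% 1:3))
  expect_true(all(unlist(e$syllables) %in% vocab_names(lex$vocab_deep_phono)))
})

test_that("same-category concepts are more similar than cross-category ones", {
  lex <- generate_lexicon(100, 10, 40, D = 64, relatedness_mix = 0.5, seed = 3)
  V <- vocab_matrix(lex$vocab_concept)
  cat <- lex$entries$category
  S <- crossprod(V)
  same <- outer(cat, cat, "==") & upper.tri(S)
  diff <- (!outer(cat, cat, "==")) & upper.tri(S)
  expect_gt(sum(same), 100)
  expect_gte(mean(S[same]) - mean(S[diff]), 0.1)
})

test_that("the repetition word list is the fixed ten-item fixture", {
  lex <- small_lexicon()
  wl <- demtect_wordlist(lex)
  expect_length(wl, 10)
  expect_identical(wl[1], "C_Teller")
  expect_identical(wl[10], "C_Baum")
  expect_false(anyDuplicated(wl) > 0)
  expect_true(all(wl %in% lex$entries$concept))
})

test_that("the naming item set ends every scene with its target", {
  lex <- small_lexicon()
  items <- wwt_item_set(lex)
  expect_equal(nrow(items), 20)
  i_sk <- which(items$target == "C_Schubkarre")
  expect_identical(items$distractors[[i_sk]], c("C_Gras", "C_Mann", "C_Rad"))
  for (i in seq_len(nrow(items))) {
    expect_false(items$target[i] %in% items$distractors[[i]])
    expect_length(items$distractors[[i]], 3)
  }
  expect_identical(wwt_item_set(lex), items)   # deterministic
  expect_error(wwt_item_set(lex, n_items = 1000), "not enough")
})

test_that("level mappings are bijections with a production-side cleanup flag", {
  lex <- small_lexicon()
  maps <- build_level_mappings(lex)
  expect_true(isTRUE(attr(maps$concept_to_lemma, "cleanup")))
  for (m in maps) {
    expect_equal(anyDuplicated(m$input), 0)
    expect_equal(anyDuplicated(m$output), 0)
  }
  # round trip concept -> lemma -> concept is the identity
  c2w <- maps$concept_to_lemma
  w2c <- maps$lemma_to_concept
  back <- w2c$output[match(c2w$output, w2c$input)]
  expect_identical(back, c2w$input)
  # a worked entry maps across all three levels
  expect_identical(c2w$output[c2w$input == "C_Schubkarre"], "W_Schubkarre")
  l2p <- maps$lemma_to_phono
  expect_identical(l2p$output[l2p$input == "W_Schubkarre"], "P_Schubkarre")
})

test_that("lexicon JSON round trip is lossless", {
  lex <- small_lexicon()
  path <- withr::local_tempfile(fileext = ".json")
  write_lexicon_json(lex, path)
  back <- read_lexicon_json(path)
  expect_identical(back$entries$concept, lex$entries$concept)
  expect_identical(back$entries$syllables, lex$entries$syllables)
  expect_equal(back$relations, lex$relations)
  expect_equal(vocab_matrix(back$vocab_concept), vocab_matrix(lex$vocab_concept),
               tolerance = 1e-12)
  expect_identical(vocab_names(back$vocab_deep_phono),
                   vocab_names(lex$vocab_deep_phono))
  expect_equal(back$relatedness_mix, lex$relatedness_mix)
})
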