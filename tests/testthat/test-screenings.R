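# Small-scale end-to-end checks (3-5 items, 40-entry lexicon). The full
# screening-scale behaviour is exercised in test-acceptance.R.

test_that("physiological naming produces every target's phonological form", {
  lex <- small_lexicon()
  items <- wwt_item_set(lex)[1:3, ]
  tr <- run_wwt_naming(lex, items = items, seed = 1)
  expect_s3_class(tr, "screening_trial")
  expect_equal(n_correct(tr), 3)
  expect_identical(tr$produced,
                   lex$entries$phono[match(items$target, lex$entries$concept)])
  expect_true(all(tr$correct))
})

test_that("complete ablation of the production buffer silences naming", {
  lex <- small_lexicon()
  items <- wwt_item_set(lex)[1:2, ]
  tr <- run_wwt_naming(lex, items = items,
                       ablations = c(concept_prod = 1), seed = 1)
  expect_equal(n_correct(tr), 0)
  expect_true(all(is.na(tr$produced)))
  expect_error(
    run_wwt_naming(lex, items = items, ablations = c(nowhere = 0.5), seed = 1),
    "unknown ablation target")
})

test_that("zero-fraction ablation runs are bit-identical to physiological", {
  lex <- small_lexicon()
  items <- wwt_item_set(lex)[1:2, ]
  t0 <- run_wwt_naming(lex, items = items, seed = 5)
  t1 <- run_wwt_naming(lex, items = items,
                       ablations = c(concept_prod = 0, mem = 0), seed = 5)
  strip <- function(x) {
    x <- tibble::as_tibble(x)
    attributes(x) <- attributes(x)[c("names", "row.names", "class")]
    class(x) <- c("tbl_df", "tbl", "data.frame")
    x
  }
  expect_identical(strip(t0), strip(t1))
})

test_that("short word lists are repeated through the memory pathway", {
  lex <- small_lexicon()
  wl <- demtect_wordlist(lex)[1:3]
  tr <- run_demtect_repetition(lex, wordlist = wl, seed = 2)
  expect_equal(nrow(tr), 3)
  expect_gte(n_correct(tr), 2)   # k = 3 is far below capacity
})

test_that("complete memory ablation abolishes recall", {
  lex <- small_lexicon()
  wl <- demtect_wordlist(lex)[1:3]
  tr <- run_demtect_repetition(lex, wordlist = wl,
                               ablations = c(mem = 1), seed = 2)
  expect_equal(n_correct(tr), 0)
})

test_that("repetition credit is unordered and single-use per target", {
  lex <- small_lexicon()
  # synthetic scoring records via the exported scorer: clamp a trajectory
  wl <- demtect_wordlist(lex)[1:2]
  tr <- run_demtect_repetition(lex, wordlist = wl, seed = 3)
  # a word produced twice may only be credited once
  expect_lte(n_correct(tr), length(unique(stats::na.omit(tr$produced))))
})

test_that("score_production applies threshold and minimum hold duration", {
  v <- test_vocab(5)
  a <- vocab_get(v, "X1")$v
  b <- vocab_get(v, "X2")$v
  n <- 100
  X <- matrix(rep(a, each = n), n, 64)       # constant clamped target
  sim <- structure(list(probes = list(out = X),
                        time = seq(0, by = 0.01, length.out = n),
                        dt = 0.01, record_every = 1L),
                   class = "spa_simulation")
  win <- tibble::tibble(item = 1, target = "X1", t_on = 0.1, t_off = 0.9)
  sc <- score_production(sim, "out", v, win)
  expect_true(sc$correct)
  expect_identical(sc$produced, "X1")

  # all-zero trajectory -> null production, incorrect
  sim$probes$out <- matrix(0, n, 64)
  sc0 <- score_production(sim, "out", v, win)
  expect_true(is.na(sc0$produced))
  expect_false(sc0$correct)

  # two pointers alternating faster than min_hold -> null
  X2 <- matrix(0, n, 64)
  X2[seq(1, n, 2), ] <- rep(a, each = length(seq(1, n, 2)))
  X2[seq(2, n, 2), ] <- rep(b, each = length(seq(2, n, 2)))
  sim$probes$out <- X2
  sc2 <- score_production(sim, "out", v, win, min_hold = 0.05)
  expect_true(is.na(sc2$produced))

  # window outside the trajectory errors
  expect_error(
    score_production(sim, "out", v,
                     tibble::tibble(item = 1, target = "X1",
                                    t_on = 0.5, t_off = 2)),
    "beyond")
})

test_that("the realized action sequence follows the screening scripts", {
  lex <- small_lexicon()
  items <- wwt_item_set(lex)[1, ]
  tr <- run_wwt_naming(lex, items = items, seed = 4, keep_sim = TRUE)
  sim <- attr(tr, "sim")
  m <- build_screening_model(lex, screening_config(), seed = derive_seed(4, 1))
  trace <- action_trace(sim, wwt_action_rules(m$vocab_control))
  acts <- rle(trace$action[!is.na(trace$action)])$values
  expect_identical(acts, c("PROCESS_NOMEN", "SPEAK"))

  wl <- demtect_wordlist(lex)[1:2]
  tr2 <- run_demtect_repetition(lex, wordlist = wl, seed = 4, keep_sim = TRUE)
  m2 <- build_screening_model(lex, screening_config(), seed = derive_seed(4, 1))
  trace2 <- action_trace(attr(tr2, "sim"),
                         demtect_action_rules(m2$vocab_control, 2))
  acts2 <- rle(trace2$action[!is.na(trace2$action)])$values
  expect_identical(acts2, c("KEEP", "RECALL"))
})

test_that("trials serialize to JSON lines", {
  lex <- small_lexicon()
  items <- wwt_item_set(lex)[1, ]
  tr <- run_wwt_naming(lex, items = items,
                       ablations = c(concept_prod = 0.5), seed = 1)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trials_jsonl(list(tr, tr), path)
  lines <- readLines(path)
  expect_length(lines, 2)
  obj <- jsonlite::fromJSON(lines[1])
  expect_identical(obj$task, "wwt")
  expect_equal(obj$ablations$fraction, 0.5)
  expect_equal(nrow(obj$items), 1)
})
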