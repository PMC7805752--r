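test_that("pointers are unit norm, deterministic and unique-named", {
  v <- spa_vocabulary(64, seed = 3)
  a <- add_pointer(v, "A")
  expect_equal(sqrt(sum(a$v^2)), 1, tolerance = 1e-6)
  expect_error(add_pointer(v, "A"), "already exists")

  # same seed, same insertion order -> bit-identical vectors
  v2 <- spa_vocabulary(64, seed = 3)
  a2 <- add_pointer(v2, "A")
  expect_identical(a$v, a2$v)

  # independently generated entries are nearly orthogonal on average
  big <- test_vocab(n = 120, seed = 5)
  V <- vocab_matrix(big)
  S <- abs(crossprod(V))
  diag(S) <- NA
  expect_lt(mean(S, na.rm = TRUE), 3 / sqrt(64))
  # |similarity| < 0.5 for a random pair (sd of the dot product is 1/8)
  expect_lt(abs(vsa_similarity(V[, 1], V[, 2])), 0.5)
})

test_that("binding is circular convolution with exact algebraic identities", {
  # hand-computed circular convolution at D = 4
  expect_equal(vsa_bind(c(1, 0, 0, 0.5), c(0, 1, 0, 0)), c(0.5, 1, 0, 0))

  v <- test_vocab(2)
  a <- vocab_get(v, "X1")$v
  b <- vocab_get(v, "X2")$v
  e0 <- c(1, rep(0, 63))
  expect_equal(vsa_bind(a, e0), a, tolerance = 1e-12)       # identity element
  expect_equal(vsa_bind(a, b), vsa_bind(b, a), tolerance = 1e-12)
  # distributivity over superposition (binding is linear)
  expect_equal(vsa_bind(a, b + e0), vsa_bind(a, b) + vsa_bind(a, e0),
               tolerance = 1e-12)
  expect_error(vsa_bind(a, c(1, 2)), "dimension")
})

test_that("inverse is an involution and approximately inverts binding", {
  v <- test_vocab(1)
  a <- vocab_get(v, "X1")$v
  expect_identical(vsa_inverse(vsa_inverse(a)), a)
  e0 <- c(1, rep(0, 63))
  expect_identical(vsa_inverse(e0), e0)

  # Monte-Carlo: bind(a, inverse(a)) points towards the identity element
  set.seed(42)
  sims <- replicate(200, {
    x <- rnorm(64); x <- x / sqrt(sum(x^2))
    vsa_similarity(vsa_bind(x, vsa_inverse(x)), e0)
  })
  expect_gt(median(sims), 0.5)
})

test_that("unbinding recovers the bound item above distractor level", {
  set.seed(11)
  v <- test_vocab(100, seed = 9)
  V <- vocab_matrix(v)
  wins <- replicate(100, {
    ij <- sample(100, 2)
    a <- V[, ij[1]]; b <- V[, ij[2]]
    rec <- vsa_unbind(vsa_bind(a, b), b)
    s <- drop(crossprod(V, rec))
    sim_target <- s[ij[1]]
    sim_best_distractor <- max(s[-ij[1]])
    c(sim_target, sim_target > sim_best_distractor)
  })
  expect_gt(median(wins[1, ]), 0.6)
  expect_gte(mean(wins[2, ]), 0.95)

  # exact recovery with a unitary binding partner
  u <- add_unitary_pointer(v, "U")
  a <- V[, 1]
  expect_equal(vsa_unbind(vsa_bind(a, u$v), u$v), a, tolerance = 1e-6)
  expect_equal(vsa_unbind(rep(0, 64), u$v), rep(0, 64))
})

test_that("unitary pointers have flat spectra and preserve norms", {
  v <- spa_vocabulary(64, seed = 21)
  p <- add_unitary_pointer(v, "P")
  expect_equal(max(abs(Mod(fft(p$v)) - 1)), 0, tolerance = 1e-9)
  a <- add_pointer(v, "A")
  expect_equal(sqrt(sum(vsa_bind(a$v, p$v)^2)), 1, tolerance = 1e-6)
})

test_that("superposition sums, optionally normalizes, and rejects bad input", {
  v <- test_vocab(2)
  a <- vocab_get(v, "X1")$v
  expect_equal(vsa_superpose(list(a), normalize = TRUE), a, tolerance = 1e-9)
  # orthogonal unit vectors: normalized superposition has sim 1/sqrt(2)
  e1 <- c(1, rep(0, 63)); e2 <- c(0, 1, rep(0, 62))
  s <- vsa_superpose(list(e1, e2), normalize = TRUE)
  expect_equal(vsa_similarity(s, e1), 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(vsa_superpose(list(rep(0, 4), rep(0, 4)), normalize = TRUE),
               rep(0, 4))
  expect_error(vsa_superpose(list()), "nonempty")
})

test_that("similarity is the symmetric dot product", {
  v <- test_vocab(2)
  a <- vocab_get(v, "X1")$v; b <- vocab_get(v, "X2")$v
  expect_equal(vsa_similarity(a, a), 1, tolerance = 1e-9)
  expect_equal(vsa_similarity(a, -a), -1, tolerance = 1e-9)
  expect_equal(vsa_similarity(a, b), vsa_similarity(b, a))
})

test_that("cleanup oracle equals brute-force argmax on every input", {
  set.seed(5)
  v <- test_vocab(50, seed = 13)
  for (i in 1:30) {
    x <- rnorm(64) * runif(1, 0.1, 2)
    expect_identical(cleanup_oracle(x, v, 0.3), cleanup_bruteforce(x, v, 0.3))
  }
  a <- vocab_get(v, "X3")$v
  expect_identical(cleanup_oracle(a, v, threshold = 1), "X3")
  expect_identical(cleanup_oracle(rep(0, 64), v), NA_character_)

  # noisy target is still recovered at threshold 0.3
  set.seed(6)
  hit <- replicate(200, {
    noise <- rnorm(64); noise <- noise / sqrt(sum(noise^2))
    identical(cleanup_oracle(0.8 * a + 0.3 * noise, v, 0.3), "X3")
  })
  expect_gt(mean(hit), 0.99)
  expect_error(cleanup_oracle(a, spa_vocabulary(64), 0.3), "empty")
})

test_that("related pointers mix base direction with fresh noise", {
  v <- spa_vocabulary(64, seed = 31)
  base <- add_pointer(v, "base")
  dup <- add_related_pointer(v, "dup", "base", mix = 1)
  expect_equal(vsa_similarity(dup$v, base$v), 1, tolerance = 1e-9)
  sims0 <- sapply(1:20, function(i) {
    p <- add_related_pointer(v, paste0("u", i), "base", mix = 0)
    vsa_similarity(p$v, base$v)
  })
  expect_lt(max(abs(sims0)), 0.5)
  sims5 <- sapply(1:20, function(i) {
    p <- add_related_pointer(v, paste0("h", i), "base", mix = 0.5)
    vsa_similarity(p$v, base$v)
  })
  expect_gt(median(sims5), 0.5)
  expect_lt(median(sims5), 0.9)
  expect_error(add_related_pointer(v, "bad", "base", mix = 1.5), "mix")
})

test_that("positional memory capacity declines with list length", {
  set.seed(3)
  acc_at <- function(k, trials = 12) {
    hits <- 0
    for (tr in seq_len(trials)) {
      v <- test_vocab(60, seed = 100 + tr)
      pv <- spa_vocabulary(64, seed = 200 + tr)
      for (i in seq_len(k)) add_unitary_pointer(pv, paste0("P", i))
      items <- sample(60, k)
      s <- Reduce(`+`, lapply(seq_len(k), function(i) {
        vsa_bind(vocab_get(pv, paste0("P", i))$v,
                 vocab_matrix(v)[, items[i]])
      }))
      s <- s / sqrt(sum(s^2))
      for (i in seq_len(k)) {
        rec <- vsa_unbind(s, vocab_get(pv, paste0("P", i))$v)
        if (identical(cleanup_oracle(rec, v, 0.01), paste0("X", items[i]))) {
          hits <- hits + 1
        }
      }
    }
    hits / (trials * k)
  }
  acc <- sapply(c(2, 4, 7, 10), acc_at)
  # non-increasing in expectation (small slack for Monte-Carlo noise)
  expect_true(all(diff(acc) < 0.05))
  expect_gt(acc[1], acc[4])
})

test_that("vocabulary JSON round trip preserves vectors at full precision", {
  v <- spa_vocabulary(64, seed = 17)
  add_pointer(v, "A")
  add_unitary_pointer(v, "P")
  add_related_pointer(v, "R", "A", 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_vocab_json(v, path)
  v2 <- read_vocab_json(path)
  expect_identical(vocab_names(v2), vocab_names(v))
  expect_equal(vocab_matrix(v2), vocab_matrix(v), tolerance = 1e-12)
  expect_identical(v2$unitary, v$unitary)
})
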