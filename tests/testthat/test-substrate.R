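test_that("buffers have 64 x 50 neurons and decode held inputs accurately", {
  v <- test_vocab(5)
  buf <- build_buffer("b", v, seed = 2)
  expect_equal(length(buf$alive), 64 * 50)
  expect_identical(build_buffer("b", v, seed = 2)$gain, buf$gain)

  a <- vocab_get(v, "X1")$v
  tr <- simulate_buffer(buf, a, duration = 0.3, mode = "rate")
  y <- tr[nrow(tr), ]
  expect_gt(vsa_similarity(y / sqrt(sum(y^2)), a), 0.9)
  # per-component accuracy for a held unit-norm input
  expect_lt(sqrt(mean((y - a)^2)), 0.1)
})

test_that("rate and spiking modes agree at steady state", {
  v <- test_vocab(2)
  buf <- build_buffer("b", v, seed = 6)
  a <- vocab_get(v, "X1")$v
  yr <- simulate_buffer(buf, a, duration = 0.4, mode = "rate")
  ys <- simulate_buffer(buf, a, duration = 0.4, mode = "spiking")
  y1 <- yr[nrow(yr), ]
  y2 <- colMeans(ys[201:400, ])   # spiking averaged over the last 200 ms
  cos <- sum(y1 * y2) / sqrt(sum(y1^2) * sum(y2^2))
  expect_gt(cos, 0.95)
  expect_lt(abs(sqrt(sum(y2^2)) - sqrt(sum(y1^2))), 0.2)
})

test_that("tabulated rate responses match exact per-neuron evaluation", {
  v <- test_vocab(3)
  buf <- ablate(build_buffer("b", v, seed = 9), 0.3, seed = 1)
  ct <- spascreen:::compile_tables(buf)
  u <- vocab_get(v, "X2")$v
  exact <- buffer_decode(buf, u)
  interp_one <- function(j, x) {
    approx(ct$grid, ct$table[j, ], xout = x, rule = 2)$y
  }
  tabbed <- vapply(seq_len(buf$D), function(j) interp_one(j, u[j]), numeric(1))
  # bound set by the table resolution (129 nodes over 1.5x the radius)
  expect_lt(max(abs(tabbed - exact)), 5e-3)
})

test_that("connections propagate pointers through synapses", {
  v <- test_vocab(3)
  net <- spa_network(dt = 0.001)
  net <- net_add(net, build_buffer("a", v, seed = 1))
  net <- net_add(net, build_buffer("b", v, seed = 2))
  net <- net_add(net, build_buffer("c", v, seed = 3))
  net <- net_connect(net, "a", "b")
  net <- net_connect(net, "b", "c", transform = matrix(0, 64, 64))
  inp <- tibble::tibble(component = "a", pointer = "X1", t_on = 0, t_off = 0.4)
  sim <- run_network(net, 0.4, inputs = inp, probes = c("a", "b", "c"))
  x1 <- vocab_get(v, "X1")$v
  yb <- sim$probes$b[nrow(sim$probes$b), ]
  expect_gt(vsa_similarity(yb / sqrt(sum(yb^2)), x1), 0.85)
  # zero transform: downstream stays silent
  expect_lt(sqrt(sum(sim$probes$c[nrow(sim$probes$c), ]^2)), 0.1)
})

test_that("chained identity connections preserve pointer identity", {
  v <- test_vocab(8)
  net <- spa_network(dt = 0.001)
  for (nm in c("a", "b", "c")) net <- net_add(net, build_buffer(nm, v, seed = match(nm, letters)))
  net <- net_connect(net, "a", "b")
  net <- net_connect(net, "b", "c")
  inp <- tibble::tibble(component = "a", pointer = "X5", t_on = 0, t_off = 0.5)
  sim <- run_network(net, 0.5, inputs = inp, probes = "c")
  expect_identical(cleanup_oracle(sim$probes$c[nrow(sim$probes$c), ], v), "X5")
})

test_that("associative memories map, threshold, and win-take-all", {
  vin <- test_vocab(40, seed = 3)
  vout <- test_vocab(40, seed = 4)
  map <- tibble::tibble(input = paste0("X", 1:40), output = paste0("X", 1:40))
  am <- build_assoc_memory(map, vin, vout, winner_take_all = TRUE, seed = 5)
  expect_equal(length(am$alive), 2 * 64 * 50)

  # noiseless mapped input -> mapped output with similarity > 0.8
  r <- am_response(am, vocab_get(vin, "X7")$v)
  expect_gt(vsa_similarity(r$output, vocab_get(vout, "X7")$v), 0.8)

  # random non-mapped input -> output norm < 0.2
  set.seed(8)
  x <- rnorm(64); x <- x / sqrt(sum(x^2))
  r0 <- am_response(am, x)
  expect_lt(sqrt(sum(r0$output^2)), 0.2)

  # two competing mapped inputs: exactly one detector stays active
  mix <- 0.6 * vocab_get(vin, "X3")$v + 0.55 * vocab_get(vin, "X9")$v
  rw <- am_response(am, mix)
  expect_equal(sum(rw$activities > 0.1), 1)
  expect_equal(which.max(rw$activities),
               match(cleanup_oracle(mix, vin, 0.1), paste0("X", 1:40)))

  expect_error(build_assoc_memory(
    tibble::tibble(input = "nope", output = "X1"), vin, vout), "nope")
})

test_that("neural winner-take-all cleanup matches the mathematical argmax", {
  vin <- test_vocab(50, seed = 23)
  map <- tibble::tibble(input = paste0("X", 1:50), output = paste0("X", 1:50))
  am <- build_assoc_memory(map, vin, vin, winner_take_all = TRUE, seed = 6)
  agree <- 0
  for (i in 1:100) {
    # noiseless mapped pointers (two passes over the vocabulary)
    nm <- paste0("X", ((i - 1) %% 50) + 1)
    r <- am_response(am, vocab_get(vin, nm)$v)
    winner <- am$mapping$output[which.max(r$activities)]
    if (identical(winner, cleanup_oracle(vocab_get(vin, nm)$v, vin, 0.1))) {
      agree <- agree + 1
    }
  }
  expect_gte(agree, 98)
})

test_that("gated memory stores, holds, recalls and resets", {
  v <- test_vocab(30, seed = 7)
  pv <- spa_vocabulary(64, seed = 8)
  add_unitary_pointer(pv, "P1"); add_unitary_pointer(pv, "P2")
  net <- spa_network(dt = 0.001)
  net <- net_add(net, build_buffer("cin", v, seed = 1))
  net <- net_add(net, build_buffer("position", pv, seed = 2))
  net <- net_add(net, build_buffer("bind", v, seed = 3))
  net <- net_add(net, build_buffer("unbind", v, seed = 4))
  net <- net_add(net, build_gated_memory("mem", v, seed = 5, feedback_gain = 0.99))
  net <- net_connect(net, "cin", "bind", type = "bind", src2 = "position")
  net <- net_connect(net, "bind", "mem", gain = 0.45 * 0.1 / (0.3 * 0.85),
                     gate = "g_store", gate_default = 0)
  net <- net_connect(net, "mem", "unbind", type = "unbind", src2 = "position",
                     gain = 1.4, gate = "g_recall", gate_default = 0)
  inp <- tibble::tibble(
    component = c("cin", "position", "cin", "position", "position", "position"),
    pointer   = c("X1",  "P1",       "X2",  "P2",       "P1",       "P2"),
    t_on      = c(0.05,  0.05,       0.45,  0.45,       3.0,        3.4),
    t_off     = c(0.35,  0.35,       0.75,  0.75,       3.4,        3.8))
  gates <- tibble::tibble(
    gate  = c("g_store", "g_store", "g_recall", "hold_mem", "act_mem"),
    t_on  = c(0.1, 0.5, 3.0, 3.9, 3.9),
    t_off = c(0.4, 0.8, 3.8, 4.2, 4.2),
    value = c(1, 1, 1, 0, 0))
  sim <- run_network(net, 4.2, inputs = inp, gate_events = gates,
                     probes = c("mem", "unbind"))
  nrm <- sqrt(rowSums(sim$probes$mem^2))
  # drift with the gate closed: < 10% change from 0.8 s to 2.8 s
  expect_lt(abs(nrm[2800] - nrm[800]) / nrm[800], 0.10)
  # recall both items (stored 2+ seconds earlier) via unbinding + cleanup
  u1 <- sim$probes$unbind[3350, ]
  u2 <- sim$probes$unbind[3750, ]
  expect_identical(cleanup_oracle(u1, v), "X1")
  expect_identical(cleanup_oracle(u2, v), "X2")
  # reset: opening the hold gate drives the norm below 0.05 within 200 ms
  expect_lt(nrm[4100], 0.05)
  expect_error(build_gated_memory("m", v, feedback_gain = 2), "feedback_gain")
})

test_that("ablation silences the requested fraction deterministically", {
  v <- test_vocab(4)
  buf <- build_buffer("b", v, seed = 3)
  b50 <- ablate(buf, 0.5, seed = 11)
  expect_equal(sum(!b50$alive), 1600)
  expect_identical(ablate(buf, 0.5, seed = 11)$alive, b50$alive)
  expect_identical(ablate(b50, 0.5, seed = 11)$alive, b50$alive)  # idempotent
  expect_false(identical(ablate(buf, 0.5, seed = 12)$alive, b50$alive))

  # fraction 0 restores the intact component; fraction 1 silences everything
  expect_true(all(ablate(b50, 0, seed = 1)$alive))
  b100 <- ablate(buf, 1, seed = 1)
  expect_equal(max(abs(buffer_decode(b100, vocab_get(v, "X1")$v))), 0)
  expect_error(ablate(buf, 1.2, seed = 1), "fraction")

  am <- build_assoc_memory(
    tibble::tibble(input = paste0("X", 1:4), output = paste0("X", 1:4)),
    v, v, seed = 2)
  am30 <- ablate(am, 0.3, seed = 5)
  expect_equal(sum(!am30$alive), round(0.3 * length(am$alive)))
})

test_that("decoded output norm is statistically non-increasing in ablation", {
  v <- test_vocab(3)
  a <- vocab_get(v, "X1")$v
  fractions <- c(0, 0.25, 0.5, 0.75, 1)
  mean_norms <- sapply(fractions, function(f) {
    mean(sapply(1:10, function(s) {
      buf <- ablate(build_buffer("b", v, seed = s), f, seed = 100 + s)
      sqrt(sum(buffer_decode(buf, a)^2))
    }))
  })
  expect_true(all(diff(mean_norms) <= 0))
})

test_that("similarity trajectories follow the normalized-state convention", {
  v <- test_vocab(6)
  net <- spa_network(dt = 0.001)
  net <- net_add(net, build_buffer("b", v, seed = 4))
  inp <- tibble::tibble(component = "b", pointer = "X2", t_on = 0, t_off = 0.3)
  sim <- run_network(net, 0.3, inputs = inp, probes = "b")
  sims <- decode_similarities(sim, "b", v)
  late <- sims[sims$time > 0.2, ]
  expect_gt(min(late$X2), 0.95)
  expect_lt(max(abs(late$X4)), 0.5)

  # silenced buffer: zero state gives all-zero similarity rows (no division)
  net2 <- net_set_component(net, ablate(net$components$b, 1, seed = 1))
  sim2 <- run_network(net2, 0.1, inputs = inp, probes = "b")
  sims2 <- decode_similarities(sim2, "b", v)
  expect_equal(max(abs(as.matrix(sims2[, -1]))), 0)

  # TSV export round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(sims, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(sims))
  expect_equal(back$X2, sims$X2, tolerance = 1e-6)
})

test_that("network summary reports components and alive fractions", {
  v <- test_vocab(2)
  net <- spa_network()
  net <- net_add(net, build_buffer("b", v, seed = 1))
  net <- net_add(net, ablate(build_buffer("c", v, seed = 2), 0.25, seed = 3))
  s <- network_summary(net)
  expect_equal(nrow(s), 2)
  expect_equal(s$alive_fraction[s$label == "c"], 0.75)
  path <- withr::local_tempfile(fileext = ".json")
  write_architecture_json(net, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$neurons, s$neurons)
})
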