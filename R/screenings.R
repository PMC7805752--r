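#' Screening model configuration
#'
#' Free parameters of the screening simulations. These are calibrated once on
#' the physiological (unablated) runs and then frozen for all lesion
#' experiments.
#'
#' @param n_per_ensemble neurons per one-dimensional ensemble (50).
#' @param dt simulation step in seconds for the screening runs.
#' @param tau synaptic time constant of ordinary connections (s).
#' @param tau_mem recurrent synaptic time constant of the short-term memory
#'   (s); also sets the integration rate of storage.
#' @param cleanup_threshold detection threshold of the winner-take-all cleanup
#'   memories (concept_perc to concept_in, concept_through to concept_out,
#'   concept_prod to word_prod).
#' @param relay_threshold detection threshold of the plain lemma-to-phono
#'   associative memory (a 1:1 relay that needs no competition, so it sits
#'   just above the random-similarity floor).
#' @param ramp activation ramp width of associative-memory detectors.
#' @param wta_inhibit winner-take-all mutual inhibition weight.
#' @param coactivation_gain strength of the lexical-association co-activation
#'   injected where buffers access the mental lexicon (concept_perc,
#'   concept_prod); the co-activation transform is normalised so the target
#'   pointer keeps unit amplitude.
#' @param recall_gain gain of the memory-unbinding pathway during recall,
#'   chosen so a well-stored item's recalled similarity is about 1, the
#'   activation scale of every other buffer.
#' @param am_reg decoder regularisation of the associative-memory detector
#'   populations; higher than the buffer default so a detector's output
#'   degrades gracefully (proportionally) when its neurons are ablated
#'   instead of swinging with the luck of the deleted decoder weights.
#' @param score_threshold similarity a production must reach to count as a
#'   produced word.
#' @param min_hold time (s) a winning pointer must be sustained to count.
#' @param mem_radius represented half-range of the memory buffers' ensembles;
#'   matched to the component statistics of a normalized superposition
#'   (about 2.3 standard deviations at D = 64) so the recurrent decode
#'   distortion, which scales with the radius, stays small relative to the
#'   stored signal.
#' @param mem_feedback recurrent gain of the short-term memory traces; just
#'   below 1 to null the slight expansive drift of the decoded feedback loop,
#'   so stored items neither grow nor fade over the task's time scale.
#' @param timing a [screening_timing()].
#' @param n_submemories number of short-term submemory traces making up the
#'   mem component; list items are routed to submemories in rotation by the
#'   task control, which keeps each trace within its binding capacity.
#' @param record_every record every k-th simulation step.
#' @export
screening_config <- function(n_per_ensemble = 50, dt = 0.002,
                             tau = 0.01, tau_mem = 0.1,
                             cleanup_threshold = 0.3, relay_threshold = 0.2,
                             ramp = 0.15, wta_inhibit = 2.0,
                             coactivation_gain = 0.3, recall_gain = 2.5,
                             am_reg = 0.5,
                             score_threshold = 0.4, min_hold = 0.03,
                             mem_feedback = 0.99, mem_radius = 0.3,
                             timing = screening_timing(),
                             n_submemories = 2L, record_every = 1L) {
  structure(list(
    n_per_ensemble = n_per_ensemble, dt = dt, tau = tau, tau_mem = tau_mem,
    cleanup_threshold = cleanup_threshold, relay_threshold = relay_threshold,
    ramp = ramp, wta_inhibit = wta_inhibit,
    coactivation_gain = coactivation_gain, recall_gain = recall_gain,
    am_reg = am_reg,
    score_threshold = score_threshold, min_hold = min_hold,
    mem_feedback = mem_feedback, mem_radius = mem_radius,
    timing = timing, n_submemories = as.integer(n_submemories),
    record_every = as.integer(record_every)
  ), class = "screening_config")
}

mem_labels <- function(config) sprintf("mem_%d", seq_len(config$n_submemories))

#' Lexical co-activation weight matrix
#'
#' Symmetric sum of outer products over the lexicon's association relations;
#' added (scaled) to the identity on connections where a buffer accesses the
#' mental lexicon, so related concepts co-activate.
#'
#' @param lexicon a [generate_lexicon()].
#' @export
coactivation_matrix <- function(lexicon) {
  V <- vocab_matrix(lexicon$vocab_concept)
  rel <- dplyr::filter(lexicon$relations, .data$rel == "ASSOC")
  D <- lexicon$dimension
  R <- matrix(0, D, D)
  if (nrow(rel)) {
    A <- V[, rel$from, drop = FALSE]
    B <- V[, rel$to, drop = FALSE]
    R <- B %*% t(A)
    R <- R + t(R)
  }
  R
}

control_pointer_names <- function(n_items = 10) {
  c("Q_NOMEN", "PRODUCE_NOMEN", "KEEP", "RECALL",
    sprintf("LISTEN_I%02d", seq_len(n_items)),
    sprintf("PRODUCE_I%02d", seq_len(n_items)))
}

#' Build the full screening model
#'
#' Wires the in-scope functional architecture: the visual pathway (visual_in,
#' con_visual), the auditory pathway (audio_in, phono_audio, word_audio,
#' con_audio), the cognitive processing module (concept_perc, concept_in,
#' concept_through, concept_out, plus position, bind, unbind and the gated
#' short-term memory mem), the speaking production pathway (concept_prod,
#' word_prod, phono_prod), the input-control buffer, and the four associative
#' memories (three winner-take-all cleanups and the lemma-to-phono relay).
#'
#' @param lexicon a [generate_lexicon()].
#' @param config a [screening_config()].
#' @param seed integer seed for all neural tuning draws.
#' @param n_positions number of ordinal position pointers (default 10).
#' @return an object of class `screening_model`.
#' @export
build_screening_model <- function(lexicon, config = screening_config(),
                                  seed = 1L, n_positions = 10) {
  D <- lexicon$dimension
  vocab_control <- spa_vocabulary(D, seed = derive_seed(seed, 601L))
  for (nm in control_pointer_names(n_positions)) add_pointer(vocab_control, nm)
  vocab_position <- spa_vocabulary(D, seed = derive_seed(seed, 602L))
  for (i in seq_len(n_positions)) {
    add_unitary_pointer(vocab_position, sprintf("Pos_%02d", i))
  }

  np <- config$n_per_ensemble
  mk <- local({
    counter <- 0L
    function(label, vocab) {
      counter <<- counter + 1L
      build_buffer(label, vocab, n_per_ensemble = np,
                   seed = derive_seed(seed, 100L + counter))
    }
  })

  net <- spa_network(dt = config$dt)
  vc <- lexicon$vocab_concept
  for (b in list(
    mk("visual_in", vc), mk("con_visual", vc),
    mk("audio_in", lexicon$vocab_phono), mk("phono_audio", lexicon$vocab_phono),
    mk("word_audio", lexicon$vocab_lemma), mk("con_audio", vc),
    mk("concept_perc", vc), mk("concept_in", vc),
    mk("concept_through", vc), mk("concept_out", vc),
    mk("concept_prod", vc), mk("word_prod", lexicon$vocab_lemma),
    mk("phono_prod", lexicon$vocab_phono),
    mk("position", vocab_position), mk("bind", vc), mk("unbind", vc),
    mk("input_control", vocab_control)
  )) {
    net <- net_add(net, b)
  }
  for (j in seq_len(config$n_submemories)) {
    net <- net_add(net, build_gated_memory(
      sprintf("mem_%d", j), vc, n_per_ensemble = np,
      seed = derive_seed(seed, 150L + j), radius = config$mem_radius,
      feedback_gain = config$mem_feedback, synapse_tau = config$tau_mem))
  }

  maps <- build_level_mappings(lexicon)
  identity_map <- tibble::tibble(input = lexicon$entries$concept,
                                 output = lexicon$entries$concept)
  net <- net_add(net, build_assoc_memory(
    identity_map, vc, vc, threshold = config$cleanup_threshold,
    winner_take_all = TRUE, label = "concept_perc_to_concept_in",
    n_per_ensemble = np, ramp = config$ramp, inhibit = config$wta_inhibit,
    reg = config$am_reg, seed = derive_seed(seed, 201L)))
  net <- net_add(net, build_assoc_memory(
    identity_map, vc, vc, threshold = config$cleanup_threshold,
    winner_take_all = TRUE, label = "concept_through_to_concept_out",
    n_per_ensemble = np, ramp = config$ramp, inhibit = config$wta_inhibit,
    reg = config$am_reg, seed = derive_seed(seed, 202L)))
  net <- net_add(net, build_assoc_memory(
    maps$concept_to_lemma, vc, lexicon$vocab_lemma,
    threshold = config$cleanup_threshold, winner_take_all = TRUE,
    label = "concept_prod_to_word_prod",
    n_per_ensemble = np, ramp = config$ramp, inhibit = config$wta_inhibit,
    reg = config$am_reg, seed = derive_seed(seed, 203L)))
  # the phonological output stage is winner-take-all: only one articulatory
  # form can be realised at a time, so the relay doubles as final selection
  net <- net_add(net, build_assoc_memory(
    maps$lemma_to_phono, lexicon$vocab_lemma, lexicon$vocab_phono,
    threshold = config$relay_threshold, winner_take_all = TRUE,
    label = "word_prod_to_phono_prod",
    n_per_ensemble = np, ramp = config$ramp, inhibit = config$wta_inhibit,
    reg = config$am_reg, seed = derive_seed(seed, 204L)))
  # auditory level-up associations; winner-take-all because only one word is
  # heard at a time, and at D = 64 a purely linear associator over the full
  # lexicon would drown the signal in crosstalk
  net <- net_add(net, build_assoc_memory(
    maps$phono_to_lemma, lexicon$vocab_phono, lexicon$vocab_lemma,
    threshold = config$cleanup_threshold, winner_take_all = TRUE,
    label = "phono_audio_to_word_audio",
    n_per_ensemble = np, ramp = config$ramp, inhibit = config$wta_inhibit,
    reg = config$am_reg, seed = derive_seed(seed, 205L)))
  net <- net_add(net, build_assoc_memory(
    maps$lemma_to_concept, lexicon$vocab_lemma, lexicon$vocab_concept,
    threshold = config$cleanup_threshold, winner_take_all = TRUE,
    label = "word_audio_to_con_audio",
    n_per_ensemble = np, ramp = config$ramp, inhibit = config$wta_inhibit,
    reg = config$am_reg, seed = derive_seed(seed, 206L)))

  R <- coactivation_matrix(lexicon)
  g <- config$coactivation_gain
  tau <- config$tau
  Tin <- diag(D) + g * R
  # normalise so a lexical pointer keeps about unit amplitude after
  # co-activation (the added related-entry mass must not inflate the signal)
  V <- vocab_matrix(lexicon$vocab_concept)
  Tin <- Tin / mean(sqrt(colSums((Tin %*% V)^2)))

  net <- net |>
    net_connect("visual_in", "con_visual", tau = tau) |>
    net_connect("con_visual", "concept_perc", transform = Tin, tau = tau) |>
    net_connect("audio_in", "phono_audio", tau = tau) |>
    net_connect("phono_audio", "phono_audio_to_word_audio", tau = tau) |>
    net_connect("phono_audio_to_word_audio", "word_audio", tau = tau) |>
    net_connect("word_audio", "word_audio_to_con_audio", tau = tau) |>
    net_connect("word_audio_to_con_audio", "con_audio", tau = tau) |>
    net_connect("con_audio", "concept_perc", transform = Tin, tau = tau) |>
    net_connect("concept_perc", "concept_perc_to_concept_in", tau = tau) |>
    net_connect("concept_perc_to_concept_in", "concept_in", tau = tau) |>
    net_connect("concept_in", "concept_through", tau = tau,
                gate = "g_through", gate_default = 1) |>
    net_connect("concept_through", "concept_through_to_concept_out", tau = tau) |>
    net_connect("concept_through_to_concept_out", "concept_out", tau = tau) |>
    net_connect("concept_out", "concept_prod", transform = Tin, tau = tau,
                gate = "g_produce", gate_default = 0) |>
    net_connect("concept_prod", "concept_prod_to_word_prod", tau = tau) |>
    net_connect("concept_prod_to_word_prod", "word_prod", tau = tau) |>
    net_connect("word_prod", "word_prod_to_phono_prod", tau = tau) |>
    net_connect("word_prod_to_phono_prod", "phono_prod", tau = tau) |>
    net_connect("concept_in", "bind", type = "bind", src2 = "position",
                tau = tau)
  for (j in seq_len(config$n_submemories)) {
    mj <- sprintf("mem_%d", j)
    net <- net |>
      net_connect("bind", mj, tau = tau, gain = 1,
                  gate = sprintf("g_store_%d", j), gate_default = 0) |>
      net_connect(mj, "unbind", type = "unbind", src2 = "position",
                  tau = tau, gain = config$recall_gain,
                  gate = sprintf("g_recall_%d", j), gate_default = 0)
  }
  net <- net_connect(net, "unbind", "concept_through", tau = tau)

  structure(list(net = net, lexicon = lexicon, config = config,
                 vocab_control = vocab_control,
                 vocab_position = vocab_position,
                 n_positions = n_positions,
                 seed = as.integer(seed)),
            class = "screening_model")
}

#' @export
print.screening_model <- function(x, ...) {
  s <- network_summary(x$net)
  cat(sprintf("<screening_model> %d components, %s neurons, D = %d\n",
              nrow(s), format(sum(s$neurons), big.mark = ","),
              x$lexicon$dimension))
  invisible(x)
}

#' Specify an ablation
#'
#' @param target component label (e.g. `concept_prod`, `mem`, `concept_in`,
#'   `concept_prod_to_word_prod`, `concept_through_to_concept_out`).
#' @param fraction fraction of the component's neurons to silence, in
#'   `[0, 1]`.
#' @param seed optional integer seed for the neuron draw; when `NULL` it is
#'   derived from the run seed.
#' @export
ablation_spec <- function(target, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  structure(list(target = target, fraction = fraction, seed = seed),
            class = "ablation_spec")
}

normalize_ablations <- function(ablations) {
  if (is.null(ablations)) return(list())
  if (inherits(ablations, "ablation_spec")) return(list(ablations))
  if (is.numeric(ablations) && !is.null(names(ablations))) {
    return(unname(purrr::imap(as.list(ablations),
                              function(f, nm) ablation_spec(nm, f))))
  }
  stopifnot(is.list(ablations))
  ablations
}

#' Apply ablations to a screening model
#'
#' @param model a [build_screening_model()].
#' @param ablations a named numeric vector `c(component = fraction, ...)`, an
#'   [ablation_spec()], or a list of them.
#' @param seed run seed from which per-ablation seeds are derived when a spec
#'   carries none.
#' @export
apply_ablations <- function(model, ablations, seed = 1L) {
  ablations <- normalize_ablations(ablations)
  for (i in seq_along(ablations)) {
    ab <- ablations[[i]]
    s <- if (is.null(ab$seed)) derive_seed(seed, 500L + i) else ab$seed
    if (identical(ab$target, "mem")) {
      # the short-term memory is a bank of submemory traces; "mem" ablates
      # round(fraction x total bank neurons), drawn jointly across the bank
      labs <- grep("^mem_", names(model$net$components), value = TRUE)
      sizes <- vapply(labs, function(l) length(model$net$components[[l]]$alive), 1L)
      alive <- ablate_mask(sum(sizes), ab$fraction, s)
      off <- 0L
      for (l in labs) {
        comp <- model$net$components[[l]]
        comp$alive <- alive[(off + 1L):(off + length(comp$alive))]
        comp$ablation <- list(fraction = ab$fraction, seed = as.integer(s))
        model$net <- net_set_component(model$net, comp)
        off <- off + length(comp$alive)
      }
      next
    }
    comp <- model$net$components[[ab$target]]
    if (is.null(comp)) {
      stop(sprintf("unknown ablation target '%s'", ab$target), call. = FALSE)
    }
    model$net <- net_set_component(model$net, ablate(comp, ab$fraction, s))
  }
  model
}

#' Score productions from a simulated trajectory
#'
#' Within each scoring window, a symbol counts as produced if it is the
#' maximal-similarity vocabulary entry with raw (unnormalised) similarity of
#' at least `score_threshold`, sustained for at least `min_hold` seconds; the
#' produced symbol of the window is the one with the longest sustained run.
#' No sustained supra-threshold winner means a null production (incorrect).
#'
#' @param sim a [run_network()] result.
#' @param component probed component to score (e.g. `phono_prod`).
#' @param vocab vocabulary of candidate forms.
#' @param windows tibble with columns `item`, `target` (expected symbol in
#'   `vocab`), `t_on`, `t_off`.
#' @param score_threshold,min_hold decision parameters.
#' @return tibble with one row per window: `item`, `target`, `produced`,
#'   `produced_time`, `correct`.
#' @export
score_production <- function(sim, component, vocab, windows,
                             score_threshold = 0.4, min_hold = 0.03) {
  X <- sim$probes[[component]]
  if (is.null(X)) stop(sprintf("component '%s' was not probed", component), call. = FALSE)
  if (max(windows$t_off) > max(sim$time) + 1e-9) {
    stop("scoring window extends beyond the simulated trajectory", call. = FALSE)
  }
  V <- vocab_matrix(vocab)
  nms <- vocab_names(vocab)
  step <- sim$dt * sim$record_every
  need <- max(1L, as.integer(ceiling(min_hold / step)))
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    sel <- sim$time >= windows$t_on[i] & sim$time <= windows$t_off[i]
    S <- X[sel, , drop = FALSE] %*% V
    if (nrow(S) == 0) {
      return(tibble::tibble(item = windows$item[i], target = windows$target[i],
                            produced = NA_character_, produced_time = NA_real_,
                            correct = FALSE))
    }
    win_j <- max.col(S, ties.method = "first")
    win_s <- S[cbind(seq_len(nrow(S)), win_j)]
    ok <- win_s >= score_threshold
    # run-length encode the winning symbol among supra-threshold steps
    sym <- ifelse(ok, win_j, 0L)
    r <- rle(sym)
    good <- which(r$values != 0L & r$lengths >= need)
    if (length(good) == 0) {
      produced <- NA_character_; ptime <- NA_real_
    } else {
      best <- good[which.max(r$lengths[good])]
      produced <- nms[r$values[best]]
      start_idx <- sum(r$lengths[seq_len(best - 1)]) + 1L
      ptime <- sim$time[sel][start_idx]
    }
    tibble::tibble(item = windows$item[i], target = windows$target[i],
                   produced = produced, produced_time = ptime,
                   correct = identical(produced, windows$target[i]))
  })
}

new_screening_trial <- function(records, task, n_correct, seed, ablations,
                                sim = NULL) {
  structure(records,
            task = task, n_correct = n_correct, seed = seed,
            ablations = ablations, sim = sim,
            class = c("screening_trial", class(records)))
}

#' @export
print.screening_trial <- function(x, ...) {
  cat(sprintf("<screening_trial> task '%s': %d / %d correct (seed %d)\n",
              attr(x, "task"), attr(x, "n_correct"), nrow(x), attr(x, "seed")))
  NextMethod()
}

#' Number of correct items of a trial
#' @param trial a screening trial.
#' @export
n_correct <- function(trial) attr(trial, "n_correct")

#' Simulate the picture-induced word-naming screening
#'
#' Runs the visual pathway, cognitive processing and the speaking pathway for
#' each scene of the item set, and scores the phonological production buffer
#' within each production window. In the physiological case (no ablation)
#' every item is named correctly.
#'
#' @param lexicon a [generate_lexicon()].
#' @param items a [wwt_item_set()] tibble; default the 20-item set.
#' @param ablations see [apply_ablations()]; `NULL` for the physiological
#'   case.
#' @param seed integer seed controlling the neural build and ablation draws.
#' @param config a [screening_config()].
#' @param keep_sim keep the simulation object (memory-heavy) as an attribute.
#' @param model optional pre-built [build_screening_model()] to reuse; it is
#'   re-ablated from scratch for this run.
#' @return a `screening_trial` tibble, one row per item, with attributes
#'   `n_correct`, `task`, `seed`, `ablations`.
#' @export
run_wwt_naming <- function(lexicon, items = NULL, ablations = NULL, seed = 1L,
                           config = screening_config(), keep_sim = FALSE,
                           model = NULL) {
  if (is.null(items)) items <- wwt_item_set(lexicon)
  if (is.null(model)) {
    model <- build_screening_model(lexicon, config, seed = derive_seed(seed, 1L))
  }
  model <- apply_ablations(model, ablations, seed = derive_seed(seed, 2L))
  script <- build_wwt_script(items, config$timing)
  probes <- c("phono_prod", "concept_prod", "input_control")
  if (keep_sim) probes <- c(probes, "visual_in", "concept_out", "word_prod")
  sim <- run_network(model$net, duration = script$duration,
                     inputs = script$events, gate_events = script$gates,
                     probes = probes, dt = config$dt,
                     record_every = config$record_every)
  e <- lexicon$entries
  windows <- script$windows
  windows$target_concept <- windows$target
  windows$target <- e$phono[match(windows$target, e$concept)]
  rec <- score_production(sim, "phono_prod", lexicon$vocab_phono, windows,
                          config$score_threshold, config$min_hold)
  rec$target_concept <- windows$target_concept
  new_screening_trial(rec, task = "wwt", n_correct = sum(rec$correct),
                      seed = as.integer(seed),
                      ablations = normalize_ablations(ablations),
                      sim = if (keep_sim) sim else NULL)
}

#' Simulate the word-list repetition screening
#'
#' KEEP phase: each auditorily presented word climbs the perception pathway,
#' is bound to its ordinal position pointer and accumulates in the gated
#' short-term memory. RECALL phase: positions are re-activated one by one,
#' the memory is unbound, and the cleaned-up concepts flow to the production
#' pathway. A produced concept is credited if it belongs to the target list
#' (unordered; each target creditable once).
#'
#' @inheritParams run_wwt_naming
#' @param wordlist concept symbols to repeat; default [demtect_wordlist()].
#' @export
run_demtect_repetition <- function(lexicon, wordlist = NULL, ablations = NULL,
                                   seed = 1L, config = screening_config(),
                                   keep_sim = FALSE, model = NULL) {
  if (is.null(wordlist)) wordlist <- demtect_wordlist(lexicon)
  k <- length(wordlist)
  if (is.null(model)) {
    model <- build_screening_model(lexicon, config, seed = derive_seed(seed, 1L))
  }
  if (k > model$n_positions) {
    stop("word list exceeds available position pointers", call. = FALSE)
  }
  model <- apply_ablations(model, ablations, seed = derive_seed(seed, 2L))
  script <- build_demtect_script(wordlist, lexicon, config$timing,
                                 n_submemories = config$n_submemories)
  # storage gain: each item should integrate to about 1/sqrt(items per trace)
  # amplitude so each trace's superposition stays within its represented range
  k_per <- ceiling(k / config$n_submemories)
  store_window <- config$timing$present - 0.10
  store_gain <- (1 / sqrt(k_per)) * config$tau_mem / (store_window * 0.95)
  model$net$connections <- lapply(model$net$connections, function(cn) {
    if (cn$src == "bind" && grepl("^mem_", cn$dst)) cn$gain <- store_gain
    cn
  })
  gates <- dplyr::bind_rows(
    script$gates,
    tibble::tibble(gate = "g_through", t_on = 0, t_off = script$duration,
                   value = 0)
  )
  probes <- c("concept_prod", "input_control")
  if (keep_sim) probes <- c(probes, "audio_in", "concept_in",
                            mem_labels(config), "concept_out", "position")
  sim <- run_network(model$net, duration = script$duration,
                     inputs = script$events, gate_events = gates,
                     probes = probes, dt = config$dt,
                     record_every = config$record_every)
  rec <- score_production(sim, "concept_prod", lexicon$vocab_concept,
                          script$windows, config$score_threshold,
                          config$min_hold)
  # unordered list credit: a produced concept scores if it is any not-yet
  # credited target word
  credited <- character(0)
  rec$correct <- FALSE
  for (i in seq_len(nrow(rec))) {
    p <- rec$produced[i]
    if (!is.na(p) && p %in% wordlist && !(p %in% credited)) {
      rec$correct[i] <- TRUE
      credited <- c(credited, p)
    }
  }
  new_screening_trial(rec, task = "demtect", n_correct = sum(rec$correct),
                      seed = as.integer(seed),
                      ablations = normalize_ablations(ablations),
                      sim = if (keep_sim) sim else NULL)
}

#' Write trials as JSON lines (one trial per line)
#'
#' @param trials a `screening_trial` or list of them.
#' @param path output path.
#' @param append append to an existing file.
#' @export
write_trials_jsonl <- function(trials, path, append = FALSE) {
  if (inherits(trials, "screening_trial")) trials <- list(trials)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con), add = TRUE)
  for (tr in trials) {
    abl <- lapply(attr(tr, "ablations"), function(a) {
      list(target = a$target, fraction = a$fraction)
    })
    obj <- list(task = attr(tr, "task"), seed = attr(tr, "seed"),
                n_correct = attr(tr, "n_correct"), ablations = abl,
                items = tibble::as_tibble(tr))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}
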