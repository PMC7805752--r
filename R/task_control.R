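#' Task timing configuration
#'
#' Interval durations for the timed stimulus scripts. The durations are free
#' parameters of the simulations (sub-second phases per item): 0.25 s per
#' visual/auditory presentation, 0.1 s gap, 0.5 s production window.
#'
#' @param present presentation duration per visual/auditory item (s).
#' @param gap silent gap between presentations (s).
#' @param produce production window per item (s).
#' @param lead lead-in duration for task-phase pointers such as KEEP (s).
#' @export
screening_timing <- function(present = 0.25, gap = 0.1, produce = 0.5,
                             lead = 0.25) {
  stopifnot(present > 0, gap >= 0, produce > 0, lead >= 0)
  structure(list(present = present, gap = gap, produce = produce, lead = lead),
            class = "screening_timing")
}

new_task_script <- function(task, events, gates, windows, duration) {
  structure(list(task = task, events = events, gates = gates,
                 windows = windows, duration = duration),
            class = "spa_task_script")
}

#' @export
print.spa_task_script <- function(x, ...) {
  cat(sprintf("<spa_task_script> task '%s': %d events, %d windows, %.2f s\n",
              x$task, nrow(x$events), nrow(x$windows), x$duration))
  invisible(x)
}

#' Build the timed script for the picture-naming task
#'
#' Per item, the scene's distractor objects and then the target object are
#' presented on the visual input while the input-control buffer carries
#' Q_NOMEN; the target picture stays in view through the production window,
#' during which input control carries PRODUCE_NOMEN and the production gate is
#' open.
#'
#' @param items a [wwt_item_set()] tibble (columns `target`, `distractors`).
#' @param timing a [screening_timing()].
#' @return a `spa_task_script`.
#' @export
build_wwt_script <- function(items, timing = screening_timing()) {
  stopifnot(nrow(items) >= 1)
  if (timing$present <= 0 || timing$produce <= 0) {
    stop("zero-length intervals are not allowed", call. = FALSE)
  }
  slot <- timing$present + timing$gap
  ev <- list(); gt <- list(); win <- list()
  t0 <- 0
  for (i in seq_len(nrow(items))) {
    seqv <- c(items$distractors[[i]], items$target[i])
    n_vis <- length(seqv)
    t_prod <- t0 + n_vis * slot
    block_end <- t_prod + timing$produce + timing$gap
    for (k in seq_len(n_vis)) {
      on <- t0 + (k - 1) * slot
      off <- if (k == n_vis) t_prod + timing$produce else on + timing$present
      ev[[length(ev) + 1]] <- tibble::tibble(
        component = "visual_in", pointer = seqv[k], t_on = on, t_off = off)
    }
    ev[[length(ev) + 1]] <- tibble::tibble(
      component = "input_control", pointer = "Q_NOMEN", t_on = t0, t_off = t_prod)
    ev[[length(ev) + 1]] <- tibble::tibble(
      component = "input_control", pointer = "PRODUCE_NOMEN",
      t_on = t_prod, t_off = t_prod + timing$produce)
    gt[[length(gt) + 1]] <- tibble::tibble(
      gate = "g_produce", t_on = t_prod, t_off = t_prod + timing$produce, value = 1)
    win[[length(win) + 1]] <- tibble::tibble(
      item = i, target = items$target[i],
      t_on = t_prod + 0.05, t_off = t_prod + timing$produce)
    t0 <- block_end
  }
  new_task_script("wwt",
                  events = dplyr::bind_rows(ev),
                  gates = dplyr::bind_rows(gt),
                  windows = dplyr::bind_rows(win),
                  duration = t0)
}

#' Build the timed script for the word-list repetition task
#'
#' KEEP phase: the list words arrive on the auditory input while the position
#' buffer is clamped to the ordinal position pointers Pos_01, Pos_02, ... in
#' temporal synchrony, and the bind-and-store gates are open so each
#' position-word binding accumulates in the short-term memory. RECALL phase:
#' the position pointers are re-activated one after the other while the
#' unbinding pathway and the production gate are open.
#'
#' @param wordlist concept symbols in list order (at most the number of
#'   available position pointers; the screening list has 10).
#' @param lexicon the [generate_lexicon()] supplying each word's phonological
#'   form (the auditory input is set to the phonological form).
#' @param timing a [screening_timing()].
#' @param n_submemories number of short-term submemory traces; items are
#'   routed to traces in rotation (gates `g_store_<j>` / `g_recall_<j>`).
#' @export
build_demtect_script <- function(wordlist, lexicon,
                                 timing = screening_timing(),
                                 n_submemories = 2L) {
  k <- length(wordlist)
  stopifnot(k >= 1)
  if (k > 99) stop("word list exceeds available position pointers", call. = FALSE)
  e <- lexicon$entries
  phono <- e$phono[match(wordlist, e$concept)]
  if (anyNA(phono)) {
    stop("word list contains concepts missing from the lexicon", call. = FALSE)
  }
  slot <- timing$present + timing$gap
  ev <- list(); gt <- list(); win <- list()

  ev[[1]] <- tibble::tibble(component = "input_control", pointer = "KEEP",
                            t_on = 0, t_off = timing$lead)
  t0 <- timing$lead
  for (i in seq_len(k)) {
    on <- t0 + (i - 1) * slot
    off <- on + timing$present
    ev[[length(ev) + 1]] <- tibble::tibble(
      component = "audio_in", pointer = phono[i], t_on = on, t_off = off)
    ev[[length(ev) + 1]] <- tibble::tibble(
      component = "input_control", pointer = sprintf("LISTEN_I%02d", i),
      t_on = on, t_off = off)
    ev[[length(ev) + 1]] <- tibble::tibble(
      component = "position", pointer = sprintf("Pos_%02d", i),
      t_on = on, t_off = off)
    # the store window opens only once the perception chain has settled on
    # the new word, so the binding is not contaminated by the item handover
    sub_j <- ((i - 1L) %% n_submemories) + 1L
    gt[[length(gt) + 1]] <- tibble::tibble(
      gate = sprintf("g_store_%d", sub_j),
      t_on = on + 0.10, t_off = off, value = 1)
  }
  t_recall <- t0 + k * slot
  ev[[length(ev) + 1]] <- tibble::tibble(
    component = "input_control", pointer = "RECALL",
    t_on = t_recall, t_off = t_recall + timing$lead)
  t0 <- t_recall + timing$lead
  for (i in seq_len(k)) {
    on <- t0 + (i - 1) * (timing$produce + timing$gap)
    off <- on + timing$produce
    ev[[length(ev) + 1]] <- tibble::tibble(
      component = "input_control", pointer = sprintf("PRODUCE_I%02d", i),
      t_on = on, t_off = off)
    ev[[length(ev) + 1]] <- tibble::tibble(
      component = "position", pointer = sprintf("Pos_%02d", i),
      t_on = on, t_off = off)
    sub_j <- ((i - 1L) %% n_submemories) + 1L
    gt[[length(gt) + 1]] <- tibble::tibble(
      gate = sprintf("g_recall_%d", sub_j), t_on = on, t_off = off, value = 1)
    gt[[length(gt) + 1]] <- tibble::tibble(
      gate = "g_produce", t_on = on + 0.05, t_off = off, value = 1)
    win[[length(win) + 1]] <- tibble::tibble(
      item = i, target = wordlist[i], t_on = on + 0.1, t_off = off)
    t0_i <- off
  }
  duration <- t0 + k * (timing$produce + timing$gap)
  new_task_script("demtect",
                  events = dplyr::bind_rows(ev),
                  gates = dplyr::bind_rows(gt),
                  windows = dplyr::bind_rows(win),
                  duration = duration)
}

#' Define an action rule
#'
#' A rule's utility is a weighted sum of dot products between named buffers'
#' decoded states and condition pointers, emulating how the basal
#' ganglia-thalamus loop scores candidate actions against cortical state.
#'
#' @param name action name (e.g. `PROCESS_NOMEN`, `SPEAK`, `KEEP`, `RECALL`).
#' @param terms a tibble with columns `component`, `vector` (list column of
#'   condition pointer vectors) and `weight`.
#' @export
action_rule <- function(name, terms) {
  structure(list(name = name, terms = terms), class = "spa_action_rule")
}

rule_terms <- function(component, vocab, names, weight = 1) {
  tibble::tibble(
    component = component,
    vector = lapply(names, function(nm) vocab_get(vocab, nm)$v),
    weight = weight
  )
}

#' Action rules for the two screening tasks
#'
#' The naming task maps Q_NOMEN to PROCESS_NOMEN and PRODUCE_NOMEN to SPEAK;
#' the repetition task maps KEEP/LISTEN_* to KEEP and RECALL/PRODUCE_* to
#' RECALL.
#'
#' @param control_vocab the input-control vocabulary.
#' @param n_items list length for the repetition task.
#' @return list of [action_rule()]s.
#' @export
wwt_action_rules <- function(control_vocab) {
  list(
    action_rule("PROCESS_NOMEN",
                rule_terms("input_control", control_vocab, "Q_NOMEN")),
    action_rule("SPEAK",
                rule_terms("input_control", control_vocab, "PRODUCE_NOMEN"))
  )
}

#' @rdname wwt_action_rules
#' @export
demtect_action_rules <- function(control_vocab, n_items = 10) {
  listen <- sprintf("LISTEN_I%02d", seq_len(n_items))
  produce <- sprintf("PRODUCE_I%02d", seq_len(n_items))
  list(
    action_rule("KEEP",
                rule_terms("input_control", control_vocab, c("KEEP", listen))),
    action_rule("RECALL",
                rule_terms("input_control", control_vocab, c("RECALL", produce)))
  )
}

#' Evaluate rule utilities against a model state
#'
#' @param rules list of [action_rule()]s.
#' @param state named list of decoded state vectors, one per referenced
#'   component.
#' @return numeric utility per rule.
#' @export
evaluate_utilities <- function(rules, state) {
  vapply(rules, function(r) {
    s <- 0
    for (i in seq_len(nrow(r$terms))) {
      comp <- r$terms$component[i]
      if (!comp %in% names(state)) {
        stop(sprintf("rule '%s' references unknown buffer '%s'", r$name, comp),
             call. = FALSE)
      }
      s <- s + r$terms$weight[i] * sum(state[[comp]] * r$terms$vector[[i]])
    }
    s
  }, numeric(1))
}

#' Reference action selector with hysteresis
#'
#' Argmax over utilities if the maximum reaches `threshold`; the incumbent
#' rule is retained unless a challenger exceeds its utility by `margin`
#' (hysteresis against chattering). Ties break by rule declaration order.
#'
#' @param utilities numeric vector.
#' @param threshold selection threshold (>= 0).
#' @param incumbent index of the currently selected rule, or `NA`.
#' @param margin hysteresis margin.
#' @return selected rule index, or `NA_integer_` if nothing reaches threshold.
#' @export
select_action <- function(utilities, threshold = 0.3, incumbent = NA_integer_,
                          margin = 0.05) {
  stopifnot(threshold >= 0)
  j <- which.max(utilities)
  if (utilities[j] < threshold) return(NA_integer_)
  if (!is.na(incumbent) && incumbent != j &&
      utilities[incumbent] >= threshold &&
      utilities[j] <= utilities[incumbent] + margin) {
    return(as.integer(incumbent))
  }
  as.integer(j)
}

#' Neural action selector (mutual-inhibition population)
#'
#' A simple competitive population settled to steady state: each candidate
#' accumulates its utility minus inhibition from the others. Provided as a
#' neural counterpart of [select_action()]; the two must agree on steady
#' inputs.
#'
#' @inheritParams select_action
#' @param inhibit mutual inhibition weight.
#' @param steps settling iterations.
#' @export
select_action_neural <- function(utilities, threshold = 0.3, inhibit = 1.5,
                                 steps = 200) {
  a <- pmax(utilities - threshold, 0)
  for (i in seq_len(steps)) {
    drive <- utilities - threshold - inhibit * (sum(a) - a)
    a <- 0.8 * a + 0.2 * pmax(drive, 0)
  }
  if (all(a < 1e-6)) return(NA_integer_)
  as.integer(which.max(a))
}

#' Realized action trace of a simulation
#'
#' Runs the reference selector along the recorded trajectory of the
#' input-control buffer (and any other buffers the rules reference) and
#' returns the selected action per time step.
#'
#' @param sim a [run_network()] result probing every component the rules use.
#' @param rules list of [action_rule()]s.
#' @param threshold,margin selector parameters.
#' @return tibble with `time`, `action` (name or `NA`).
#' @export
action_trace <- function(sim, rules, threshold = 0.3, margin = 0.05) {
  comps <- unique(unlist(lapply(rules, function(r) r$terms$component)))
  n <- length(sim$time)
  sel <- rep(NA_integer_, n)
  inc <- NA_integer_
  for (t in seq_len(n)) {
    state <- stats::setNames(
      lapply(comps, function(cp) sim$probes[[cp]][t, ]), comps)
    u <- evaluate_utilities(rules, state)
    inc <- select_action(u, threshold, inc, margin)
    sel[t] <- inc
  }
  tibble::tibble(
    time = sim$time,
    action = ifelse(is.na(sel), NA_character_,
                    vapply(rules, function(r) r$name, character(1))[sel])
  )
}
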