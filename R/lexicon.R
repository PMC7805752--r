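#' Synthetic mental lexicon
#'
#' The mental lexicon has three levels — concepts (`C_*`, meaning), lemmata
#' (`W_*`, grammatical word) and phonological forms (`P_*`, sound sequence) —
#' in 1:1:1 correspondence, plus superordinate (category) concepts in a deep
#' concept network and syllable-part entries in a deep phonological network.
#' Concepts in the same category are generated around a shared category core
#' so that semantically related words have above-chance pointer similarity,
#' which is what makes related entries co-activate during lexical access.
#'
#' The item fixtures of the two screenings are always present: the ten-word
#' repetition list (Teller, Hund, Lampe, Brief, Apfel, Hose, Tisch, Wiese,
#' Glas, Baum) and the picture-naming example scene (Gras, Mann, Rad,
#' Schubkarre).
#'
#' @name lexicon
NULL

demtect_words <- c("Teller", "Hund", "Lampe", "Brief", "Apfel",
                   "Hose", "Tisch", "Wiese", "Glas", "Baum")
wwt_scene_words <- c("Gras", "Mann", "Rad", "Schubkarre")
fixture_words <- c(demtect_words, wwt_scene_words)

#' Generate a synthetic mental lexicon
#'
#' Deterministic given `seed`. The full scale of the knowledge repository is
#' about 1,000 entries, 250 superordinates and 1,200 syllable parts; all
#' counts are configurable down to tens of entries for fast experiments.
#'
#' @param n_entries number of lexical entries (>= 30, so that both screening
#'   fixtures and a 20-item naming set fit).
#' @param n_superordinates number of superordinate (category) concepts.
#' @param n_syllable_parts size of the deep phonological syllable-part pool.
#' @param D pointer dimensionality.
#' @param relatedness_mix mixing coefficient binding same-category concepts to
#'   their category core (0 = unrelated, 1 = identical); default 0.4.
#' @param seed integer seed.
#' @return an object of class `spa_lexicon`.
#' @export
generate_lexicon <- function(n_entries = 1000, n_superordinates = 250,
                             n_syllable_parts = 1200, D = 64,
                             relatedness_mix = 0.4, seed = 1L) {
  n_fix <- length(fixture_words)
  if (n_entries < 30) {
    stop("n_entries must be at least 30 (screening fixtures plus naming set)",
         call. = FALSE)
  }
  stopifnot(n_superordinates >= 1, n_syllable_parts >= 3)

  words <- c(fixture_words,
             sprintf("Wort%04d", seq_len(n_entries - n_fix)))
  categories <- sprintf("Kat%03d", seq_len(n_superordinates))

  vocab_concept <- spa_vocabulary(D, seed = derive_seed(seed, 1L))
  vocab_lemma <- spa_vocabulary(D, seed = derive_seed(seed, 2L))
  vocab_phono <- spa_vocabulary(D, seed = derive_seed(seed, 3L))
  vocab_deep_concept <- spa_vocabulary(D, seed = derive_seed(seed, 4L))
  vocab_deep_phono <- spa_vocabulary(D, seed = derive_seed(seed, 5L))

  # category cores: superordinate pointers in the deep concept network
  for (cat in categories) add_pointer(vocab_deep_concept, paste0("S_", cat))

  cat_of <- categories[((seq_len(n_entries) - 1L) %% n_superordinates) + 1L]
  for (i in seq_len(n_entries)) {
    core <- vocab_get(vocab_deep_concept, paste0("S_", cat_of[i]))
    add_related_pointer(vocab_concept, paste0("C_", words[i]),
                        core, mix = relatedness_mix)
    add_pointer(vocab_lemma, paste0("W_", words[i]))
    add_pointer(vocab_phono, paste0("P_", words[i]))
  }

  syl_pool <- sprintf("syl%04d", seq_len(n_syllable_parts))
  for (sp in syl_pool) add_pointer(vocab_deep_phono, sp)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 6L))
  syllables <- lapply(seq_len(n_entries), function(i) {
    k <- sample(1:3, 1)
    sample(syl_pool, k)
  })

  # associations: each entry associates with the next same-category entry
  assoc_partner <- vapply(seq_len(n_entries), function(i) {
    same <- which(cat_of == cat_of[i])
    same <- same[same != i]
    if (length(same) == 0) NA_character_ else {
      nxt <- same[same > i]
      paste0("C_", words[if (length(nxt)) nxt[1] else same[1]])
    }
  }, character(1))

  entries <- tibble::tibble(
    concept = paste0("C_", words),
    lemma = paste0("W_", words),
    phono = paste0("P_", words),
    category = paste0("S_", cat_of),
    associations = lapply(assoc_partner, function(a) if (is.na(a)) character(0) else a),
    syllables = syllables
  )

  relations <- dplyr::bind_rows(
    tibble::tibble(from = entries$concept, rel = "IS_A", to = entries$category),
    tibble::tibble(
      from = entries$concept[!is.na(assoc_partner)],
      rel = "ASSOC",
      to = assoc_partner[!is.na(assoc_partner)]
    )
  )

  structure(list(
    entries = entries,
    superordinates = paste0("S_", categories),
    relations = relations,
    vocab_concept = vocab_concept,
    vocab_lemma = vocab_lemma,
    vocab_phono = vocab_phono,
    vocab_deep_concept = vocab_deep_concept,
    vocab_deep_phono = vocab_deep_phono,
    dimension = as.integer(D),
    relatedness_mix = relatedness_mix,
    seed = as.integer(seed)
  ), class = "spa_lexicon")
}

#' @export
print.spa_lexicon <- function(x, ...) {
  cat(sprintf("<spa_lexicon> %d entries, %d superordinates, D = %d, seed = %d\n",
              nrow(x$entries), length(x$superordinates), x$dimension, x$seed))
  invisible(x)
}

#' The ten-word repetition list
#'
#' The word list of the repetition screening subtask, in presentation order
#' (plate, dog, lamp, letter, apple, pants, table, lawn, drinking glass,
#' tree — German labels).
#'
#' @param lexicon a [generate_lexicon()].
#' @return character vector of 10 concept symbols, `C_Teller` ... `C_Baum`.
#' @export
demtect_wordlist <- function(lexicon) {
  wl <- paste0("C_", demtect_words)
  missing <- setdiff(wl, lexicon$entries$concept)
  if (length(missing)) {
    stop("lexicon is missing repetition-list fixtures: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  wl
}

#' Picture-naming item set
#'
#' Each item is a visual scene: an ordered sequence of distractor concepts
#' followed by the target concept (the last object fed into the visual
#' pathway is the target to be named). The wheelbarrow scene always uses the
#' canonical distractors grass, man, wheel.
#'
#' @param lexicon a [generate_lexicon()].
#' @param n_items number of scenes (default 20).
#' @param n_distractors distractors per scene (default 3).
#' @return a tibble with columns `target` and `distractors` (list column); the
#'   visual sequence of a scene is `c(distractors, target)`.
#' @export
wwt_item_set <- function(lexicon, n_items = 20, n_distractors = 3) {
  concepts <- lexicon$entries$concept
  if (n_items > length(concepts)) {
    stop("not enough lexicon entries for the requested item count", call. = FALSE)
  }
  scene_fix <- paste0("C_", wwt_scene_words)
  stopifnot(all(scene_fix %in% concepts))
  # targets: the wheelbarrow fixture first, then entries in insertion order,
  # skipping its scene distractors so no scene names its own distractor
  pool <- setdiff(concepts, scene_fix)
  targets <- c("C_Schubkarre", utils::head(pool, n_items - 1))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  distractors <- lapply(seq_along(targets), function(i) {
    if (targets[i] == "C_Schubkarre") {
      c("C_Gras", "C_Mann", "C_Rad")
    } else {
      set.seed(derive_seed(lexicon$seed, 91L, i))
      sample(setdiff(concepts, targets[i]), n_distractors)
    }
  })
  tibble::tibble(target = targets, distractors = distractors)
}

#' Level-to-level mapping tables of the lexicon
#'
#' Four 1:1 mapping tables for associative memories: production-side
#' concept-to-lemma (flagged as a winner-take-all cleanup) and lemma-to-phono,
#' and perception-side phono-to-lemma and lemma-to-concept.
#'
#' @param lexicon a [generate_lexicon()].
#' @return named list of tibbles with columns `input`, `output`; the
#'   `concept_to_lemma` element carries `attr(, "cleanup") = TRUE`.
#' @export
build_level_mappings <- function(lexicon) {
  e <- lexicon$entries
  c2w <- tibble::tibble(input = e$concept, output = e$lemma)
  attr(c2w, "cleanup") <- TRUE
  list(
    concept_to_lemma = c2w,
    lemma_to_phono = tibble::tibble(input = e$lemma, output = e$phono),
    phono_to_lemma = tibble::tibble(input = e$phono, output = e$lemma),
    lemma_to_concept = tibble::tibble(input = e$lemma, output = e$concept)
  )
}

vocab_serialize <- function(vocab) {
  list(
    dimension = vocab$dimension,
    seed = vocab$seed,
    unitary = stats::setNames(as.list(vocab$unitary), vocab$names),
    entries = stats::setNames(
      lapply(seq_along(vocab$names), function(j) vocab$vectors[, j]),
      vocab$names
    )
  )
}

vocab_deserialize <- function(obj) {
  v <- spa_vocabulary(obj$dimension, seed = obj$seed)
  nm <- names(obj$entries)
  for (j in seq_along(nm)) {
    vocab_register(v, nm[j], as.numeric(obj$entries[[j]]),
                   unitary = isTRUE(as.logical(obj$unitary[[nm[j]]])))
  }
  v
}

#' Serialize a lexicon to JSON (lossless round trip)
#'
#' @param lexicon a [generate_lexicon()].
#' @param path file path.
#' @export
write_lexicon_json <- function(lexicon, path) {
  obj <- list(
    dimension = lexicon$dimension,
    seed = lexicon$seed,
    relatedness_mix = lexicon$relatedness_mix,
    superordinates = lexicon$superordinates,
    entries = lapply(seq_len(nrow(lexicon$entries)), function(i) {
      e <- lexicon$entries[i, ]
      list(concept = e$concept, lemma = e$lemma, phono = e$phono,
           category = e$category,
           associations = e$associations[[1]],
           syllables = e$syllables[[1]])
    }),
    relations = lexicon$relations,
    vocabularies = list(
      concept = vocab_serialize(lexicon$vocab_concept),
      lemma = vocab_serialize(lexicon$vocab_lemma),
      phono = vocab_serialize(lexicon$vocab_phono),
      deep_concept = vocab_serialize(lexicon$vocab_deep_concept),
      deep_phono = vocab_serialize(lexicon$vocab_deep_phono)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lexicon_json
#' @export
read_lexicon_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- purrr::map_dfr(obj$entries, function(e) {
    tibble::tibble(concept = e$concept, lemma = e$lemma, phono = e$phono,
                   category = e$category,
                   associations = list(as.character(unlist(e$associations))),
                   syllables = list(as.character(unlist(e$syllables))))
  })
  relations <- purrr::map_dfr(obj$relations, function(r) {
    tibble::tibble(from = r$from, rel = r$rel, to = r$to)
  })
  deser <- function(o) {
    vocab_deserialize(list(
      dimension = o$dimension, seed = o$seed,
      unitary = o$unitary,
      entries = lapply(o$entries, function(v) as.numeric(unlist(v)))
    ))
  }
  structure(list(
    entries = entries,
    superordinates = as.character(unlist(obj$superordinates)),
    relations = relations,
    vocab_concept = deser(obj$vocabularies$concept),
    vocab_lemma = deser(obj$vocabularies$lemma),
    vocab_phono = deser(obj$vocabularies$phono),
    vocab_deep_concept = deser(obj$vocabularies$deep_concept),
    vocab_deep_phono = deser(obj$vocabularies$deep_phono),
    dimension = as.integer(obj$dimension),
    relatedness_mix = as.numeric(obj$relatedness_mix),
    seed = as.integer(obj$seed)
  ), class = "spa_lexicon")
}
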