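#' Ablation sweep configuration
#'
#' @param task `"wwt"` (picture naming, correct count out of the item set) or
#'   `"demtect"` (word-list repetition, correct count out of the list).
#' @param target component label to ablate.
#' @param fractions ablation fractions; default 0 to 0.9 in steps of 0.1.
#' @param n_repeats repetitions per fraction (default 3), each with a fresh
#'   neural build and a fresh ablation draw.
#' @param base_seed base seed; per-row seeds are derived from
#'   `(base_seed, fraction index, repeat)`.
#' @param lexicon a [generate_lexicon()].
#' @param config a [screening_config()].
#' @param items optional item set for the naming task.
#' @param wordlist optional word list for the repetition task.
#' @export
sweep_config <- function(task = c("wwt", "demtect"), target,
                         fractions = seq(0, 0.9, by = 0.1), n_repeats = 3,
                         base_seed = 1L, lexicon = NULL,
                         config = screening_config(),
                         items = NULL, wordlist = NULL) {
  task <- match.arg(task)
  fractions <- sort(unique(fractions))
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(task = task, target = target, fractions = fractions,
                 n_repeats = n_repeats, base_seed = as.integer(base_seed),
                 lexicon = lexicon, config = config,
                 items = items, wordlist = wordlist),
            class = "sweep_config")
}

#' Run a performance-versus-ablation sweep
#'
#' For every (fraction, repeat) cell an independent model is built, the target
#' component is ablated with a fresh seeded draw, the task is simulated, and
#' the correct-item count recorded. Rows are complete even when the count is
#' zero.
#'
#' @param cfg a [sweep_config()].
#' @param .progress print one line per row.
#' @return an `ablation_sweep` tibble with columns `fraction`, `rep`, `seed`,
#'   `n_correct`, carrying the configuration as attributes.
#' @export
run_sweep <- function(cfg, .progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  lexicon <- cfg$lexicon
  if (is.null(lexicon)) stop("sweep_config needs a lexicon", call. = FALSE)
  probe_model <- build_screening_model(lexicon, cfg$config, seed = 1L)
  known <- c(names(probe_model$net$components), "mem")
  if (!cfg$target %in% known) {
    stop(sprintf("component '%s' is not present in the task's model", cfg$target),
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    fi = seq_along(cfg$fractions),
    rep = seq_len(cfg$n_repeats)
  )
  rows <- purrr::pmap_dfr(grid, function(fi, rep) {
    fraction <- cfg$fractions[fi]
    seed <- derive_seed(cfg$base_seed, fi, rep)
    abl <- list(ablation_spec(cfg$target, fraction))
    trial <- if (cfg$task == "wwt") {
      run_wwt_naming(lexicon, items = cfg$items, ablations = abl,
                     seed = seed, config = cfg$config)
    } else {
      run_demtect_repetition(lexicon, wordlist = cfg$wordlist, ablations = abl,
                             seed = seed, config = cfg$config)
    }
    if (.progress) {
      message(sprintf("  %s %s %.0f%% rep %d -> %d correct",
                      cfg$task, cfg$target, 100 * fraction, rep,
                      n_correct(trial)))
    }
    tibble::tibble(fraction = fraction, rep = rep, seed = seed,
                   n_correct = n_correct(trial))
  })
  structure(rows,
            task = cfg$task, target = cfg$target, base_seed = cfg$base_seed,
            n_items = if (cfg$task == "wwt") {
              if (is.null(cfg$items)) 20L else nrow(cfg$items)
            } else {
              if (is.null(cfg$wordlist)) 10L else length(cfg$wordlist)
            },
            class = c("ablation_sweep", class(rows)))
}

#' @export
print.ablation_sweep <- function(x, ...) {
  cat(sprintf("<ablation_sweep> task '%s', target '%s', %d rows\n",
              attr(x, "task"), attr(x, "target"), nrow(x)))
  NextMethod()
}

#' Per-fraction summary of a sweep
#'
#' @param x an [run_sweep()] result.
#' @param ... unused.
#' @return tibble with per-fraction mean, min and max correct counts.
#' @method tidy ablation_sweep
#' @export
tidy.ablation_sweep <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$fraction),
    mean_correct = mean(.data$n_correct),
    min_correct = min(.data$n_correct),
    max_correct = max(.data$n_correct),
    n = dplyr::n(), .groups = "drop"
  )
}

#' One-row summary of a sweep: onset, floor, pooled median
#'
#' @inheritParams tidy.ablation_sweep
#' @param cutoff cut-off for the proportion of runs above it.
#' @method glance ablation_sweep
#' @export
glance.ablation_sweep <- function(x, cutoff = 11, ...) {
  th <- find_thresholds(x)
  ag <- aggregate_cutoff(x, cutoff)
  tibble::tibble(
    task = attr(x, "task"), target = attr(x, "target"),
    onset = th$onset, floor = th$floor,
    median_correct = ag$median, prop_above_cutoff = ag$proportion,
    cutoff = cutoff
  )
}

#' Pooled cut-off statistics of a sweep
#'
#' Pools all rows (all fractions and repeats, physiological and pathological)
#' and reports the proportion of runs with correct count strictly above
#' `cutoff` and the pooled median (even row counts use the lower-median
#' convention: the n/2-th order statistic).
#'
#' @param result an [run_sweep()] result (or any data frame with `n_correct`).
#' @param cutoff integer cut-off.
#' @return tibble with `proportion` and `median`.
#' @export
aggregate_cutoff <- function(result, cutoff = 11) {
  x <- result$n_correct
  if (length(x) == 0) stop("empty sweep result", call. = FALSE)
  s <- sort(x)
  med <- if (length(s) %% 2 == 1) {
    s[(length(s) + 1) / 2]
  } else {
    s[length(s) / 2]   # lower median
  }
  tibble::tibble(proportion = mean(x > cutoff), median = med)
}

#' Onset and floor of a lesion-response curve
#'
#' Onset: the largest ablation fraction whose per-fraction mean correct count
#' is still at `hi_level` (default: the mean at fraction 0, i.e. performance
#' unaffected). Floor: the smallest fraction whose mean correct count has
#' fallen to `lo_level` or below (default 1). Either is `NA` when never
#' reached.
#'
#' @param result an [run_sweep()] result.
#' @param hi_level unaffected-performance level; default the physiological
#'   (fraction 0) mean.
#' @param lo_level collapsed-performance level (default 1 correct item).
#' @return tibble with `onset` and `floor` (fractions).
#' @export
find_thresholds <- function(result, hi_level = NULL, lo_level = 1) {
  tt <- tidy.ablation_sweep(result)
  if (nrow(tt) < 4) stop("need means at >= 4 fractions", call. = FALSE)
  if (is.null(hi_level)) hi_level <- tt$mean_correct[tt$fraction == min(tt$fraction)]
  ok <- tt$fraction[tt$mean_correct >= hi_level - 1e-9]
  onset <- if (length(ok)) max(ok) else NA_real_
  low <- tt$fraction[tt$mean_correct <= lo_level + 1e-9]
  floorv <- if (length(low)) min(low) else NA_real_
  tibble::tibble(onset = onset, floor = floorv)
}

#' Export / import a sweep
#'
#' CSV (`fraction,rep,seed,n_correct`) or JSON (rows plus recomputable
#' aggregates); re-import reproduces the rows exactly.
#'
#' @param result an [run_sweep()] result.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @export
export_sweep <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  rows <- tibble::as_tibble(result)[, c("fraction", "rep", "seed", "n_correct")]
  if (format == "csv") {
    ok <- tryCatch({
      utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop(sprintf("failed to write sweep to '%s': %s", path,
                   conditionMessage(ok)), call. = FALSE)
    }
  } else {
    obj <- list(task = attr(result, "task"), target = attr(result, "target"),
                rows = rows,
                aggregates = list(
                  per_fraction = tidy.ablation_sweep(result),
                  cutoff11 = aggregate_cutoff(result, 11)
                ))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname export_sweep
#' @param task,target metadata restored onto the imported object (JSON files
#'   carry their own).
#' @export
import_sweep <- function(path, format = c("csv", "json"),
                         task = NA_character_, target = NA_character_) {
  format <- match.arg(format)
  if (format == "csv") {
    rows <- tibble::as_tibble(utils::read.csv(path))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    rows <- tibble::as_tibble(obj$rows)
    task <- obj$task; target <- obj$target
  }
  structure(rows, task = task, target = target,
            class = c("ablation_sweep", class(rows)))
}
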