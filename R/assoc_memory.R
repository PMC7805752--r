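#' Neural associative memory between two vocabularies
#'
#' One thresholded LIF detector population per mapping entry. Each detector
#' receives the dot product of the memory's input with its entry's input
#' pointer and, when that similarity exceeds `threshold`, projects the mapped
#' output pointer with an activity that ramps from 0 to 1 over `ramp`
#' similarity units. The total neuron count is twice that of a standard buffer
#' (`2 * D * n_per_ensemble`), divided evenly among the mapping entries.
#' With `winner_take_all = TRUE` the detectors mutually inhibit so that at most
#' one stays active in steady state — the cleanup-memory subtype that snaps a
#' noisy pointer to its nearest stored entry.
#'
#' @param mapping a data frame with columns `input` and `output` (entry names),
#'   or a named character vector `c(input = output, ...)`.
#' @param input_vocab,output_vocab [spa_vocabulary()] objects containing every
#'   mapped name.
#' @param threshold detection threshold on input similarity (default 0.3).
#' @param winner_take_all add mutual inhibition between detectors.
#' @param label component label.
#' @param n_per_ensemble buffer ensemble size the 2x neuron budget is based on.
#' @param ramp width of the activation ramp above threshold.
#' @param inhibit mutual-inhibition weight used when `winner_take_all`.
#' @param params a [neuron_params()].
#' @param seed integer seed for detector tuning curves.
#' @param reg relative decoder regularisation.
#' @return an object of class `spa_assoc_memory`.
#' @export
build_assoc_memory <- function(mapping, input_vocab, output_vocab,
                               threshold = 0.3, winner_take_all = FALSE,
                               label = "assoc", n_per_ensemble = 50,
                               ramp = 0.15, inhibit = 2.0,
                               params = neuron_params(), seed = 1L, reg = 0.1) {
  if (is.character(mapping) && !is.null(names(mapping))) {
    mapping <- tibble::tibble(input = names(mapping), output = unname(mapping))
  }
  mapping <- tibble::as_tibble(mapping)
  stopifnot(all(c("input", "output") %in% names(mapping)), nrow(mapping) >= 1)
  missing_in <- setdiff(mapping$input, vocab_names(input_vocab))
  missing_out <- setdiff(mapping$output, vocab_names(output_vocab))
  if (length(missing_in)) {
    stop("mapping inputs not in input vocabulary: ",
         paste(missing_in, collapse = ", "), call. = FALSE)
  }
  if (length(missing_out)) {
    stop("mapping outputs not in output vocabulary: ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  }

  M <- nrow(mapping)
  D <- input_vocab$dimension
  n_det <- max(1L, round(2 * D * n_per_ensemble / M))
  N <- M * n_det

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 23L))
  max_rate <- stats::runif(N, params$max_rates[1], params$max_rates[2])
  intercept <- stats::runif(N, threshold, min(threshold + ramp, 0.95))
  gb <- lif_gain_bias(max_rate, intercept, params)

  Ein <- t(vocab_matrix(input_vocab)[, mapping$input, drop = FALSE])    # M x D
  Eout <- t(vocab_matrix(output_vocab)[, mapping$output, drop = FALSE]) # M x Dout

  am <- structure(list(
    label = label, mapping = mapping,
    input_vocab = input_vocab, output_vocab = output_vocab,
    threshold = threshold, ramp = ramp,
    winner_take_all = winner_take_all, inhibit = inhibit,
    M = M, n_det = n_det, D = D, Dout = output_vocab$dimension,
    params = params, seed = as.integer(seed), reg = reg,
    gain = gb$gain, bias = gb$bias,
    det_id = rep(seq_len(M), each = n_det),
    alive = rep(TRUE, N), decoders = numeric(N),
    Ein = Ein, Eout = Eout,
    ablation = NULL, kind = "am"
  ), class = "spa_assoc_memory")
  am$decoders <- am_solve_decoders(am)
  am
}

# detector rates for similarity values s (vector) -> N x length(s)
am_rates_all <- function(am, s) {
  J <- (am$gain) %o% s + am$bias   # encoders are +1 on the similarity axis
  lif_rate(J, am$params)
}

am_solve_decoders <- function(am, n_eval = 160) {
  s <- seq(0, 1.2, length.out = n_eval)
  target <- pmin(pmax((s - am$threshold) / am$ramp, 0), 1)
  R <- am_rates_all(am, s)     # N x P
  n <- am$n_det
  d <- numeric(am$M * n)
  for (j in seq_len(am$M)) {
    idx <- ((j - 1) * n + 1):(j * n)
    A <- t(R[idx, , drop = FALSE])
    d[idx] <- ridge_decoders(A, target, reg = am$reg)
  }
  d
}

# tabulated detector activation a_i(s) honouring the alive mask -> M x G
am_compile_tables <- function(am, n_grid = 41, lo = -0.2, hi = 1.4) {
  grid <- seq(lo, hi, length.out = n_grid)
  R <- am_rates_all(am, grid)
  W <- R * (am$decoders * am$alive)
  tab <- rowsum(W, am$det_id)
  list(grid = grid, table = tab)
}

#' Static response of an associative memory
#'
#' Evaluates the memory's steady-state output for a constant input vector.
#' With winner-take-all, mutual inhibition is settled by damped fixed-point
#' iteration (the dynamical network does the same through its synapses).
#'
#' @param am a [build_assoc_memory()].
#' @param x input vector.
#' @param settle fixed-point iterations for winner-take-all settling.
#' @return list with `activities` (per mapping entry) and `output` (vector in
#'   the output space).
#' @export
am_response <- function(am, x, settle = 80) {
  x <- as_sp_vector(x)
  stopifnot(length(x) == am$D)
  s <- drop(am$Ein %*% x)
  act_of <- function(si) {
    J <- am$gain * si[am$det_id] + am$bias
    r <- lif_rate(J, am$params)
    as.numeric(rowsum(r * am$decoders * am$alive, am$det_id))
  }
  a <- act_of(s)
  if (am$winner_take_all) {
    for (it in seq_len(settle)) {
      inh <- am$inhibit * (sum(a) - a)
      a_new <- act_of(s - inh)
      a <- 0.7 * a + 0.3 * a_new
    }
  }
  list(activities = a, output = drop(crossprod(am$Eout, a)))
}

#' @export
print.spa_assoc_memory <- function(x, ...) {
  cat(sprintf(
    "<spa_assoc_memory> '%s': %d entries x %d neurons = %d (%.1f%% alive)%s\n",
    x$label, x$M, x$n_det, length(x$alive),
    100 * mean(x$alive), if (x$winner_take_all) ", winner-take-all" else ""
  ))
  invisible(x)
}

#' Linear associator transform between two vocabularies
#'
#' The sum of outer products `sum_k out_k %*% t(in_k)` implementing a 1:1
#' mapping as a simple connection weight matrix (no detector thresholding).
#' Used for the level-up associations of the auditory pathway.
#'
#' @inheritParams build_assoc_memory
#' @return a `Dout x Din` matrix.
#' @export
associator_transform <- function(mapping, input_vocab, output_vocab) {
  if (is.character(mapping) && !is.null(names(mapping))) {
    mapping <- tibble::tibble(input = names(mapping), output = unname(mapping))
  }
  Vin <- vocab_matrix(input_vocab)[, mapping$input, drop = FALSE]
  Vout <- vocab_matrix(output_vocab)[, mapping$output, drop = FALSE]
  Vout %*% t(Vin)
}
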