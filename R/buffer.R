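#' Neural buffers
#'
#' A buffer represents one D-dimensional semantic pointer with D independent
#' one-dimensional LIF ensembles of `n_per_ensemble` neurons each (the default
#' 64 x 50 = 3,200 neurons). Encoders are +-1 scalars; decoders are the
#' ridge-regularised least-squares identity decoders of each ensemble. A
#' recurrently connected buffer ([build_gated_memory()]) acts as a gated
#' short-term memory.
#'
#' @name buffers
NULL

#' Build a neural buffer
#'
#' @param label symbol label of the buffer.
#' @param vocab the [spa_vocabulary()] whose pointers the buffer represents.
#' @param n_per_ensemble neurons per one-dimensional ensemble (default 50).
#' @param params a [neuron_params()].
#' @param seed integer seed for the tuning-curve draw.
#' @param radius represented half-range of each ensemble. The default
#'   `4 / sqrt(D)` covers about four standard deviations of the components of
#'   a random unit pointer, which concentrates representational accuracy where
#'   pointer components actually live.
#' @param reg relative decoder regularisation.
#' @return an object of class `spa_buffer`.
#' @export
build_buffer <- function(label, vocab, n_per_ensemble = 50,
                         params = neuron_params(), seed = 1L,
                         radius = NULL, reg = 0.1) {
  stopifnot(n_per_ensemble >= 1, inherits(vocab, "spa_vocabulary"))
  D <- vocab$dimension
  if (is.null(radius)) radius <- 4 / sqrt(D)
  N <- D * n_per_ensemble
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 11L))
  enc <- sample(c(-1, 1), N, replace = TRUE)
  max_rate <- stats::runif(N, params$max_rates[1], params$max_rates[2])
  intercept <- stats::runif(N, params$intercepts[1], params$intercepts[2])
  gb <- lif_gain_bias(max_rate, intercept, params)

  buf <- structure(list(
    label = label, vocab = vocab, D = D, n_per_ensemble = n_per_ensemble,
    params = params, radius = radius, seed = as.integer(seed), reg = reg,
    enc = enc, gain = gb$gain, bias = gb$bias,
    ens_id = rep(seq_len(D), each = n_per_ensemble),
    alive = rep(TRUE, N),
    decoders = numeric(N),
    ablation = NULL,
    kind = "buffer", mode = "rate"
  ), class = "spa_buffer")
  buf$decoders <- buffer_solve_identity_decoders(buf)
  buf
}

# rates of all neurons at normalised points xn (vector), -> N x length(xn)
buffer_rates_all <- function(buf, xn) {
  J <- (buf$gain * buf$enc) %o% xn + buf$bias
  lif_rate(J, buf$params)
}

buffer_solve_identity_decoders <- function(buf, n_eval = 250) {
  xn <- seq(-1, 1, length.out = n_eval)
  R <- buffer_rates_all(buf, xn)            # N x P
  target <- xn * buf$radius
  n <- buf$n_per_ensemble
  d <- numeric(buf$D * n)
  for (j in seq_len(buf$D)) {
    idx <- ((j - 1) * n + 1):(j * n)
    A <- t(R[idx, , drop = FALSE])          # P x n
    d[idx] <- ridge_decoders(A, target, reg = buf$reg)
  }
  d
}

#' Static rate-mode decode of a buffer driven by a constant input
#'
#' Evaluates each neuron's steady-state rate for input vector `u` and returns
#' the decoded D-vector, honouring the alive mask. This is the exact
#' (non-tabulated) buffer response used for verification.
#'
#' @param buf a [build_buffer()].
#' @param u input vector of length D.
#' @export
buffer_decode <- function(buf, u) {
  stopifnot(length(u) == buf$D)
  xn <- pmin(pmax(u / buf$radius, -1.5), 1.5)
  J <- buf$gain * buf$enc * xn[buf$ens_id] + buf$bias
  r <- lif_rate(J, buf$params)
  w <- r * buf$decoders * buf$alive
  as.numeric(rowsum(w, buf$ens_id))
}

# Tabulate the decoded static response of every ensemble on a uniform input
# grid; the simulation engine interpolates these tables. Exact at the nodes.
compile_tables <- function(buf, n_grid = 129, span = 1.5) {
  grid <- seq(-span, span, length.out = n_grid) * buf$radius
  R <- buffer_rates_all(buf, grid / buf$radius)     # N x G
  W <- R * (buf$decoders * buf$alive)
  tab <- rowsum(W, buf$ens_id)                      # D x G
  list(grid = grid, table = tab)
}

#' Build a gated recurrent short-term memory buffer
#'
#' A buffer whose decoded output is fed back to itself through a slow synapse
#' (`synapse_tau`, default 100 ms) with gain `feedback_gain`; with gain 1 it
#' integrates its gated input, which is how bound position-word pairs
#' accumulate as a superposition during list presentation.
#'
#' @inheritParams build_buffer
#' @param feedback_gain recurrent gain in (0, 1.2].
#' @param synapse_tau recurrent synaptic time constant in seconds.
#' @export
build_gated_memory <- function(label, vocab, n_per_ensemble = 50,
                               params = neuron_params(), seed = 1L,
                               radius = NULL, reg = 0.1,
                               feedback_gain = 1.0, synapse_tau = 0.1) {
  if (feedback_gain <= 0 || feedback_gain > 1.2) {
    stop("feedback_gain must be in (0, 1.2]", call. = FALSE)
  }
  buf <- build_buffer(label, vocab, n_per_ensemble, params, seed, radius, reg)
  buf$kind <- "memory"
  buf$feedback_gain <- feedback_gain
  buf$synapse_tau <- synapse_tau
  class(buf) <- c("spa_gated_memory", "spa_buffer")
  buf
}

#' @export
print.spa_buffer <- function(x, ...) {
  n_alive <- sum(x$alive)
  cat(sprintf("<%s> '%s': D = %d, %d x %d = %d neurons (%.1f%% alive)\n",
              class(x)[1], x$label, x$D, x$D, x$n_per_ensemble,
              length(x$alive), 100 * n_alive / length(x$alive)))
  invisible(x)
}

#' Silence a random fraction of a component's neurons
#'
#' `round(fraction * N)` distinct neurons, chosen uniformly at random from the
#' component's full neuron population using `seed`, are silenced: they fire no
#' spikes, carry no bias-driven activity and contribute nothing to any decoded
#' output, for the whole simulation. Decoders are not re-solved (a lesion, not
#' re-learning). Re-applying the same specification is idempotent; a fraction
#' of 0 restores the intact component.
#'
#' @param component a `spa_buffer`, `spa_gated_memory` or `spa_assoc_memory`.
#' @param fraction fraction of neurons to silence, in `[0, 1]`.
#' @param seed integer seed for the neuron selection.
#' @return the modified component.
#' @export
ablate <- function(component, fraction, seed = 1L) {
  UseMethod("ablate")
}

ablate_mask <- function(n_total, fraction, seed) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  k <- round(fraction * n_total)
  alive <- rep(TRUE, n_total)
  if (k > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, 137L))
    alive[sample.int(n_total, k)] <- FALSE
  }
  alive
}

#' @export
ablate.spa_buffer <- function(component, fraction, seed = 1L) {
  component$alive <- ablate_mask(length(component$alive), fraction, seed)
  component$ablation <- list(fraction = fraction, seed = as.integer(seed))
  component
}

#' @export
ablate.spa_assoc_memory <- function(component, fraction, seed = 1L) {
  component$alive <- ablate_mask(length(component$alive), fraction, seed)
  component$ablation <- list(fraction = fraction, seed = as.integer(seed))
  component
}

#' Simulate a single buffer with a constant input
#'
#' Runs one buffer in `rate` or `spiking` mode for `duration` seconds with a
#' constant input current vector, filtering the decoded output through a
#' first-order synapse. Used to verify that the two modes agree at steady
#' state.
#'
#' @param buf a [build_buffer()].
#' @param u constant input vector (length D).
#' @param duration simulated seconds.
#' @param dt time step in seconds.
#' @param mode `"rate"` or `"spiking"`.
#' @param tau_syn output synapse time constant.
#' @param seed seed for the spiking initial membrane voltages.
#' @return matrix of decoded states, one row per step.
#' @export
simulate_buffer <- function(buf, u, duration = 0.5, dt = 0.001,
                            mode = c("rate", "spiking"), tau_syn = 0.01,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(u) == buf$D)
  xn <- pmin(pmax(u / buf$radius, -1.5), 1.5)
  J <- buf$gain * buf$enc * xn[buf$ens_id] + buf$bias
  n_steps <- round(duration / dt)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 31L))
  v0 <- stats::runif(length(J))
  buffer_sim_cpp(J, buf$decoders * buf$alive, as.integer(buf$ens_id),
                 buf$D, n_steps, dt, buf$params$tau_rc, buf$params$tau_ref,
                 tau_syn, mode == "spiking", v0,
                 as.numeric(buf$alive))
}
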