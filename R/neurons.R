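#' Leaky integrate-and-fire neuron parameters
#'
#' Defaults mirror the standard LIF ensemble parameters of mainstream
#' neural-engineering simulators: membrane time constant 20 ms, refractory
#' period 2 ms, maximum firing rates drawn uniformly from 200-400 Hz and
#' intercepts uniformly from \[-1, 1\] of the represented range.
#'
#' @param tau_rc membrane time constant in seconds.
#' @param tau_ref absolute refractory period in seconds.
#' @param max_rates length-2 Hz interval from which per-neuron maximum rates
#'   are drawn.
#' @param intercepts length-2 interval within \[-1, 1\] (relative to the
#'   ensemble radius) from which per-neuron intercepts are drawn.
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(tau_rc = 0.02, tau_ref = 0.002,
                          max_rates = c(200, 400), intercepts = c(-1, 1)) {
  stopifnot(tau_rc > 0, tau_ref > 0,
            length(max_rates) == 2, all(max_rates > 0), max_rates[1] <= max_rates[2],
            length(intercepts) == 2, intercepts[1] <= intercepts[2],
            intercepts[1] >= -1, intercepts[2] <= 1)
  structure(list(tau_rc = tau_rc, tau_ref = tau_ref,
                 max_rates = max_rates, intercepts = intercepts),
            class = "neuron_params")
}

#' LIF steady-state firing rate for input current J
#'
#' `rate = 1 / (tau_ref + tau_rc * log(1 + 1 / (J - 1)))` for `J > 1`, else 0.
#'
#' @param J input current (threshold current is 1).
#' @param params a [neuron_params()].
#' @export
lif_rate <- function(J, params = neuron_params()) {
  r <- numeric(length(J))
  up <- J > 1 + 1e-12
  r[up] <- 1 / (params$tau_ref + params$tau_rc * log1p(1 / (J[up] - 1)))
  dim(r) <- dim(J)
  r
}

# gain (alpha) and bias current so that rate(intercept) = 0 and
# rate(1) = max_rate, on the normalised input axis x in [-1, 1]
lif_gain_bias <- function(max_rate, intercept, params = neuron_params()) {
  z <- 1 / (1 - exp((params$tau_ref - 1 / max_rate) / params$tau_rc))
  gain <- (z - 1) / (1 - intercept)
  bias <- 1 - gain * intercept
  list(gain = gain, bias = bias)
}

#' Build a one-dimensional LIF ensemble
#'
#' An ensemble of `n` LIF neurons encodes a scalar on \[-radius, radius\] with
#' +-1 encoders. Tuning (encoder sign, maximum rate, intercept) is sampled
#' deterministically from `seed`.
#'
#' @param n number of neurons (>= 1).
#' @param seed integer seed.
#' @param params a [neuron_params()].
#' @param radius represented range half-width.
#' @return an object of class `spa_ensemble` with per-neuron `gain`, `bias`,
#'   `enc`.
#' @export
build_ensemble <- function(n, seed, params = neuron_params(), radius = 1) {
  stopifnot(n >= 1, radius > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  enc <- sample(c(-1, 1), n, replace = TRUE)
  max_rate <- stats::runif(n, params$max_rates[1], params$max_rates[2])
  intercept <- stats::runif(n, params$intercepts[1], params$intercepts[2])
  gb <- lif_gain_bias(max_rate, intercept, params)
  structure(list(n = n, enc = enc, gain = gb$gain, bias = gb$bias,
                 max_rate = max_rate, intercept = intercept,
                 params = params, radius = radius, seed = as.integer(seed)),
            class = "spa_ensemble")
}

#' Tuning-curve firing rates of an ensemble
#'
#' @param ens a [build_ensemble()].
#' @param x numeric vector of represented values (in \[-radius, radius\]).
#' @return a `length(x) x n` matrix of firing rates in Hz.
#' @export
tuning_rates <- function(ens, x) {
  xn <- x / ens$radius
  J <- outer(xn, ens$gain * ens$enc) +
    matrix(ens$bias, length(x), ens$n, byrow = TRUE)
  lif_rate(J, ens$params)
}

#' Ridge-regularised least-squares decoders
#'
#' Solves for decoder weights `d` minimising
#' `||A d - y||^2 + m * (reg * max(A))^2 ||d||^2` over `m` evaluation points,
#' the standard NEF decoder problem. A fully silent activity matrix yields
#' all-zero decoders flagged with `attr(, "silent") = TRUE` rather than an
#' error, so fully ablated ensembles still run.
#'
#' @param A `m x n` activity matrix (rates at evaluation points).
#' @param y length-`m` target values (or `m x k` matrix).
#' @param reg relative regularisation (fraction of the maximum rate);
#'   default 0.1.
#' @return decoder vector (or matrix) with `n` rows.
#' @export
ridge_decoders <- function(A, y, reg = 0.1) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (n < 1) stop("need at least one neuron", call. = FALSE)
  amax <- max(A)
  y <- as.matrix(y)
  if (amax <= 0) {
    d <- matrix(0, n, ncol(y))
    attr(d, "silent") <- TRUE
    return(if (ncol(d) == 1) structure(drop(d), silent = TRUE) else d)
  }
  lambda <- m * (reg * amax)^2
  G <- crossprod(A) + diag(lambda, n)
  d <- solve(G, crossprod(A, y))
  if (ncol(d) == 1) drop(d) else d
}

#' Solve decoders for an ensemble and target function
#'
#' @param ens a [build_ensemble()].
#' @param target_function function of the represented value; default identity.
#' @param reg relative ridge regularisation.
#' @param eval_points evaluation points; default a uniform grid of 250 points
#'   over \[-radius, radius\].
#' @export
solve_decoders <- function(ens, target_function = identity, reg = 0.1,
                           eval_points = NULL) {
  if (is.null(eval_points)) {
    eval_points <- seq(-ens$radius, ens$radius, length.out = 250)
  }
  A <- tuning_rates(ens, eval_points)
  if (sum(A) == 0) {
    d <- rep(0, ens$n)
    attr(d, "silent") <- TRUE
    return(d)
  }
  ridge_decoders(A, target_function(eval_points), reg = reg)
}
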