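#' Assemble a semantic-pointer network
#'
#' A network is a collection of components (buffers, gated memories,
#' associative memories) and first-order-synapse connections between them.
#' Connections can carry the identity, a weight matrix, or the circular
#' convolution (binding / unbinding) of two source buffers, and can be gated
#' by named multiplicative gate signals that the task schedule drives.
#'
#' @param dt default simulation time step in seconds.
#' @return an object of class `spa_network`.
#' @export
spa_network <- function(dt = 0.001) {
  structure(list(components = list(), connections = list(),
                 gate_defaults = numeric(0), dt = dt),
            class = "spa_network")
}

#' @export
print.spa_network <- function(x, ...) {
  cat(sprintf("<spa_network> %d components, %d connections, %d gates\n",
              length(x$components), length(x$connections),
              length(x$gate_defaults)))
  invisible(x)
}

#' Add a component to a network
#'
#' Gated memories automatically receive their recurrent feedback connection,
#' gated by `hold_<label>` (default open); driving that gate to 0 resets the
#' memory.
#'
#' @param net a [spa_network()].
#' @param component a `spa_buffer`, `spa_gated_memory` or `spa_assoc_memory`.
#' @export
net_add <- function(net, component) {
  label <- component$label
  if (label %in% names(net$components)) {
    stop(sprintf("component '%s' already in network", label), call. = FALSE)
  }
  net$components[[label]] <- component
  if (inherits(component, "spa_gated_memory")) {
    net <- net_connect(net, label, label,
                       gain = component$feedback_gain,
                       tau = component$synapse_tau,
                       gate = paste0("hold_", label), gate_default = 1)
    # inhibitory output gate: driving act_<label> to 0 resets the memory
    net$gate_defaults[paste0("act_", label)] <- 1
  }
  net
}

#' Connect two components
#'
#' @param net a [spa_network()].
#' @param src,dst component labels.
#' @param transform `NULL` for the identity, or a weight matrix
#'   (`dim(dst input) x dim(src output)`).
#' @param gain scalar gain applied to the connection signal.
#' @param tau synaptic time constant in seconds.
#' @param type `"linear"`, `"bind"` (circular convolution of `src` and `src2`)
#'   or `"unbind"` (convolution of `src` with the involution of `src2`).
#' @param src2 second source label for bind / unbind connections.
#' @param gate optional gate name; the gate's value multiplies the signal.
#' @param gate_default resting value of the gate (1 = open, 0 = closed).
#' @export
net_connect <- function(net, src, dst, transform = NULL, gain = 1,
                        tau = 0.01, type = c("linear", "bind", "unbind"),
                        src2 = NULL, gate = NA_character_, gate_default = 1) {
  type <- match.arg(type)
  for (lab in c(src, dst, src2)) {
    if (!lab %in% names(net$components)) {
      stop(sprintf("unknown component '%s'", lab), call. = FALSE)
    }
  }
  dim_out_of <- function(lab) {
    comp <- net$components[[lab]]
    if (inherits(comp, "spa_assoc_memory")) comp$Dout else comp$D
  }
  dim_in_of <- function(lab) net$components[[lab]]$D
  d_src <- dim_out_of(src)
  d_dst <- dim_in_of(dst)
  if (type == "linear") {
    if (is.null(transform)) {
      if (d_src != d_dst) stop("dimension mismatch for identity connection", call. = FALSE)
    } else {
      transform <- as.matrix(transform)
      if (!all(dim(transform) == c(d_dst, d_src))) {
        stop("transform must be dim(dst) x dim(src)", call. = FALSE)
      }
    }
  } else {
    if (is.null(src2)) stop("bind/unbind connections need src2", call. = FALSE)
    if (dim_out_of(src2) != d_src || d_src != d_dst) {
      stop("bind/unbind requires equal dimensions", call. = FALSE)
    }
  }
  if (!is.na(gate) && !(gate %in% names(net$gate_defaults))) {
    net$gate_defaults[gate] <- gate_default
  }
  net$connections[[length(net$connections) + 1]] <- list(
    src = src, dst = dst, src2 = src2, type = type,
    transform = transform, gain = gain, tau = tau, gate = gate
  )
  net
}

#' Replace a component (e.g. after ablation)
#'
#' @param net a [spa_network()].
#' @param component component carrying the same label as the one to replace.
#' @export
net_set_component <- function(net, component) {
  if (!component$label %in% names(net$components)) {
    stop(sprintf("unknown component '%s'", component$label), call. = FALSE)
  }
  net$components[[component$label]] <- component
  net
}

compile_component <- function(comp, gate_names = character(0)) {
  ogate <- if (inherits(comp, "spa_gated_memory")) {
    match(paste0("act_", comp$label), gate_names) - 1L
  } else {
    -1L
  }
  if (is.na(ogate)) ogate <- -1L
  if (inherits(comp, "spa_assoc_memory")) {
    ct <- am_compile_tables(comp)
    list(kind = 1L, dim_in = comp$D, dim_out = comp$Dout, ogate = ogate,
         grid = ct$grid, table = ct$table,
         Ein = comp$Ein, Eout = comp$Eout,
         wta = if (comp$winner_take_all) comp$inhibit else 0,
         tau_inh = 0.005)
  } else {
    ct <- compile_tables(comp)
    list(kind = 0L, dim_in = comp$D, dim_out = comp$D, ogate = ogate,
         grid = ct$grid, table = ct$table)
  }
}

#' Run a network simulation
#'
#' @param net a [spa_network()].
#' @param duration simulated seconds.
#' @param inputs a data frame of clamp events with columns `component`,
#'   `pointer` (an entry name in the component's vocabulary, or a numeric
#'   vector in a list column), `t_on`, `t_off` and optionally `gain`.
#' @param gate_events optional data frame with columns `gate`, `t_on`, `t_off`,
#'   `value` overriding gate defaults during the given interval.
#' @param probes character vector of component labels whose decoded state is
#'   recorded.
#' @param dt time step; defaults to the network's.
#' @param record_every record every k-th step.
#' @return an object of class `spa_simulation`: named list of probe matrices
#'   (`steps x D`) plus the time grid.
#' @export
run_network <- function(net, duration, inputs = NULL, gate_events = NULL,
                        probes = character(0), dt = NULL, record_every = 1L) {
  if (is.null(dt)) dt <- net$dt
  n_steps <- as.integer(round(duration / dt))
  labels <- names(net$components)
  comp_idx <- stats::setNames(seq_along(labels) - 1L, labels)

  gate_names <- names(net$gate_defaults)
  comps <- lapply(net$components, compile_component, gate_names = gate_names)
  n_gates <- length(gate_names)
  gates_mat <- matrix(rep(net$gate_defaults, n_steps), nrow = max(n_gates, 1))
  if (n_gates == 0) gates_mat <- matrix(0, 1, n_steps)
  if (!is.null(gate_events) && nrow(gate_events) > 0) {
    for (i in seq_len(nrow(gate_events))) {
      g <- match(gate_events$gate[i], gate_names)
      if (is.na(g)) stop(sprintf("unknown gate '%s'", gate_events$gate[i]), call. = FALSE)
      on <- max(1L, as.integer(round(gate_events$t_on[i] / dt)) + 1L)
      off <- min(n_steps, as.integer(round(gate_events$t_off[i] / dt)))
      if (off >= on) gates_mat[g, on:off] <- gate_events$value[i]
    }
  }

  conns <- lapply(net$connections, function(cn) {
    type_code <- switch(cn$type, linear = if (is.null(cn$transform)) 0L else 1L,
                        bind = 2L, unbind = 3L)
    list(src = unname(comp_idx[cn$src]), dst = unname(comp_idx[cn$dst]),
         src2 = if (is.null(cn$src2)) -1L else unname(comp_idx[cn$src2]),
         type = type_code,
         transform = if (type_code == 1L) cn$transform else matrix(0, 1, 1),
         gain = cn$gain, tau = cn$tau,
         gate = if (is.na(cn$gate)) -1L else match(cn$gate, gate_names) - 1L)
  })

  if (is.null(inputs) || nrow(inputs) == 0) {
    ext_comp <- integer(0); ext_on <- integer(0); ext_off <- integer(0)
    ext_vec <- matrix(0, 0, 1)
  } else {
    if (!"gain" %in% names(inputs)) inputs$gain <- 1
    dmax <- max(vapply(net$components, function(x) x$D, 1L))
    ext_vec <- matrix(0, nrow(inputs), dmax)
    ext_comp <- integer(nrow(inputs)); ext_on <- integer(nrow(inputs))
    ext_off <- integer(nrow(inputs))
    for (i in seq_len(nrow(inputs))) {
      lab <- inputs$component[i]
      if (!lab %in% labels) stop(sprintf("unknown component '%s'", lab), call. = FALSE)
      comp <- net$components[[lab]]
      p <- inputs$pointer[[i]]
      v <- if (is.character(p)) vocab_get(comp$vocab, p)$v else as_sp_vector(p)
      if (length(v) != comp$D) stop("input vector dimension mismatch", call. = FALSE)
      ext_vec[i, seq_along(v)] <- v * inputs$gain[i]
      ext_comp[i] <- unname(comp_idx[lab])
      ext_on[i] <- as.integer(round(inputs$t_on[i] / dt))
      ext_off[i] <- as.integer(round(inputs$t_off[i] / dt))
    }
  }

  probe_idx <- unname(comp_idx[probes])
  if (anyNA(probe_idx)) stop("unknown probe label", call. = FALSE)

  raw <- engine_run_cpp(comps, conns, ext_comp, ext_on, ext_off, ext_vec,
                        gates_mat, n_steps, dt, as.integer(probe_idx),
                        as.integer(record_every))
  names(raw) <- probes
  time <- (seq_len(nrow(raw[[1]])) - 1L) * dt * record_every
  structure(list(probes = raw, time = time, dt = dt,
                 record_every = record_every,
                 labels = labels),
            class = "spa_simulation")
}

#' @export
print.spa_simulation <- function(x, ...) {
  cat(sprintf("<spa_simulation> %.3f s, dt = %g s, probes: %s\n",
              max(x$time), x$dt, paste(names(x$probes), collapse = ", ")))
  invisible(x)
}

#' Similarity trajectories of a probed buffer
#'
#' For every recorded time step and vocabulary entry, the dot product of the
#' entry's pointer with the buffer's decoded state. With `normalize = TRUE`
#' (the plotting convention) the state is first scaled to its unit direction;
#' a decoded state of exactly zero norm yields a row of zeros.
#'
#' @param sim a [run_network()] result.
#' @param component probed component label.
#' @param vocab vocabulary to compare against.
#' @param normalize compare against the unit direction of the state rather
#'   than the raw state.
#' @return a tibble with `time` and one column per pointer name.
#' @export
decode_similarities <- function(sim, component, vocab, normalize = TRUE) {
  X <- sim$probes[[component]]
  if (is.null(X)) stop(sprintf("component '%s' was not probed", component), call. = FALSE)
  V <- vocab_matrix(vocab)
  if (normalize) {
    nrm <- sqrt(rowSums(X^2))
    scale <- ifelse(nrm > 1e-9, 1 / nrm, 0)
    X <- X * scale
  }
  S <- X %*% V
  colnames(S) <- vocab_names(vocab)
  out <- dplyr::bind_cols(tibble::tibble(time = sim$time), tibble::as_tibble(S))
  class(out) <- c("spa_similarity", class(out))
  out
}

#' Export a similarity trajectory as a tab-separated table
#'
#' First column is time in seconds (6 decimals), remaining columns one per
#' pointer name.
#'
#' @param sims a [decode_similarities()] tibble.
#' @param path output file path.
#' @export
write_trajectory_tsv <- function(sims, path) {
  out <- sims
  out$time <- sprintf("%.6f", out$time)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Architecture summary of a network
#'
#' @param net a [spa_network()].
#' @return a tibble with one row per component: label, kind, neuron count and
#'   alive fraction.
#' @export
network_summary <- function(net) {
  purrr::map_dfr(net$components, function(comp) {
    tibble::tibble(label = comp$label,
                   kind = if (inherits(comp, "spa_assoc_memory")) "assoc_memory"
                          else if (inherits(comp, "spa_gated_memory")) "gated_memory"
                          else "buffer",
                   neurons = length(comp$alive),
                   alive_fraction = mean(comp$alive))
  })
}

#' Dump the model architecture as JSON
#'
#' @param net a [spa_network()].
#' @param path output path.
#' @export
write_architecture_json <- function(net, path) {
  jsonlite::write_json(network_summary(net), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
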