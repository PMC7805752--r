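#' Semantic-pointer algebra
#'
#' Semantic pointers are named unit vectors in `R^D`. A vocabulary collects
#' pointers of a common dimensionality and owns the random stream from which
#' they are drawn, so that a `(seed, insertion index)` pair always yields the
#' same vector. Binding is circular convolution, unbinding is binding with the
#' index-involution approximate inverse, and similarity is the Euclidean dot
#' product.
#'
#' @name vsa
NULL

#' Mix integer seeds into a derived seed
#'
#' Deterministic seed derivation used throughout the package so that every
#' random draw is reproducible from one base seed. Kept below 2^31.
#'
#' @param ... integers to mix.
#' @return a single integer seed.
#' @export
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  stopifnot(length(parts) >= 1, all(is.finite(parts)))
  acc <- 0
  for (p in parts) {
    acc <- (acc * 69069 + (p %% 2147483647) + 1) %% 2147483647
  }
  as.integer(acc)
}

unit_vector_from_seed <- function(d, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Create an empty vocabulary of semantic pointers
#'
#' @param dimension positive integer `D`; all pointers in the vocabulary share
#'   this dimensionality (64 in the screening model).
#' @param seed integer seed owning the vocabulary's random stream.
#' @return an object of class `spa_vocabulary`. The object is
#'   environment-backed: [add_pointer()] and friends register entries in place.
#' @examples
#' v <- spa_vocabulary(64, seed = 1)
#' a <- add_pointer(v, "A")
#' b <- add_pointer(v, "B")
#' vsa_similarity(a, b)
#' @export
spa_vocabulary <- function(dimension, seed = 1L) {
  stopifnot(is.numeric(dimension), dimension >= 1)
  env <- new.env(parent = emptyenv())
  env$dimension <- as.integer(dimension)
  env$seed <- as.integer(seed)
  env$names <- character(0)
  # D x n matrix of pointer vectors, one column per entry, insertion order
  env$vectors <- matrix(numeric(0), nrow = dimension, ncol = 0)
  env$unitary <- logical(0)
  class(env) <- "spa_vocabulary"
  env
}

#' @export
print.spa_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<spa_vocabulary> D = %d, %d entries, seed = %d\n",
    x$dimension, length(x$names), x$seed
  ))
  if (length(x$names)) {
    shown <- utils::head(x$names, 8)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$names) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.spa_vocabulary <- function(x) length(x$names)

vocab_check_new_name <- function(vocab, name) {
  stopifnot(inherits(vocab, "spa_vocabulary"), is.character(name), length(name) == 1)
  if (name %in% vocab$names) {
    stop(sprintf("pointer name '%s' already exists in vocabulary", name), call. = FALSE)
  }
}

vocab_register <- function(vocab, name, v, unitary = FALSE) {
  vocab$names <- c(vocab$names, name)
  vocab$vectors <- cbind(vocab$vectors, v)
  colnames(vocab$vectors) <- vocab$names
  vocab$unitary <- c(vocab$unitary, unitary)
  semantic_pointer(name, v)
}

semantic_pointer <- function(name, v) {
  structure(list(name = name, v = as.numeric(v)), class = "semantic_pointer")
}

#' @export
print.semantic_pointer <- function(x, ...) {
  cat(sprintf("<semantic_pointer> '%s', D = %d, norm = %.6f\n",
              x$name, length(x$v), sqrt(sum(x$v^2))))
  invisible(x)
}

as_sp_vector <- function(x) {
  if (inherits(x, "semantic_pointer")) x$v else as.numeric(x)
}

#' Add a random unit pointer to a vocabulary
#'
#' Components are drawn i.i.d. Gaussian and the vector is normalised to unit
#' norm. The draw is deterministic given the vocabulary seed and the entry's
#' insertion index.
#'
#' @param vocab a [spa_vocabulary()].
#' @param name unique symbol label.
#' @return the new `semantic_pointer` (invisibly registered in `vocab`).
#' @export
add_pointer <- function(vocab, name) {
  vocab_check_new_name(vocab, name)
  idx <- length(vocab$names) + 1L
  v <- unit_vector_from_seed(vocab$dimension, derive_seed(vocab$seed, idx))
  vocab_register(vocab, name, v)
}

#' Add a unitary pointer (norm-preserving under binding)
#'
#' A unitary pointer has unit magnitude at every frequency of its discrete
#' Fourier spectrum, so circular convolution with it is norm-preserving and
#' exactly invertible. Used for the ordinal position pointers of the word-list
#' memory, so bound list items can be recovered without norm distortion.
#'
#' @inheritParams add_pointer
#' @export
add_unitary_pointer <- function(vocab, name) {
  vocab_check_new_name(vocab, name)
  idx <- length(vocab$names) + 1L
  d <- vocab$dimension
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(vocab$seed, idx, 77L))
  # random phases with conjugate symmetry -> real vector with |FFT| == 1
  half <- floor(d / 2)
  phases <- numeric(d)
  phases[1] <- sample(c(0, pi), 1)   # DC component is +-1
  if (d %% 2 == 0) phases[half + 1] <- sample(c(0, pi), 1)
  k <- seq_len(half - if (d %% 2 == 0) 1 else 0)
  ph <- stats::runif(length(k), -pi, pi)
  phases[1 + k] <- ph
  phases[d + 1 - k] <- -ph
  spec <- exp(1i * phases)
  v <- Re(stats::fft(spec, inverse = TRUE)) / d
  v <- v / sqrt(sum(v^2))  # numerically exact unit norm
  vocab_register(vocab, name, v, unitary = TRUE)
}

#' Add a pointer related to an existing one
#'
#' The new pointer is `normalize(mix * base + (1 - mix) * r)` with `r` a fresh
#' random unit vector, so lexical relations (same category, association) show
#' up as above-chance similarity between pointers.
#'
#' @inheritParams add_pointer
#' @param base name of an existing entry, or a `semantic_pointer`.
#' @param mix mixing coefficient in `[0, 1]`; 0 gives an unrelated pointer,
#'   1 duplicates the base direction.
#' @export
add_related_pointer <- function(vocab, name, base, mix) {
  vocab_check_new_name(vocab, name)
  if (mix < 0 || mix > 1) stop("mix must be in [0, 1]", call. = FALSE)
  base_v <- if (inherits(base, "semantic_pointer")) {
    base$v
  } else {
    vocab_get(vocab, base)$v
  }
  idx <- length(vocab$names) + 1L
  r <- unit_vector_from_seed(vocab$dimension, derive_seed(vocab$seed, idx))
  v <- mix * base_v + (1 - mix) * r
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate mixture; base and noise cancelled", call. = FALSE)
  vocab_register(vocab, name, v / n)
}

#' Retrieve a pointer from a vocabulary
#' @inheritParams add_pointer
#' @export
vocab_get <- function(vocab, name) {
  stopifnot(inherits(vocab, "spa_vocabulary"))
  j <- match(name, vocab$names)
  if (is.na(j)) stop(sprintf("no pointer named '%s' in vocabulary", name), call. = FALSE)
  semantic_pointer(name, vocab$vectors[, j])
}

#' @rdname vocab_get
#' @export
vocab_names <- function(vocab) vocab$names

#' @rdname vocab_get
#' @export
vocab_matrix <- function(vocab) vocab$vectors

#' Circular-convolution binding of two pointers
#'
#' Computed via the FFT; commutative; the output is not renormalised.
#'
#' @param a,b numeric vectors or `semantic_pointer`s of equal dimension.
#' @return numeric vector of the same dimension.
#' @export
vsa_bind <- function(a, b) {
  a <- as_sp_vector(a); b <- as_sp_vector(b)
  if (length(a) != length(b)) stop("dimension mismatch in vsa_bind", call. = FALSE)
  Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / length(a)
}

#' Index-involution approximate inverse
#'
#' Component 0 is fixed and the remaining components are reversed; binding a
#' pointer with its involution approximates the identity element.
#'
#' @param a numeric vector or `semantic_pointer`.
#' @export
vsa_inverse <- function(a) {
  a <- as_sp_vector(a)
  c(a[1], rev(a[-1]))
}

#' Unbind: bind with the approximate inverse
#'
#' `vsa_unbind(vsa_bind(a, b), b)` approximately recovers `a`; exactly so when
#' `b` is unitary.
#'
#' @param x,b numeric vectors or `semantic_pointer`s of equal dimension.
#' @export
vsa_unbind <- function(x, b) {
  vsa_bind(x, vsa_inverse(b))
}

#' Superpose (sum) pointers
#'
#' @param vectors a list of numeric vectors / `semantic_pointer`s.
#' @param normalize if `TRUE`, scale the sum to unit norm (the zero vector is
#'   left as zero).
#' @export
vsa_superpose <- function(vectors, normalize = FALSE) {
  if (!is.list(vectors) || length(vectors) == 0) {
    stop("vectors must be a nonempty list", call. = FALSE)
  }
  vs <- lapply(vectors, as_sp_vector)
  d <- unique(lengths(vs))
  if (length(d) != 1) stop("dimension mismatch in vsa_superpose", call. = FALSE)
  s <- Reduce(`+`, vs)
  if (normalize) {
    n <- sqrt(sum(s^2))
    if (n > 1e-12) s <- s / n
  }
  s
}

#' Dot-product similarity
#'
#' @param a,b numeric vectors or `semantic_pointer`s of equal dimension.
#' @export
vsa_similarity <- function(a, b) {
  a <- as_sp_vector(a); b <- as_sp_vector(b)
  if (length(a) != length(b)) stop("dimension mismatch in vsa_similarity", call. = FALSE)
  sum(a * b)
}

#' Mathematical cleanup: snap a vector to its nearest vocabulary entry
#'
#' Returns the name of the vocabulary entry with maximal dot-product similarity
#' to `x`, provided that maximum reaches `threshold`; otherwise `NA`. Ties are
#' broken by vocabulary insertion order. This is the mathematical oracle the
#' neural cleanup memories are tested against.
#'
#' @param x numeric vector or `semantic_pointer`.
#' @param vocab a [spa_vocabulary()].
#' @param threshold acceptance threshold in `(0, 1]`; the default 0.3 is about
#'   2.4 standard deviations of the similarity of two random unit vectors at
#'   D = 64, so noiseless entries always pass and random vectors essentially
#'   never do.
#' @return entry name, or `NA_character_` if nothing reaches threshold.
#' @export
cleanup_oracle <- function(x, vocab, threshold = 0.3) {
  stopifnot(inherits(vocab, "spa_vocabulary"))
  if (length(vocab$names) == 0) stop("empty vocabulary", call. = FALSE)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]", call. = FALSE)
  x <- as_sp_vector(x)
  sims <- drop(crossprod(vocab$vectors, x))
  j <- which.max(sims)  # which.max is first-maximum = insertion order tie-break
  if (sims[j] >= threshold - 1e-9) vocab$names[j] else NA_character_
}

#' Serialize a vocabulary to JSON
#'
#' Round-trips at full double precision (>= 15 significant digits).
#'
#' @param vocab a [spa_vocabulary()].
#' @param path file path.
#' @export
write_vocab_json <- function(vocab, path) {
  entries <- stats::setNames(
    lapply(seq_along(vocab$names), function(j) vocab$vectors[, j]),
    vocab$names
  )
  obj <- list(
    dimension = vocab$dimension,
    seed = vocab$seed,
    unitary = stats::setNames(as.list(vocab$unitary), vocab$names),
    entries = entries
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vocab_json
#' @export
read_vocab_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- spa_vocabulary(obj$dimension, seed = obj$seed)
  nm <- names(obj$entries)
  for (j in seq_along(nm)) {
    vec <- as.numeric(obj$entries[[j]])
    unitary <- isTRUE(as.logical(obj$unitary[[nm[j]]]))
    vocab_register(v, nm[j], vec, unitary = unitary)
  }
  v
}
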