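#' Deterministic random streams
#'
#' All randomness in the package flows through explicit stream objects so
#' that a single master seed reproduces every augmentation draw, weight
#' initialisation, shuffle and split bit-for-bit, regardless of what the
#' caller's global RNG is doing. A stream owns a private Mersenne-Twister
#' state; every draw swaps that state into `.Random.seed` and back, leaving
#' the user's RNG untouched.
#'
#' @param seed integer master seed (any finite number; reduced mod 2^31 - 1).
#' @return an object of class `rng_stream`.
#' @seealso [rng_substream()] for derived, decorrelated child streams.
#' @export
#' @examples
#' s <- rng_stream(7)
#' rs_runif(s, 3)
rng_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(abs(seed) %% 2147483646) + 1L
  old <- .GlobalEnv$.Random.seed
  set.seed(env$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  env$state <- get(".Random.seed", envir = .GlobalEnv)
  if (is.null(old)) {
    rm(".Random.seed", envir = .GlobalEnv)
  } else {
    assign(".Random.seed", old, envir = .GlobalEnv)
  }
  class(env) <- "rng_stream"
  env
}

#' Derive a decorrelated child stream
#'
#' Children are keyed by integer coordinates (e.g. image index, view index,
#' epoch) through a Lehmer-style integer mix, so data-loading order cannot
#' reorder randomness: view 2 of image 17 in epoch 3 always sees the same
#' draws under a given master seed.
#'
#' @param parent an `rng_stream` or a single integer seed.
#' @param ... integer keys identifying the substream.
#' @return a new `rng_stream`.
#' @export
rng_substream <- function(parent, ...) {
  h <- if (inherits(parent, "rng_stream")) parent$seed else {
    if (!is.numeric(parent) || length(parent) != 1L)
      stop("'parent' must be an rng_stream or a single seed")
    as.numeric(abs(parent) %% 2147483647)
  }
  h <- as.numeric(h)
  keys <- as.numeric(c(...))
  # Lehmer-style mixing; all intermediates stay below 2^53 so doubles are exact
  for (k in keys) {
    h <- (h * 48271 + (abs(k) %% 2147483647) * 16807 + 104729) %% 2147483647
  }
  rng_stream(h)
}

# Evaluate `expr` under the stream's private RNG state.
rs_eval <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- .GlobalEnv$.Random.seed
  assign(".Random.seed", stream$state, envir = .GlobalEnv)
  on.exit({
    stream$state <- get(".Random.seed", envir = .GlobalEnv)
    if (is.null(old)) {
      rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  expr
}

#' Draw from a stream
#'
#' Thin wrappers over the base generators that consume a stream's private
#' state: uniform, normal, integer sample without replacement, and a single
#' Bernoulli event.
#'
#' @param stream an [rng_stream()].
#' @param n number of draws.
#' @param min,max,mean,sd distribution parameters as in [stats::runif()] /
#'   [stats::rnorm()].
#' @return numeric vector of draws (`rs_bernoulli` returns a single logical).
#' @name stream-draws
#' @export
rs_runif <- function(stream, n, min = 0, max = 1)
  rs_eval(stream, stats::runif(n, min, max))

#' @rdname stream-draws
#' @export
rs_rnorm <- function(stream, n, mean = 0, sd = 1)
  rs_eval(stream, stats::rnorm(n, mean, sd))

#' @rdname stream-draws
#' @param k upper bound; samples from `1:k`.
#' @param size sample size.
#' @param replace sample with replacement?
#' @export
rs_sample_int <- function(stream, k, size = 1, replace = FALSE)
  rs_eval(stream, sample.int(k, size, replace = replace))

#' @rdname stream-draws
#' @param p success probability.
#' @export
rs_bernoulli <- function(stream, p) rs_runif(stream, 1L) < p

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream seed=", x$seed, ">\n", sep = "")
  invisible(x)
}
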