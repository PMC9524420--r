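# Internal helpers shared across modules.

# Wrap angles into [0, 2*pi). R's %% already returns a non-negative value
# for a positive modulus.
.wrap_phase <- function(phi) phi %% (2 * pi)

#' Derive a stream of child seeds from one master seed
#'
#' One global seed fans out to per-stage (and per-epoch) child seeds through
#' a fixed multiplicative congruential rule, so every stage of a pipeline is
#' individually reproducible from the master seed alone. All seeds stay
#' below 2^31 - 1.
#'
#' @param seed Master seed (single integer-valued number).
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`.
#' @export
#' @examples
#' split_seed(42, 3)
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), n >= 1)
  m <- 2147483647
  s <- (abs(as.double(seed)) %% (m - 1)) + 1
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (48271 * s) %% m
    out[i] <- as.integer(s)
  }
  out
}

# stop() with a class so callers/tests can match specific failure modes
.err <- function(class, msg, ...) {
  stop(structure(class = c(class, "ssvepkit_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
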