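# Internal helpers: seeded RNG scoping and counter-based seed splitting.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps all generators deterministic and
# side-effect free with respect to the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a master seed and one or more integer counters.
# Multiplicative mixing keeps derived streams distinct for distinct counters
# while staying inside the 32-bit signed integer range.
split_seed <- function(seed, ...) {
  counters <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in counters) {
    h <- (h * 48271 + as.numeric(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Midpoint-rounded integer pixel coordinate (1-based) from a continuous
# coordinate in pixel units.
px_index <- function(x) as.integer(round(x))
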