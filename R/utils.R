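# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

assert_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_config(field, sprintf("must be a whole number >= %d", min))
  as.integer(x)
}

assert_number <- function(x, field, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    lb <- if (open_lower) paste0("(", lower) else paste0("[", lower)
    ub <- if (open_upper) paste0(upper, ")") else paste0(upper, "]")
    stop_config(field, sprintf("must be a number in %s, %s", lb, ub))
  }
  as.numeric(x)
}

# run code with a private, restored RNG state so generators are pure
# functions of (config, seed) and never disturb the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a per-iteration random seed
#'
#' Deterministic stream splitting: the seed for iteration `i` is a pure
#' function of `(base_seed, i)`, so iterations can be computed in any order
#' (or concurrently) with identical results. The value always fits in a
#' signed 32-bit integer.
#'
#' @param base_seed integer base seed.
#' @param i iteration index (1-based) or any non-negative offset.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, i) {
  base_seed <- assert_count(base_seed, "base_seed", min = 0L)
  i <- assert_count(i, "i", min = 0L)
  # Lehmer-style mix kept in double precision (exact below 2^53)
  as.integer((as.double(base_seed) * 48271 + as.double(i) * 16807) %%
               2147483646) + 1L
}

# empirical percentiles, estimator exposed for the aggregation module
pctl <- function(x, probs = c(2.5, 50, 97.5), type = 7) {
  stats::quantile(x, probs = probs / 100, type = type, names = FALSE, na.rm = TRUE)
}

as_date <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}
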