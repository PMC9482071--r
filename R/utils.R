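#' @importFrom stats rnorm runif rbinom rpois pnorm dnorm
#' @importFrom utils head tail
NULL

# Run code under a temporary RNG state so callers' streams are untouched.
# All user-facing randomness in the package goes through an explicit `seed`
# argument routed here; identical seed => identical result.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# C-locale (radix) sort: stable across platforms and locales.
sort_c <- function(x) sort(x, method = "radix")

# Row-wise softmax of a matrix, numerically stabilised.
row_softmax <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# Row-wise log-softmax.
row_log_softmax <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  s <- x - m
  s - log(rowSums(exp(s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

triple_key <- function(h, r, t) paste(h, r, t, sep = "\x1f")
pair_key <- function(a, b) paste(a, b, sep = "\x1f")
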