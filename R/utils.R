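#' @useDynLib dispersim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef cor cor.test t.test aov TukeyHSD dnorm filter
#'   splinefun isoreg rnorm runif quantile sd complete.cases
#' @importFrom utils read.csv write.csv packageVersion head tail
#' @keywords internal
"_PACKAGE"

# classed condition helper: every user-facing error carries a class that
# tests and callers can match on, plus "dispersim_error"
ds_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "dispersim_error"),
                      call = call))
}

ds_warn <- function(msg, class = "dispersim_warning") {
  warning(warningCondition(msg, class = c(class, "dispersim_warning")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All generators route their randomness here so
# that identical (spec, seed) gives bit-identical output regardless of the
# surrounding RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    ds_stop("seed must be a single integer", "invalid_spec")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a global seed
#'
#' Deterministic splitting rule used by [run_scenario()] to hand each module
#' its own independent stream: `child = (seed * 48271 + index) mod (2^31-1)`,
#' a Lehmer-style mix that keeps results inside R's 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param index non-negative integer module index.
#' @return a single integer seed.
#' @export
child_seed <- function(seed, index) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(index)) %% m)
}

# shoelace area of a closed polygon given vertex coordinates
polygon_area <- function(x, y) {
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}
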