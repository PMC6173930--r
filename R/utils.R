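#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded operations inside the package never perturb the user's random
#' stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named seed substream from a global seed
#'
#' Every stochastic stage of the pipeline draws its seed through this
#' function so that a single global seed determines all randomness while
#' stages (and individual bootstrap replicates) can be re-run in isolation
#' with identical streams. The derivation is a fixed 31-bit linear hash of
#' `(seed, label, index)`; results are always in `[0, 2^31 - 2]`.
#'
#' @param seed Integer global seed.
#' @param label Character stream label, e.g. `"simulate"` or `"boot-03"`.
#' @param index Optional non-negative integer within-stream index.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, label, index = 0L) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% m
  s <- as.numeric(seed) %% m
  as.integer((s * 48271 + h * 7919 + as.numeric(index) * 69621) %% m)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x > 0 && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed-format numeric rendering used by all writers so that re-running a
# pipeline byte-reproduces its outputs.
format_num <- function(x) sprintf("%.10g", x)
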