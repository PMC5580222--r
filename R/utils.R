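#' @keywords internal
"_PACKAGE"

# Run code with a locally-seeded Mersenne-Twister RNG, restoring the caller's
# RNG state afterwards.  All stochastic code in the package funnels through
# this so that (config, seed) -> output is reproducible.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# Derive a per-stage seed from a global one without exceeding .Machine 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 97L + as.integer(offset)) %% 2147483587L
}

stop_radsig <- function(fmt, ..., class = "radsig_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

warn_radsig <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
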