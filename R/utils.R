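#' @importFrom stats var sd median quantile rnorm runif setNames optimize
#'   prcomp predict sd wilcox.test complete.cases qnorm
#' @importFrom utils head tail
NULL

# Derive a stage-scoped seed from a master seed and a text tag.
# Keeps results reproducible from one master integer while decorrelating
# stages; always returns a value in [1, 2^31 - 2].
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  val <- (as.double(master) * 48271 + h * 16807) %% (2^31 - 1)
  as.integer(max(1, val))
}

# Run an expression under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population (biased, 1/n) central moments used throughout the histogram
# feature family.
pop_moment <- function(x, k) {
  mean((x - mean(x))^k)
}
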