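#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm pnorm qnorm rnorm rpois runif rlnorm quantile sd
#'   var cor lm coef kmeans wilcox.test t.test rbinom aggregate complete.cases
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL leaves the current stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Derive a stage-specific child seed from a base seed (kept < 2^31).
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + offset) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
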