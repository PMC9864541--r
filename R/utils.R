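#' @importFrom rlang %||% abort warn .data
#' @importFrom stats qnorm pnorm plogis qlogis rnorm runif rbinom rchisq
#'   sd var cor cor.test quantile weighted.mean complete.cases setNames
#'   model.matrix coef
#' @importFrom utils head
NULL

# Derive a reproducible 31-bit substream seed from a master seed and an
# index path, so every stochastic stage (replicate, method, chain) gets an
# independent, replayable stream.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 16807 + 11) %% 2147483629
  }
  as.integer(s %% 2147483629)
}

# Run code under a fixed seed when one is supplied; otherwise use the
# session RNG stream untouched.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Standardize a numeric vector to mean 0, sd 1; a zero-variance column has
# no defined scale and is rejected.
standardize <- function(x, label = "predictor") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("zero-variance %s: standardization undefined", label))
  }
  (x - mean(x)) / s
}

is_categorical <- function(vtype) vtype %in% c("binary", "nominal", "ordinal")

# Numeric coding used for screening/association checks: factors by level
# index, numerics as-is.
numeric_code <- function(x) {
  if (is.factor(x)) as.numeric(as.integer(x)) else as.numeric(x)
}
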