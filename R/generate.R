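#' Generate a complete "full sample" population
#'
#' Draws `n` rows from a Gaussian copula: a latent multivariate normal
#' vector with the spec's correlation matrix is mapped coordinate-wise
#' through each variable's monotone link. Continuous variables use an
#' identity (location/scale) or exponential (lognormal) link; categorical
#' variables are thresholded at standard-normal quantiles of their
#' cumulative prevalences; semicontinuous variables use a two-part link —
#' an exact zero when the latent uniform falls below `zero_mass`, otherwise
#' a lognormal positive part driven by the renormalized upper tail, so the
#' whole map stays monotone in the latent coordinate.
#'
#' The output is fully observed; amputation is a separate, later step.
#'
#' @param spec A [population_spec()].
#' @param n Sample size (defaults to the spec's).
#' @param seed Integer seed (defaults to the spec's); the draw is
#'   deterministic given spec and seed.
#' @return A tibble with `n` rows, one column per schema variable
#'   (categorical columns as factors), with the schema attached as the
#'   `"schema"` attribute.
#' @examples
#' spec <- brfss_like_spec(seed = 1)
#' pop <- generate_population(spec, n = 500)
#' dplyr::glimpse(pop)
#' @export
generate_population <- function(spec, n = spec$n, seed = spec$seed) {
  stopifnot(inherits(spec, "population_spec"))
  schema <- spec$schema
  p <- nrow(schema)
  z <- with_seed_maybe(seed, {
    matrix(rnorm(n * p), nrow = n, ncol = p) %*% chol(spec$correlation)
  })
  cols <- vector("list", p)
  names(cols) <- schema$name
  for (j in seq_len(p)) {
    v <- schema[j, ]
    zj <- z[, j]
    cols[[j]] <- switch(
      v$vtype,
      continuous = if (identical(v$transform, "log")) {
        exp(v$mean + v$sd * zj)
      } else {
        v$mean + v$sd * zj
      },
      semicontinuous = {
        u <- pnorm(zj)
        zm <- v$zero_mass
        out <- numeric(n)
        pos <- u >= zm
        out[pos] <- exp(v$mean + v$sd * qnorm((u[pos] - zm) / (1 - zm)))
        out
      },
      { # binary / nominal / ordinal: threshold the latent normal
        lv <- v$levels[[1]]
        cuts <- qnorm(cumsum(v$prevalence[[1]])[-length(lv)])
        idx <- findInterval(zj, cuts) + 1L
        factor(lv[idx], levels = lv)
      }
    )
  }
  out <- tibble::as_tibble(cols)
  attr(out, "schema") <- schema
  out
}

#' Full-sample (truth) values of the analysis estimands
#'
#' Computes the estimand value Q on a completely observed dataset for every
#' entry of the analysis plan — the reference against which every method's
#' Monte-Carlo estimates are compared.
#'
#' @param data A fully observed tibble (e.g. from [generate_population()]).
#' @param plan An [analysis_plan()].
#' @param schema Optional schema; taken from the data attribute otherwise.
#' @return Tibble with columns `id`, `estimate`, `n`.
#' @export
true_estimands <- function(data, plan, schema = NULL) {
  schema <- get_schema(data, schema)
  if (anyNA(data)) abort("true_estimands requires a fully observed dataset")
  compute_estimates(data, plan)
}

# ---- packaged fixtures ----------------------------------------------------

#' Packaged population fixtures
#'
#' `brfss_like_spec()` mirrors the shape of a diabetes-module extract from a
#' large telephone health survey: six outcome variables (one age-like
#' continuous, two very positively skewed semicontinuous utilization counts,
#' three binary) over thirteen fully observed demographic/behavioral
#' covariates. `nhanes_like_spec()` mirrors a cardiovascular extract from an
#' examination survey: five outcomes (four binary, one skewed positive
#' biomarker resembling high-sensitivity C-reactive protein) over fourteen
#' covariates. Dependence is induced by a three-factor loading structure
#' (age, socioeconomic status, metabolic burden), so every outcome shares
#' latent correlation with several covariates and missingness that depends
#' on those covariates is informative and recoverable.
#'
#' @param seed Integer seed stored in the spec (generation default).
#' @param n Default sample size stored in the spec.
#' @return A [population_spec()].
#' @export
brfss_like_spec <- function(seed = 1L, n = 5000) {
  # loadings: (age, ses, metabolic)
  vars <- list(
    list(var_spec("age_group", "covariate", "ordinal",
                  levels = c("18-39", "40-54", "55-69", "70+"),
                  prevalence = c(0.15, 0.30, 0.30, 0.25)), c(0.80, 0, 0)),
    list(var_spec("sex", "covariate", "binary", levels = c("female", "male"),
                  prevalence = c(0.52, 0.48)), c(0, 0, 0.05)),
    list(var_spec("race", "covariate", "nominal",
                  levels = c("white", "black", "other"),
                  prevalence = c(0.55, 0.25, 0.20)), c(0, 0.30, 0)),
    list(var_spec("education", "covariate", "ordinal",
                  levels = c("<hs", "hs", ">hs"),
                  prevalence = c(0.30, 0.40, 0.30)), c(0, 0.70, 0)),
    list(var_spec("income", "covariate", "ordinal",
                  levels = c("low", "mid", "high"),
                  prevalence = c(0.35, 0.35, 0.30)), c(-0.10, 0.72, -0.10)),
    list(var_spec("marital", "covariate", "nominal",
                  levels = c("married", "formerly", "never"),
                  prevalence = c(0.50, 0.30, 0.20)), c(-0.20, -0.25, 0)),
    list(var_spec("employment", "covariate", "binary",
                  levels = c("not_working", "working"),
                  prevalence = c(0.45, 0.55)), c(-0.35, 0.45, -0.10)),
    list(var_spec("insurance", "covariate", "binary",
                  levels = c("insured", "uninsured"),
                  prevalence = c(0.88, 0.12)), c(-0.20, -0.40, 0.10)),
    list(var_spec("bmi", "covariate", "continuous", mean = 30, sd = 6),
         c(-0.10, -0.10, 0.55)),
    list(var_spec("exercise", "covariate", "binary",
                  levels = c("inactive", "active"),
                  prevalence = c(0.40, 0.60)), c(0, 0.30, -0.45)),
    list(var_spec("smoker", "covariate", "binary",
                  levels = c("never", "ever"),
                  prevalence = c(0.55, 0.45)), c(0.10, -0.30, 0.30)),
    list(var_spec("gen_health", "covariate", "ordinal",
                  levels = c("good", "fair", "poor"),
                  prevalence = c(0.45, 0.35, 0.20)), c(0.10, -0.30, 0.60)),
    list(var_spec("checkup", "covariate", "ordinal",
                  levels = c("<1y", "1-2y", ">2y"),
                  prevalence = c(0.60, 0.25, 0.15)), c(-0.25, -0.15, -0.20)),
    # outcomes: the six diabetes-module variables made incomplete downstream
    list(var_spec("age_dx", "outcome", "continuous", mean = 50, sd = 10),
         c(0.60, -0.10, 0.30)),
    list(var_spec("feet_checks", "outcome", "semicontinuous",
                  zero_mass = 0.30, mean = 0.80, sd = 0.70),
         c(0.20, 0.25, 0.45)),
    list(var_spec("a1c_checks", "outcome", "semicontinuous",
                  zero_mass = 0.25, mean = 0.90, sd = 0.60),
         c(0.15, 0.30, 0.50)),
    list(var_spec("insulin_use", "outcome", "binary",
                  levels = c("no", "yes"), prevalence = c(0.70, 0.30)),
         c(0.25, -0.15, 0.55)),
    list(var_spec("eyes_affected", "outcome", "binary",
                  levels = c("no", "yes"), prevalence = c(0.75, 0.25)),
         c(0.30, -0.15, 0.50)),
    list(var_spec("diabetes_class", "outcome", "binary",
                  levels = c("no", "yes"), prevalence = c(0.55, 0.45)),
         c(-0.10, 0.40, 0.20))
  )
  schema <- imp_schema(lapply(vars, `[[`, 1))
  loadings <- do.call(rbind, lapply(vars, `[[`, 2))
  population_spec(schema, correlation_from_loadings(loadings),
                  n = n, seed = seed)
}

#' @rdname brfss_like_spec
#' @export
nhanes_like_spec <- function(seed = 1L, n = 5000) {
  vars <- list(
    list(var_spec("sex", "covariate", "binary", levels = c("female", "male"),
                  prevalence = c(0.51, 0.49)), c(0, 0, 0.05)),
    list(var_spec("age", "covariate", "continuous", mean = 48, sd = 17),
         c(0.85, 0, 0)),
    list(var_spec("race", "covariate", "nominal",
                  levels = c("white", "black", "other"),
                  prevalence = c(0.60, 0.22, 0.18)), c(0, 0.30, 0)),
    list(var_spec("education", "covariate", "ordinal",
                  levels = c("<hs", "hs", ">hs"),
                  prevalence = c(0.25, 0.40, 0.35)), c(0, 0.70, 0)),
    list(var_spec("income", "covariate", "ordinal",
                  levels = c("low", "mid", "high"),
                  prevalence = c(0.30, 0.40, 0.30)), c(-0.10, 0.72, -0.10)),
    list(var_spec("marital", "covariate", "nominal",
                  levels = c("married", "formerly", "never"),
                  prevalence = c(0.52, 0.27, 0.21)), c(-0.25, -0.25, 0)),
    list(var_spec("insurance", "covariate", "binary",
                  levels = c("insured", "uninsured"),
                  prevalence = c(0.85, 0.15)), c(-0.20, -0.40, 0.10)),
    list(var_spec("healthcare_access", "covariate", "binary",
                  levels = c("yes", "no"), prevalence = c(0.80, 0.20)),
         c(-0.20, -0.45, 0.10)),
    list(var_spec("gen_health", "covariate", "ordinal",
                  levels = c("good", "fair", "poor"),
                  prevalence = c(0.50, 0.32, 0.18)), c(0.10, -0.30, 0.55)),
    list(var_spec("employment", "covariate", "binary",
                  levels = c("not_working", "working"),
                  prevalence = c(0.42, 0.58)), c(-0.35, 0.50, -0.10)),
    list(var_spec("bmi", "covariate", "continuous", mean = 29, sd = 7),
         c(-0.05, -0.10, 0.55)),
    list(var_spec("alcohol", "covariate", "binary",
                  levels = c("no", "yes"), prevalence = c(0.35, 0.65)),
         c(-0.15, 0.20, 0.20)),
    list(var_spec("smoker", "covariate", "binary",
                  levels = c("never", "ever"), prevalence = c(0.58, 0.42)),
         c(0.10, -0.25, 0.30)),
    list(var_spec("diet_quality", "covariate", "ordinal",
                  levels = c("poor", "fair", "good"),
                  prevalence = c(0.25, 0.45, 0.30)), c(0.10, 0.35, -0.35)),
    # outcomes: the five cardiovascular variables made incomplete downstream
    list(var_spec("high_bp", "outcome", "binary",
                  levels = c("no", "yes"), prevalence = c(0.55, 0.45)),
         c(0.40, -0.10, 0.50)),
    list(var_spec("high_chol", "outcome", "binary",
                  levels = c("no", "yes"), prevalence = c(0.60, 0.40)),
         c(0.35, -0.05, 0.45)),
    list(var_spec("overweight", "outcome", "binary",
                  levels = c("no", "yes"), prevalence = c(0.35, 0.65)),
         c(0.05, -0.05, 0.60)),
    list(var_spec("hscrp", "outcome", "continuous",
                  mean = 0.80, sd = 0.90, transform = "log"),
         c(0.10, -0.15, 0.50)),
    list(var_spec("salt_reduce", "outcome", "binary",
                  levels = c("no", "yes"), prevalence = c(0.65, 0.35)),
         c(0.30, -0.10, 0.35))
  )
  schema <- imp_schema(lapply(vars, `[[`, 1))
  loadings <- do.call(rbind, lapply(vars, `[[`, 2))
  population_spec(schema, correlation_from_loadings(loadings),
                  n = n, seed = seed)
}
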