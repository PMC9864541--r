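# Small desk-scale populations used across the suite. Built in code so the
# repository ships no binary fixtures.

# One continuous outcome over four mixed covariates, with enough shared
# latent structure that covariate-driven missingness is informative.
small_spec <- function(n = 4000, seed = 1L) {
  vars <- list(
    list(var_spec("x1", "covariate", "continuous"), c(0.7, 0)),
    list(var_spec("x2", "covariate", "continuous"), c(0, 0.6)),
    list(var_spec("g", "covariate", "binary", levels = c("a", "b"),
                  prevalence = c(0.5, 0.5)), c(0.4, 0.2)),
    list(var_spec("e", "covariate", "ordinal", levels = c("l", "m", "h"),
                  prevalence = c(0.3, 0.4, 0.3)), c(0.2, 0.5)),
    list(var_spec("y", "outcome", "continuous", mean = 50, sd = 10),
         c(0.5, 0.4))
  )
  schema <- imp_schema(lapply(vars, `[[`, 1))
  population_spec(
    schema,
    imputesim:::correlation_from_loadings(do.call(rbind, lapply(vars, `[[`, 2))),
    n = n, seed = seed
  )
}

# One semicontinuous outcome (large zero mass, skewed positive part) over
# three covariates; used by the two-step procedure tests.
semi_spec <- function(n = 5000, seed = 1L, zero_mass = 0.7) {
  vars <- list(
    list(var_spec("x1", "covariate", "continuous"), c(0.7, 0)),
    list(var_spec("x2", "covariate", "continuous"), c(0, 0.6)),
    list(var_spec("g", "covariate", "binary", levels = c("a", "b"),
                  prevalence = c(0.5, 0.5)), c(0.4, 0.2)),
    list(var_spec("s", "outcome", "semicontinuous", zero_mass = zero_mass,
                  mean = 0.5, sd = 0.8), c(0.5, 0.4))
  )
  schema <- imp_schema(lapply(vars, `[[`, 1))
  population_spec(
    schema,
    imputesim:::correlation_from_loadings(do.call(rbind, lapply(vars, `[[`, 2))),
    n = n, seed = seed
  )
}

# Binary outcome over mixed covariates, for the latent imputer's
# threshold-consistency checks.
binary_spec <- function(n = 4000, seed = 1L, prevalence = 0.3) {
  vars <- list(
    list(var_spec("x1", "covariate", "continuous"), c(0.7, 0)),
    list(var_spec("x2", "covariate", "continuous"), c(0, 0.6)),
    list(var_spec("b", "outcome", "binary", levels = c("no", "yes"),
                  prevalence = c(1 - prevalence, prevalence)), c(0.5, 0.3))
  )
  schema <- imp_schema(lapply(vars, `[[`, 1))
  population_spec(
    schema,
    imputesim:::correlation_from_loadings(do.call(rbind, lapply(vars, `[[`, 2))),
    n = n, seed = seed
  )
}

# Attach a schema to a hand-built tibble.
with_schema <- function(data, schema) {
  attr(data, "schema") <- schema
  data
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}
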