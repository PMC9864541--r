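#' Describe one variable of a mixed-type dataset
#'
#' A variable specification records everything the generator, the amputation
#' step and the imputers need to know about a column: its role in the study
#' design (fully observed covariate vs. outcome that may be made
#' incomplete), its type, and the marginal parameters of its population
#' distribution.
#'
#' Types follow the usual survey taxonomy: `continuous` (optionally
#' lognormal via `transform = "log"`), `binary`, `nominal`, `ordinal`, and
#' `semicontinuous` — a nonnegative variable with a point mass at zero
#' (probability `zero_mass`) and a right-skewed, strictly positive
#' continuous part (lognormal with log-scale parameters `mean` and `sd`).
#'
#' @param name Column name.
#' @param role `"covariate"` or `"outcome"`.
#' @param vtype One of `"continuous"`, `"binary"`, `"nominal"`, `"ordinal"`,
#'   `"semicontinuous"`.
#' @param levels Character vector of category labels (categorical types
#'   only; binary requires exactly two).
#' @param prevalence Numeric vector of population level probabilities,
#'   summing to 1 (categorical types only).
#' @param zero_mass Probability of an exact zero (semicontinuous only),
#'   strictly inside (0, 1).
#' @param mean,sd Location and scale of the continuous part. For
#'   `transform = "log"` and for the semicontinuous positive part these are
#'   log-scale (lognormal) parameters.
#' @param transform `"identity"` or `"log"` for continuous variables;
#'   the monotone link from the latent normal scale to the observed scale.
#' @return A one-row tibble; combine rows with [imp_schema()].
#' @seealso [imp_schema()], [generate_population()]
#' @export
var_spec <- function(name, role = c("covariate", "outcome"),
                     vtype = c("continuous", "binary", "nominal", "ordinal",
                               "semicontinuous"),
                     levels = NULL, prevalence = NULL, zero_mass = NA_real_,
                     mean = 0, sd = 1, transform = "identity") {
  role <- match.arg(role)
  vtype <- match.arg(vtype)
  tibble::tibble(
    name = as.character(name), role = role, vtype = vtype,
    levels = list(levels), prevalence = list(prevalence),
    zero_mass = zero_mass, mean = mean, sd = sd, transform = transform
  )
}

#' Assemble and validate a variable schema
#'
#' Binds [var_spec()] rows into a schema and enforces the structural rules
#' the rest of the package relies on: unique names, well-formed level sets,
#' prevalences that sum to one, and the outcome screening rule that every
#' level of a categorical outcome must have population prevalence of at
#' least 20% (rare outcome categories are excluded from the study design).
#'
#' @param ... One-row tibbles from [var_spec()], or data frames of them.
#' @return A tibble of class `imp_schema`.
#' @export
imp_schema <- function(...) {
  sch <- dplyr::bind_rows(...)
  if (anyDuplicated(sch$name)) abort("schema variable names must be unique")
  for (i in seq_len(nrow(sch))) {
    v <- sch[i, ]
    lv <- v$levels[[1]]
    pv <- v$prevalence[[1]]
    if (is_categorical(v$vtype)) {
      if (length(lv) < 2) {
        abort(sprintf("'%s': categorical variables need >= 2 levels", v$name))
      }
      if (v$vtype == "binary" && length(lv) != 2) {
        abort(sprintf("'%s': binary variables need exactly 2 levels", v$name))
      }
      if (length(pv) != length(lv)) {
        abort(sprintf("'%s': prevalence must match levels", v$name))
      }
      if (any(pv <= 0) || abs(sum(pv) - 1) > 1e-8) {
        abort(sprintf("'%s': prevalences must be positive and sum to 1", v$name))
      }
      if (v$role == "outcome" && any(pv < 0.2 - 1e-12)) {
        abort(sprintf(
          paste0("'%s': categorical outcome level with prevalence %.3f < 0.20; ",
                 "outcome categories must have at least 20%% occurrence in the ",
                 "full sample"),
          v$name, min(pv)
        ))
      }
    } else {
      if (!is.null(lv)) abort(sprintf("'%s': levels only for categorical", v$name))
    }
    if (v$vtype == "semicontinuous") {
      if (!is.finite(v$zero_mass) || v$zero_mass <= 0 || v$zero_mass >= 1) {
        abort(sprintf("'%s': zero_mass must lie strictly in (0, 1)", v$name))
      }
    }
    if (v$vtype %in% c("continuous", "semicontinuous") && v$sd <= 0) {
      abort(sprintf("'%s': sd must be positive", v$name))
    }
  }
  class(sch) <- c("imp_schema", class(tibble::tibble()))
  sch
}

#' @export
print.imp_schema <- function(x, ...) {
  cat(sprintf("<imp_schema: %d variables (%d covariates, %d outcomes)>\n",
              nrow(x), sum(x$role == "covariate"), sum(x$role == "outcome")))
  NextMethod()
}

outcome_names <- function(schema) schema$name[schema$role == "outcome"]
covariate_names <- function(schema) schema$name[schema$role == "covariate"]

schema_row <- function(schema, name) {
  i <- match(name, schema$name)
  if (is.na(i)) abort(sprintf("unknown variable '%s'", name))
  schema[i, ]
}

#' Population specification for the synthetic generator
#'
#' Couples a schema with the latent correlation matrix of the Gaussian
#' copula that induces the dependence structure, plus a default sample size
#' and seed. The correlation matrix must be symmetric with unit diagonal and
#' strictly positive eigenvalues.
#'
#' @param schema An [imp_schema()].
#' @param correlation Symmetric positive-definite matrix, one row/column per
#'   schema variable, unit diagonal.
#' @param n Default sample size drawn by [generate_population()].
#' @param seed Default integer seed.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(schema, correlation, n = 5000, seed = 1L) {
  stopifnot(inherits(schema, "imp_schema"))
  p <- nrow(schema)
  if (!is.matrix(correlation) || nrow(correlation) != p || ncol(correlation) != p) {
    abort("correlation must be a square matrix matching the schema dimension")
  }
  if (max(abs(correlation - t(correlation))) > 1e-10) {
    abort("correlation matrix must be symmetric")
  }
  if (max(abs(diag(correlation) - 1)) > 1e-10) {
    abort("correlation matrix must have unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort(sprintf(
      "correlation matrix is not positive definite (smallest eigenvalue %.3g)",
      min(ev)
    ))
  }
  structure(
    list(schema = schema, correlation = correlation,
         n = as.integer(n), seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec: %d variables, default n = %d, seed = %d>\n",
              nrow(x$schema), x$n, x$seed))
  invisible(x)
}

# Correlation matrix from a factor-loading matrix: R = L L' + diag residual.
# Guarantees positive definiteness whenever every communality is < 1.
correlation_from_loadings <- function(loadings) {
  comm <- rowSums(loadings^2)
  if (any(comm >= 1)) abort("factor loadings imply communality >= 1")
  r <- tcrossprod(loadings)
  diag(r) <- 1
  r
}

get_schema <- function(data, schema = NULL) {
  schema <- schema %||% attr(data, "schema")
  if (is.null(schema)) abort("no schema supplied and none attached to the data")
  schema
}
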