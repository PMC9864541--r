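#' Build an analysis plan
#'
#' An analysis plan is a tibble of estimands: descriptive statistics
#' (means, level proportions) and regression coefficients (linear or
#' logistic), each identified by an `id`. Regression predictor lists may —
#' and in the packaged plans deliberately do — include incomplete
#' variables, mirroring real analyses where both the outcome and several
#' predictors carry missingness.
#'
#' @param ... Plan rows from [plan_mean()], [plan_proportion()],
#'   [plan_coef()], or data frames of them.
#' @return A tibble of class `analysis_plan`.
#' @export
analysis_plan <- function(...) {
  plan <- dplyr::bind_rows(...)
  if (anyDuplicated(plan$id)) abort("estimand ids must be unique")
  class(plan) <- c("analysis_plan", class(tibble::tibble()))
  plan
}

#' @rdname analysis_plan
#' @param variable Column name.
#' @param id Estimand id (defaults to a descriptive one).
#' @export
plan_mean <- function(variable, id = paste0("mean_", variable)) {
  tibble::tibble(id = id, kind = "mean", variable = variable,
                 level = NA_character_, outcome = NA_character_,
                 predictors = list(NULL), family = NA_character_,
                 term = NA_character_)
}

#' @rdname analysis_plan
#' @param level Level whose proportion is estimated.
#' @export
plan_proportion <- function(variable, level,
                            id = paste0("prop_", variable, "_", level)) {
  tibble::tibble(id = id, kind = "proportion", variable = variable,
                 level = level, outcome = NA_character_,
                 predictors = list(NULL), family = NA_character_,
                 term = NA_character_)
}

#' @rdname analysis_plan
#' @param outcome Regression outcome name.
#' @param predictors Character vector of predictor names.
#' @param family `"linear"` or `"logistic"`.
#' @param term Name of the coefficient of interest, as produced by
#'   reference coding (e.g. `"eyes_affected_yes"` for the `yes` indicator
#'   of a factor, or a numeric predictor's own name).
#' @export
plan_coef <- function(outcome, predictors, family = c("linear", "logistic"),
                      term, id = paste0("coef_", outcome, "_", term)) {
  family <- match.arg(family)
  tibble::tibble(id = id, kind = "coef", variable = NA_character_,
                 level = NA_character_, outcome = outcome,
                 predictors = list(predictors), family = family, term = term)
}

# Reference-coded model matrix for a regression estimand (unstandardized:
# coefficients keep their natural units).
regression_design <- function(data, predictors) {
  cols <- list()
  for (v in predictors) {
    x <- data[[v]]
    if (is.null(x)) abort(sprintf("unknown variable '%s'", v))
    if (is.factor(x)) {
      for (l in levels(x)[-1]) cols[[paste0(v, "_", l)]] <- as.numeric(x == l)
    } else {
      cols[[v]] <- as.numeric(x)
    }
  }
  do.call(cbind, cols)
}

#' Least-squares and logistic fits used by the estimand calculator
#'
#' `fit_linear()` solves the (weighted) least-squares problem through a QR
#' decomposition; `fit_logistic()` maximizes the (weighted) Bernoulli
#' likelihood by iteratively reweighted least squares. Both accept an
#' intercept-free design matrix (an intercept column is added internally)
#' and return named coefficients. A singular design falls back to a small
#' ridge with a warning.
#'
#' @param y Response vector (0/1 for logistic).
#' @param X Design matrix without intercept.
#' @param weights Optional nonnegative case weights.
#' @return Named coefficient vector (first entry `(Intercept)`).
#' @export
fit_linear <- function(y, X, weights = NULL) {
  X1 <- cbind(`(Intercept)` = 1, X)
  w <- weights %||% rep(1, length(y))
  fit <- tryCatch(
    stats::lm.wfit(X1, y, w),
    error = function(e) NULL
  )
  if (is.null(fit) || any(is.na(fit$coefficients))) {
    warn("singular linear design: ridge-stabilized solve used")
    xtwx <- crossprod(X1, X1 * w) + diag(1e-8, ncol(X1))
    return(drop(solve(xtwx, crossprod(X1, w * y))))
  }
  fit$coefficients
}

#' @rdname fit_linear
#' @export
fit_logistic <- function(y, X, weights = NULL) {
  X1 <- cbind(`(Intercept)` = 1, X)
  w <- weights %||% rep(1, length(y))
  p <- ncol(X1)
  beta <- rep(0, p)
  for (i in 1:100) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    wt <- pmax(w * mu * (1 - mu), 1e-12)
    grad <- crossprod(X1, w * (y - mu))
    if (max(abs(grad)) < 1e-8 && i > 1) break
    xtwx <- crossprod(X1, X1 * wt)
    step <- tryCatch(solve(xtwx, grad), error = function(e) {
      warn("separation or singular logistic design: ridge-stabilized step")
      solve(xtwx + diag(1e-6 * (1 + diag(xtwx)), p), grad)
    })
    beta <- beta + drop(step)
    if (max(abs(step)) > 50) {
      warn("diverging logistic fit: coefficients capped")
      beta <- pmin(pmax(beta, -50), 50)
      break
    }
  }
  setNames(drop(beta), colnames(X1))
}

# Compute every estimand of a plan on one (weighted) dataset. Rows with
# missing values in the referenced variables are listwise-deleted when
# `complete_case = TRUE`; otherwise the data must be complete on the
# referenced variables. Undefined estimands come back NA with a note.
compute_estimates <- function(data, plan, weights = NULL,
                              complete_case = FALSE) {
  w_all <- weights %||% rep(1, nrow(data))
  purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    e <- plan[i, ]
    vars <- if (e$kind == "coef") c(e$outcome, e$predictors[[1]]) else e$variable
    miss_vars <- setdiff(vars, names(data))
    if (length(miss_vars)) {
      abort(sprintf("estimand '%s' references unknown column(s): %s",
                    e$id, paste(miss_vars, collapse = ", ")))
    }
    sub <- data[vars]
    keep <- stats::complete.cases(sub)
    if (!complete_case && !all(keep)) {
      abort(sprintf("estimand '%s': data not complete on referenced variables",
                    e$id))
    }
    d <- data[keep, , drop = FALSE]
    w <- w_all[keep]
    if (!nrow(d)) {
      return(tibble::tibble(id = e$id, estimate = NA_real_, n = 0,
                            note = "no complete cases"))
    }
    est <- tryCatch(
      switch(e$kind,
        mean = weighted.mean(as.numeric(d[[e$variable]]), w),
        proportion = weighted.mean(d[[e$variable]] == e$level, w),
        coef = {
          X <- regression_design(d, e$predictors[[1]])
          if (e$family == "linear") {
            y <- as.numeric(d[[e$outcome]])
            cf <- fit_linear(y, X, w)
          } else {
            yv <- d[[e$outcome]]
            y <- if (is.factor(yv)) as.integer(yv == levels(yv)[2]) else
              as.numeric(yv)
            cf <- fit_logistic(y, X, w)
          }
          if (!e$term %in% names(cf)) {
            abort(sprintf("term '%s' not found among coefficients (%s)",
                          e$term, paste(names(cf), collapse = ", ")))
          }
          unname(cf[e$term])
        }
      ),
      error = function(err) NA_real_
    )
    tibble::tibble(id = e$id, estimate = est, n = nrow(d),
                   note = if (is.na(est)) "estimation failed" else NA_character_)
  })
}

#' Complete-case (listwise-deletion) estimates
#'
#' Deletes, per estimand, every row missing any variable the estimand
#' references, then computes it on the survivors. A zero-survivor estimand
#' is returned as `NA` with a note rather than dropped.
#'
#' @param data Incomplete tibble.
#' @param plan An [analysis_plan()].
#' @return Tibble `id`, `estimate`, `n`, `note`.
#' @export
estimate_complete_case <- function(data, plan) {
  compute_estimates(data, plan, complete_case = TRUE)
}

#' Pool estimates across multiply imputed datasets
#'
#' Computes each estimand on every completed dataset and pools by the
#' arithmetic mean (the combining rule for point estimates). Per-dataset
#' values are kept in the `components` list column. Any undefined
#' component leaves the pooled estimate undefined.
#'
#' @param result A multiple [new_imputation_result()].
#' @param plan An [analysis_plan()].
#' @return Tibble `id`, `estimate`, `n`, `note`, `components`.
#' @export
pool_multiple <- function(result, plan) {
  stopifnot(result$kind == "multiple")
  per <- purrr::map(result$completed, compute_estimates, plan = plan)
  purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    vals <- purrr::map_dbl(per, ~ .x$estimate[i])
    tibble::tibble(
      id = plan$id[i],
      estimate = if (anyNA(vals)) NA_real_ else mean(vals),
      n = per[[1]]$n[i],
      note = if (anyNA(vals)) "undefined component estimate" else NA_character_,
      components = list(vals)
    )
  })
}

#' Estimates from a fractional hot-deck imputation
#'
#' Expands the fractional assignment ([fractional_expand()]) and computes
#' every estimand on the weighted data: weighted means and proportions, and
#' weighted regression fits in which the fractional weights enter the
#' least-squares / likelihood objective.
#'
#' @inheritParams pool_multiple
#' @export
fractional_estimate <- function(result, plan) {
  stopifnot(result$kind == "fractional")
  ex <- fractional_expand(result)
  w <- ex$.weight
  ex$.weight <- NULL
  ex$.source_row <- NULL
  compute_estimates(ex, plan, weights = w)
}

#' Estimates from any imputation result
#'
#' Dispatches to [pool_multiple()] or [fractional_estimate()].
#'
#' @inheritParams pool_multiple
#' @export
estimate_imputation <- function(result, plan) {
  if (result$kind == "multiple") pool_multiple(result, plan)
  else fractional_estimate(result, plan)
}

#' Default analysis plans for the packaged fixtures
#'
#' `brfss_like_plan()`: means of the continuous and semicontinuous
#' outcomes, the insulin-use proportion, and the logistic coefficient of
#' the eye-complication indicator in a model for current insulin use whose
#' predictors include the other (incomplete) outcomes plus demographic
#' covariates. `nhanes_like_plan()`: the biomarker mean, the
#' high-blood-pressure proportion, and the high-cholesterol coefficient in
#' a linear model for the biomarker with incomplete predictors.
#'
#' @return An [analysis_plan()].
#' @export
brfss_like_plan <- function() {
  analysis_plan(
    plan_mean("age_dx"),
    plan_mean("feet_checks"),
    plan_mean("a1c_checks"),
    plan_proportion("insulin_use", "yes"),
    plan_coef("insulin_use",
              c("age_dx", "feet_checks", "a1c_checks", "eyes_affected",
                "diabetes_class", "age_group", "sex", "insurance", "bmi",
                "income"),
              family = "logistic", term = "eyes_affected_yes")
  )
}

#' @rdname brfss_like_plan
#' @export
nhanes_like_plan <- function() {
  analysis_plan(
    plan_mean("hscrp"),
    plan_proportion("high_bp", "yes"),
    plan_coef("hscrp",
              c("high_bp", "high_chol", "overweight", "salt_reduce",
                "sex", "age", "insurance", "gen_health",
                "healthcare_access", "bmi"),
              family = "linear", term = "high_chol_yes")
  )
}
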