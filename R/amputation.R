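#' Build the design matrix for the missingness model
#'
#' Encodes a set of fully observed predictors the way the selection model
#' expects them: categorical predictors are reference-coded into indicator
#' columns (first level is the reference), continuous and semicontinuous
#' predictors are standardized to sample mean 0 and sd 1. Optionally the
#' (standardized) target variable itself is appended as the last column —
#' the self-mask term used by the not-at-random mechanisms. Column order is
#' deterministic: schema order, then level order, self term last.
#'
#' @param data Tibble with the named columns fully observed.
#' @param predictors Character vector of predictor names.
#' @param schema Optional schema (attribute used otherwise).
#' @param include_self Optional name of the target variable to append as a
#'   standardized self term (binary targets enter via their standardized
#'   0/1 coding).
#' @return Numeric matrix with named columns.
#' @export
build_design <- function(data, predictors, schema = NULL, include_self = NULL) {
  schema <- get_schema(data, schema)
  ord <- intersect(schema$name, predictors)
  missing_vars <- setdiff(predictors, schema$name)
  if (length(missing_vars)) {
    abort(sprintf("unknown predictor(s): %s", paste(missing_vars, collapse = ", ")))
  }
  cols <- list()
  for (v in ord) {
    x <- data[[v]]
    if (anyNA(x)) abort(sprintf("predictor '%s' must be fully observed", v))
    if (is.factor(x)) {
      lv <- levels(x)
      for (l in lv[-1]) {
        cols[[paste0(v, "_", l)]] <- as.numeric(x == l)
      }
    } else {
      cols[[v]] <- standardize(as.numeric(x), label = sprintf("predictor '%s'", v))
    }
  }
  if (!is.null(include_self)) {
    y <- data[[include_self]]
    if (anyNA(y)) abort(sprintf("self term '%s' must be fully observed", include_self))
    cols[[paste0(include_self, "_self")]] <-
      standardize(numeric_code(y), label = sprintf("self term '%s'", include_self))
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  do.call(cbind, cols)
}

#' Missingness probability under the logistic selection model
#'
#' Evaluates, row-wise, P = exp(phi0 + sum_j phi_j x_j) / (1 + exp(...)) —
#' the logistic model that drives the amputation step. Numerically safe for
#' linear predictors of magnitude up to several hundred.
#'
#' @param X Numeric design matrix (one column per slope).
#' @param phi0 Intercept.
#' @param slopes Numeric vector, one entry per column of `X`.
#' @return Vector of probabilities.
#' @export
miss_prob <- function(X, phi0, slopes) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) != length(slopes)) {
    abort("slope count must equal the number of design columns")
  }
  if (length(X) && any(!is.finite(X))) abort("non-finite entries in design matrix")
  lp <- phi0 + if (ncol(X)) drop(X %*% slopes) else rep(0, nrow(X))
  plogis(lp)
}

#' Calibrate the selection-model intercept to a target missing rate
#'
#' Finds the intercept phi0 such that the mean of the row-wise missingness
#' probabilities equals `target_rate`. The mean probability is strictly
#' increasing in phi0 and spans (0, 1), so bisection always converges; the
#' result satisfies |mean(P) - target_rate| <= 1e-8 and is deterministic.
#'
#' @inheritParams miss_prob
#' @param target_rate Desired mean missingness probability, in (0, 1).
#' @return The calibrated intercept (scalar).
#' @export
calibrate_phi0 <- function(X, slopes, target_rate = 0.4) {
  if (target_rate <= 0 || target_rate >= 1) abort("target_rate must be in (0, 1)")
  if (!is.matrix(X)) X <- as.matrix(X)
  s <- if (ncol(X)) drop(X %*% slopes) else rep(0, nrow(X))
  f <- function(phi0) mean(plogis(phi0 + s)) - target_rate
  lo <- -50; hi <- 50
  # expand in the (practically unreachable) case of an extreme offset scale
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= 1e-10 || (hi - lo) < 1e-13) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Amputation configuration for one outcome
#'
#' Describes the logistic selection model that makes one outcome variable
#' incomplete: which fully observed covariates drive missingness, the
#' (+1/-1) slope attached to each design column, the self-mask coefficient
#' (0 under MAR; 0.1 and 3 for the packaged small/large not-at-random
#' mechanisms), and the target missing rate.
#'
#' When `slopes` is `NULL` the signs are resolved at amputation time from
#' the sign of each design column's marginal correlation with the outcome
#' in the full sample, which makes the covariate-driven missingness
#' informative about the outcome.
#'
#' @param target Outcome name.
#' @param predictors Character vector of covariate names.
#' @param slopes Optional numeric vector of per-design-column slopes
#'   (resolved from the data when `NULL`).
#' @param phi_self Self-mask coefficient (0 = missing at random).
#' @param target_rate Target missing rate in (0, 1); may be 0 to disable.
#' @return A list of class `amputation_config`.
#' @export
amputation_config <- function(target, predictors, slopes = NULL,
                              phi_self = 0, target_rate = 0.4) {
  if (target_rate < 0 || target_rate >= 1) abort("target_rate must be in [0, 1)")
  structure(
    list(target = target, predictors = predictors, slopes = slopes,
         phi_self = phi_self, target_rate = target_rate),
    class = "amputation_config"
  )
}

#' Screen covariates for association with an outcome
#'
#' Mirrors the preparatory screening of candidate missingness predictors:
#' covariates significantly correlated with the outcome (correlation test on
#' numeric codings at level `alpha`) are kept; if fewer than `min_keep`
#' pass, the covariates with the largest absolute correlation are taken.
#'
#' @param data Fully observed tibble.
#' @param outcome Outcome name.
#' @param schema Optional schema.
#' @param alpha Significance level.
#' @param min_keep Minimum number of predictors to return.
#' @return Character vector of covariate names.
#' @export
screen_predictors <- function(data, outcome, schema = NULL, alpha = 0.05,
                              min_keep = 3) {
  schema <- get_schema(data, schema)
  covs <- covariate_names(schema)
  y <- numeric_code(data[[outcome]])
  stat <- purrr::map_dfr(covs, function(v) {
    ct <- suppressWarnings(cor.test(numeric_code(data[[v]]), y))
    tibble::tibble(covariate = v, r = unname(ct$estimate), p = ct$p.value)
  })
  keep <- stat$covariate[stat$p < alpha]
  if (length(keep) < min_keep) {
    keep <- stat$covariate[order(-abs(stat$r))][seq_len(min_keep)]
  }
  keep
}

resolve_phi_self <- function(mechanism) {
  switch(mechanism, MAR = 0, MNAR_small = 0.1, MNAR_large = 3, MCAR = 0)
}

#' Impose multivariate missingness on a complete dataset
#'
#' For each outcome independently: build the dummy-coded/standardized
#' design from its screened covariates (plus, under the not-at-random
#' mechanisms, the standardized outcome itself with self-mask coefficient
#' 0.1 or 3), assign +1/-1 slopes by the sign of each design column's
#' marginal association with the outcome, calibrate the intercept so the
#' mean missingness probability equals the target rate (default 40%), and
#' draw a Bernoulli mask. Covariates are never amputed. The masks for
#' different outcomes use independent substreams derived from `seed`, so
#' the whole realization is replay-deterministic.
#'
#' @param data Fully observed tibble.
#' @param mechanism `"MAR"`, `"MNAR_small"`, `"MNAR_large"`, or `"MCAR"`
#'   (constant missingness probability, no predictors).
#' @param schema Optional schema.
#' @param configs Optional list of [amputation_config()]s (one per outcome);
#'   built by covariate screening when `NULL`.
#' @param target_rate Default target missing rate for auto-built configs.
#' @param seed Integer seed.
#' @return An object of class `imp_amputation`: a list with `$data` (the
#'   amputed tibble, missing cells `NA`), `$realization` (per-outcome
#'   intercepts and realized rates), `$probs` (row-by-outcome probability
#'   matrix) and `$mechanism`. `tidy()` returns the realization table.
#' @examples
#' pop <- generate_population(brfss_like_spec(), n = 1000, seed = 7)
#' amp <- ampute(pop, mechanism = "MAR", seed = 7)
#' tidy(amp)
#' @export
ampute <- function(data, mechanism = c("MAR", "MNAR_small", "MNAR_large", "MCAR"),
                   schema = NULL, configs = NULL, target_rate = 0.4,
                   seed = NULL) {
  mechanism <- match.arg(mechanism)
  schema <- get_schema(data, schema)
  if (anyNA(data)) abort("ampute requires a fully observed dataset")
  phi_self <- resolve_phi_self(mechanism)
  if (is.null(configs)) {
    configs <- purrr::map(outcome_names(schema), function(o) {
      preds <- if (mechanism == "MCAR") character(0) else
        screen_predictors(data, o, schema)
      amputation_config(o, preds, phi_self = phi_self,
                        target_rate = target_rate)
    })
  }
  targets <- purrr::map_chr(configs, "target")
  if (anyDuplicated(targets)) abort("each outcome may appear in at most one config")
  for (cfg in configs) {
    if (mechanism == "MAR" && cfg$phi_self != 0) {
      abort("MAR mechanism is incompatible with a nonzero self-mask coefficient")
    }
  }

  out <- data
  n <- nrow(data)
  probs <- matrix(NA_real_, n, length(configs),
                  dimnames = list(NULL, targets))
  rows <- vector("list", length(configs))
  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    tgt <- cfg$target
    if (!tgt %in% outcome_names(schema)) {
      abort(sprintf("'%s' is not an outcome variable", tgt))
    }
    if (cfg$target_rate == 0) {
      probs[, k] <- 0
      rows[[k]] <- tibble::tibble(outcome = tgt, phi0 = -Inf,
                                  target_rate = 0, realized_rate = 0)
      next
    }
    self <- if (mechanism %in% c("MNAR_small", "MNAR_large") ||
                cfg$phi_self != 0) tgt else NULL
    X <- build_design(data, cfg$predictors, schema, include_self = self)
    slopes <- cfg$slopes
    if (is.null(slopes)) {
      y <- numeric_code(data[[tgt]])
      npred <- ncol(X) - as.integer(!is.null(self))
      slopes <- if (npred > 0) {
        vapply(seq_len(npred), function(j) {
          r <- suppressWarnings(cor(X[, j], y))
          if (is.na(r) || r >= 0) 1 else -1
        }, numeric(1))
      } else numeric(0)
      if (!is.null(self)) slopes <- c(slopes, cfg$phi_self)
    }
    phi0 <- calibrate_phi0(X, slopes, cfg$target_rate)
    p <- miss_prob(X, phi0, slopes)
    mask <- with_seed_maybe(
      if (is.null(seed)) NULL else derive_seed(seed, 101, k),
      runif(n) < p
    )
    col <- out[[tgt]]
    col[mask] <- NA
    out[[tgt]] <- col
    probs[, k] <- p
    rows[[k]] <- tibble::tibble(outcome = tgt, phi0 = phi0,
                                target_rate = cfg$target_rate,
                                realized_rate = mean(mask))
  }
  attr(out, "schema") <- schema
  structure(
    list(data = out, realization = dplyr::bind_rows(rows), probs = probs,
         mechanism = mechanism),
    class = "imp_amputation"
  )
}

#' @export
print.imp_amputation <- function(x, ...) {
  cat(sprintf("<imp_amputation: mechanism %s, %d outcome(s)>\n",
              x$mechanism, nrow(x$realization)))
  print(x$realization)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.imp_amputation <- function(x, ...) x$realization
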