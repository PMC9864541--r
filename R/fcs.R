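# Bayesian linear regression draw (conjugate normal-inverse-gamma with a
# flat prior): returns the least-squares coefficients, a posterior draw of
# (sigma, beta), and the Cholesky factor used. Ridge fallback for rank
# deficiency.
bayes_lm_draw <- function(y, X, posterior = TRUE, ridge = 1e-6) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  xtx <- crossprod(X1)
  xty <- crossprod(X1, y)
  ch <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(xtx + diag(ridge * (1 + diag(xtx)), p))
  }
  beta_hat <- backsolve(ch, backsolve(ch, xty, transpose = TRUE))
  resid <- y - drop(X1 %*% beta_hat)
  df <- max(length(y) - p, 1)
  if (posterior) {
    sigma2 <- sum(resid^2) / rchisq(1, df)
    beta_star <- beta_hat +
      sqrt(sigma2) * backsolve(ch, rnorm(p))
  } else {
    sigma2 <- sum(resid^2) / df
    beta_star <- beta_hat
  }
  list(beta_hat = drop(beta_hat), beta_star = drop(beta_star),
       sigma2 = sigma2)
}

# k nearest observed predictions for each missing-case prediction, using a
# sorted window (the k nearest values lie within k positions of the
# insertion point in sorted order). Returns a donor index per missing case.
pmm_match <- function(yhat_obs, yhat_mis, k) {
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  n <- length(ys)
  pos <- findInterval(yhat_mis, ys)
  vapply(seq_along(yhat_mis), function(i) {
    lo <- max(1L, pos[i] - k + 1L)
    hi <- min(n, pos[i] + k)
    cand <- lo:hi
    d <- abs(ys[cand] - yhat_mis[i])
    kk <- min(k, length(cand))
    sel <- cand[order(d)[seq_len(kk)]]
    ord[if (kk == 1L) sel else sel[sample.int(kk, 1L)]]
  }, integer(1))
}

#' Predictive mean matching imputation for one variable
#'
#' Fits a Bayesian linear regression on the observed rows, predicts the
#' observed cases under the least-squares coefficients and the missing
#' cases under a posterior draw, and imputes each missing case with the
#' observed response of one of its `k_donors` nearest-predicted neighbors
#' (type-1 matching, donor chosen uniformly). Every imputed value is
#' therefore an observed donor value.
#'
#' @param y_obs Observed responses.
#' @param X_obs,X_mis Predictor matrices for observed and missing rows
#'   (no intercept column; one is added internally).
#' @param k_donors Donor pool size (default 5). Reduced with a warning when
#'   fewer observed rows are available.
#' @param posterior Draw coefficients from the posterior (`TRUE`, proper
#'   multiple imputation) or suppress the draw (`FALSE`, deterministic
#'   nearest-neighbor mode used for verification).
#' @return Numeric vector of imputed values, one per row of `X_mis`.
#' @export
pmm_impute <- function(y_obs, X_obs, X_mis, k_donors = 5, posterior = TRUE) {
  if (nrow(X_mis) == 0) return(numeric(0))
  if (k_donors > length(y_obs)) {
    warn(sprintf("pmm: donor pool reduced from %d to %d available cases",
                 k_donors, length(y_obs)))
    k_donors <- length(y_obs)
  }
  fit <- bayes_lm_draw(y_obs, X_obs, posterior = posterior)
  yhat_obs <- drop(cbind(1, X_obs) %*% fit$beta_hat)
  yhat_mis <- drop(cbind(1, X_mis) %*% fit$beta_star)
  y_obs[pmm_match(yhat_obs, yhat_mis, k_donors)]
}

# Penalized IRLS fallback used when glm.fit does not converge (e.g. under
# complete separation).
ridge_logistic <- function(y, X1, lambda = 1e-3, maxit = 50) {
  p <- ncol(X1)
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtwx <- crossprod(X1, X1 * w) + diag(lambda, p)
    beta_new <- solve(xtwx, crossprod(X1, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(beta = drop(beta), xtwx = xtwx)
}

#' Bayesian logistic-regression imputation for one binary variable
#'
#' Fits a logistic regression on the observed rows by iteratively
#' reweighted least squares, draws coefficients from the asymptotic normal
#' approximation around the maximum-likelihood fit, and imputes each
#' missing case as a Bernoulli draw of its predicted probability. Complete
#' separation falls back to a ridge-stabilized fit with a warning; a
#' single observed class imputes that class.
#'
#' @param y_obs Observed responses, 0/1.
#' @param X_obs,X_mis Predictor matrices (intercept added internally).
#' @param posterior Draw coefficients from the approximate posterior.
#' @return Integer vector of imputed 0/1 values.
#' @export
logistic_impute <- function(y_obs, X_obs, X_mis, posterior = TRUE) {
  if (nrow(X_mis) == 0) return(integer(0))
  if (length(unique(y_obs)) == 1) {
    return(rep(y_obs[1], nrow(X_mis)))
  }
  X1 <- cbind(1, X_obs)
  fit <- suppressWarnings(
    stats::glm.fit(X1, y_obs, family = stats::binomial())
  )
  if (!fit$converged || fit$boundary) {
    warn("logistic imputation: separation suspected, ridge-stabilized fit used")
    rf <- ridge_logistic(y_obs, X1)
    beta <- rf$beta
    cov <- solve(rf$xtwx)
  } else {
    beta <- coef(fit)
    w <- fit$weights
    cov <- tryCatch(solve(crossprod(X1, X1 * w)),
                    error = function(e) solve(crossprod(X1, X1 * w) +
                                                diag(1e-6, ncol(X1))))
  }
  beta_star <- if (posterior) {
    drop(beta + t(chol(cov)) %*% rnorm(length(beta)))
  } else beta
  p_mis <- plogis(drop(cbind(1, X_mis) %*% beta_star))
  rbinom(length(p_mis), 1, p_mis)
}

#' Fully conditional specification (chained equations) imputation
#'
#' The sequential multiple-imputation comparator. Missing cells are
#' initialized by random draws from the observed marginal of each variable;
#' each of the `m` independent chains then sweeps the incomplete variables
#' in schema order for `iterations` rounds, re-imputing each one from its
#' conditional model given the current working values of all other
#' variables — predictive mean matching for continuous variables, Bayesian
#' logistic regression for binary ones. With `two_step = TRUE`,
#' semicontinuous variables are split into a binary zero/positive indicator
#' (imputed with the binary method) and a positive part (imputed with
#' predictive mean matching, modeled on observed-positive rows only) and
#' merged afterwards; otherwise they are imputed directly by predictive
#' mean matching on the raw scale.
#'
#' Incomplete nominal/ordinal variables are out of scope for this method
#' family and are rejected.
#'
#' @param data Incomplete tibble (missing = `NA`).
#' @param schema Optional schema.
#' @param m Number of completed datasets (default 10).
#' @param iterations Sweeps per chain (default 20).
#' @param k_donors Predictive-mean-matching donor pool size (default 5).
#' @param two_step Use the two-part procedure for semicontinuous variables.
#' @param seed Integer seed; chains use independent derived substreams.
#' @return An [new_imputation_result()] of kind `"multiple"`.
#' @examples
#' pop <- generate_population(brfss_like_spec(), n = 400, seed = 2)
#' amp <- ampute(pop, "MAR", seed = 2)
#' res <- impute_fcs(amp$data, m = 2, iterations = 2, seed = 2)
#' res
#' @export
impute_fcs <- function(data, schema = NULL, m = 10, iterations = 20,
                       k_donors = 5, two_step = FALSE, seed = NULL) {
  stopifnot(m >= 1, iterations >= 1, k_donors >= 1)
  schema0 <- get_schema(data, schema)
  orig <- data
  if (two_step) {
    ex <- expand_semicontinuous(data, schema0)
    data <- ex$data
    schema <- ex$schema
    map <- ex$map
  } else {
    schema <- schema0
    map <- NULL
  }
  incomplete <- schema$name[purrr::map_lgl(schema$name, ~ anyNA(data[[.x]]))]
  bad <- incomplete[schema$vtype[match(incomplete, schema$name)] %in%
                      c("nominal", "ordinal")]
  if (length(bad)) {
    abort(sprintf("incomplete nominal/ordinal variable(s) not supported: %s",
                  paste(bad, collapse = ", ")))
  }

  run_chain <- function(chain_seed) {
    with_seed_maybe(chain_seed, {
      working <- data
      # initialize by marginal draws from the observed values
      for (v in incomplete) {
        x <- working[[v]]
        mis <- is.na(x)
        x[mis] <- sample(x[!mis], sum(mis), replace = TRUE)
        working[[v]] <- x
      }
      trace <- list()
      for (it in seq_len(iterations)) {
        for (v in incomplete) {
          d <- design_for_imputation(data, working, v, schema)
          vt <- schema$vtype[match(v, schema$name)]
          x <- working[[v]]
          if (vt == "binary") {
            lv <- levels(data[[v]])
            imp <- logistic_impute(as.integer(d$y_obs == lv[2]),
                                   d$X_obs, d$X_mis)
            x[!d$obs] <- factor(lv[imp + 1L], levels = lv)
          } else {
            imp <- pmm_impute(d$y_obs, d$X_obs, d$X_mis, k_donors)
            x[!d$obs] <- imp
          }
          working[[v]] <- x
        }
        trace[[it]] <- purrr::map_dbl(
          setNames(incomplete, incomplete),
          ~ mean(numeric_code(working[[.x]])[is.na(data[[.x]])])
        )
      }
      list(completed = working, trace = dplyr::bind_rows(trace))
    })
  }

  chains <- purrr::map(seq_len(m), function(c) {
    run_chain(if (is.null(seed)) NULL else derive_seed(seed, 202, c))
  })
  completed <- purrr::map(chains, "completed")
  if (two_step) {
    completed <- purrr::map(completed, collapse_semicontinuous,
                            original = orig, schema = schema0, map = map)
  }
  new_imputation_result(
    "multiple",
    method = if (two_step) "fcs_two_step" else "fcs",
    completed = completed,
    diagnostics = list(iterations = iterations, k_donors = k_donors,
                       trace = purrr::map(chains, "trace"))
  )
}
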