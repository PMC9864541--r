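# Link definitions tying each observed variable to one latent normal
# coordinate. Continuous variables standardize (optionally after log);
# binary/ordinal/nominal variables get probit thresholds fixed at
# standard-normal quantiles of the observed cumulative level frequencies;
# a semicontinuous variable imputed in one step uses a clamped identity
# link on the raw scale.
latent_links <- function(data, schema) {
  purrr::map(seq_len(nrow(schema)), function(j) {
    v <- schema[j, ]
    x <- data[[v$name]]
    if (is_categorical(v$vtype)) {
      lv <- levels(x)
      fr <- table(factor(x[!is.na(x)], levels = lv))
      pr <- pmax(as.numeric(fr) / sum(fr), 1e-6)
      pr <- pr / sum(pr)
      cuts <- qnorm(cumsum(pr)[-length(pr)])
      list(type = "probit", levels = lv,
           lower = c(-Inf, cuts), upper = c(cuts, Inf))
    } else if (v$vtype == "continuous" && identical(v$transform, "log")) {
      lx <- log(x[!is.na(x)])
      list(type = "log", mean = mean(lx), sd = max(stats::sd(lx), 1e-8))
    } else if (v$vtype == "semicontinuous") {
      ox <- x[!is.na(x)]
      list(type = "clamp", mean = mean(ox), sd = max(stats::sd(ox), 1e-8))
    } else {
      ox <- x[!is.na(x)]
      list(type = "identity", mean = mean(ox), sd = max(stats::sd(ox), 1e-8))
    }
  }) |> setNames(schema$name)
}

# Truncated standard-ish normal draw via the probability integral
# transform, safe in extreme tails.
rtruncnorm_vec <- function(mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  pl <- pmin(pl, 1 - 1e-12)
  pu <- pmax(pu, pl + 1e-12)
  qnorm(pl + runif(length(mean)) * (pu - pl), mean, sd)
}

#' Map observed data onto the latent normal scale
#'
#' Continuous values map deterministically through their standardization
#' (after log for log-linked variables); observed categorical values map to
#' a draw from the latent normal truncated to the interval between that
#' category's probit thresholds; missing entries are drawn from the
#' standard normal as an initialization (the sampler's later rounds replace
#' them by conditional draws).
#'
#' @param data Incomplete tibble.
#' @param links Link list from the fitted model (internal structure).
#' @return Numeric latent matrix, one column per variable.
#' @keywords internal
to_latent <- function(data, links) {
  n <- nrow(data)
  z <- matrix(NA_real_, n, length(links), dimnames = list(NULL, names(links)))
  for (j in seq_along(links)) {
    lk <- links[[j]]
    x <- data[[names(links)[j]]]
    obs <- !is.na(x)
    if (lk$type == "probit") {
      idx <- as.integer(x[obs])
      if (anyNA(idx)) abort("observed category outside schema levels")
      z[obs, j] <- rtruncnorm_vec(rep(0, sum(obs)), rep(1, sum(obs)),
                                  lk$lower[idx], lk$upper[idx])
    } else if (lk$type == "log") {
      z[obs, j] <- (log(x[obs]) - lk$mean) / lk$sd
    } else {
      z[obs, j] <- (x[obs] - lk$mean) / lk$sd
    }
    z[!obs, j] <- rnorm(sum(!obs))
  }
  z
}

back_transform <- function(zcol, lk) {
  switch(lk$type,
    probit = {
      idx <- findInterval(zcol, lk$upper[-length(lk$upper)]) + 1L
      factor(lk$levels[idx], levels = lk$levels)
    },
    log = exp(lk$mean + lk$sd * zcol),
    clamp = pmax(0, lk$mean + lk$sd * zcol),
    lk$mean + lk$sd * zcol
  )
}

# One parameter update: sequential (triangular, schema-order) Bayesian
# regressions of each latent coordinate on its predecessors, giving
# intercepts, coefficients B and residual sds. The triangular construction
# guarantees a positive-definite implied covariance; the implied mean
# vector is accumulated through the recursion.
update_triangular <- function(z, posterior = TRUE, ridge = 1e-6) {
  p <- ncol(z)
  B <- matrix(0, p, p)
  sds <- numeric(p)
  mu <- numeric(p)
  for (j in seq_len(p)) {
    fit <- bayes_lm_draw(z[, j], z[, seq_len(j - 1), drop = FALSE],
                         posterior = posterior, ridge = ridge)
    a <- fit$beta_star[1]
    if (j > 1) B[j, seq_len(j - 1)] <- fit$beta_star[-1]
    sds[j] <- max(sqrt(fit$sigma2), 1e-8)
    mu[j] <- a + if (j > 1) sum(B[j, seq_len(j - 1)] * mu[seq_len(j - 1)]) else 0
  }
  Bl <- B
  Bl[upper.tri(Bl, diag = TRUE)] <- 0
  A <- solve(diag(p) - Bl)
  sigma <- A %*% diag(sds^2, p) %*% t(A)
  sigma <- (sigma + t(sigma)) / 2
  list(B = B, sds = sds, mu = mu, sigma = sigma)
}

# Redraw the latent entries of missing cells from their conditional normal
# given the observed-cell latent values in the same row, grouped by missing
# pattern for vectorization.
redraw_missing <- function(z, miss, mu, sigma) {
  if (!any(miss)) return(z)
  pat <- apply(miss, 1, paste, collapse = "")
  for (pt in unique(pat[rowSums(miss) > 0])) {
    rows <- which(pat == pt & rowSums(miss) > 0)
    mset <- which(miss[rows[1], ])
    oset <- which(!miss[rows[1], ])
    if (!length(oset)) {
      ch <- chol(sigma[mset, mset, drop = FALSE] + diag(1e-10, length(mset)))
      z[rows, mset] <- rep(mu[mset], each = length(rows)) +
        matrix(rnorm(length(rows) * length(mset)), length(rows)) %*% ch
      next
    }
    soo_inv <- solve(sigma[oset, oset, drop = FALSE])
    smo <- sigma[mset, oset, drop = FALSE]
    condvar <- sigma[mset, mset, drop = FALSE] - smo %*% soo_inv %*% t(smo)
    condvar <- (condvar + t(condvar)) / 2
    ch <- chol(condvar + diag(1e-10, length(mset)))
    dev <- sweep(z[rows, oset, drop = FALSE], 2, mu[oset])
    cmu <- sweep(dev %*% t(smo %*% soo_inv), 2, mu[mset], `+`)
    z[rows, mset] <- cmu + matrix(rnorm(length(rows) * length(mset)),
                                  length(rows)) %*% ch
  }
  z
}

# Refresh the latent values of observed categorical cells: each coordinate
# is redrawn from its full conditional normal given the other coordinates,
# truncated to the interval of the observed category.
redraw_observed_categorical <- function(z, data, links, mu, sigma) {
  omega <- solve(sigma)
  for (j in seq_along(links)) {
    lk <- links[[j]]
    if (lk$type != "probit") next
    x <- data[[names(links)[j]]]
    obs <- which(!is.na(x))
    if (!length(obs)) next
    idx <- as.integer(x[obs])
    cond_var <- 1 / omega[j, j]
    w <- -omega[j, -j] * cond_var
    dev <- sweep(z[obs, -j, drop = FALSE], 2, mu[-j])
    cmu <- mu[j] + drop(dev %*% w)
    z[obs, j] <- rtruncnorm_vec(cmu, rep(sqrt(cond_var), length(obs)),
                                lk$lower[idx], lk$upper[idx])
  }
  z
}

#' Latent multivariate-normal joint-model imputation
#'
#' The joint-modelling comparator: every variable is linked to one
#' coordinate of a latent multivariate normal vector — continuous variables
#' by standardization (after a log transform for skewed, log-linked
#' variables), categorical variables by probit thresholds fixed at
#' standard-normal quantiles of their observed cumulative frequencies. The
#' sampler alternates, for `iterations` rounds, between (a) updating a
#' sequential (triangular, schema-order) system of Bayesian regressions
#' among the latent coordinates — a construction whose implied joint
#' covariance is positive definite by design — and (b) redrawing latent
#' values: conditional-normal draws for missing cells and truncated draws
#' for observed categorical cells. After burn-in, `m` imputation draws are
#' emitted from consecutive refreshes of step (b) and back-transformed
#' through the links.
#'
#' With `two_step = TRUE`, semicontinuous variables are split into a binary
#' indicator (probit link) and a log-linked positive part and merged after
#' imputation; in one step they use a zero-clamped identity link.
#'
#' @param data Incomplete tibble.
#' @param schema Optional schema.
#' @param m Number of imputation draws (default 10).
#' @param iterations Burn-in rounds (default 10).
#' @param two_step Use the two-part procedure for semicontinuous variables.
#' @param seed Integer seed.
#' @return An [new_imputation_result()] of kind `"multiple"`.
#' @examples
#' pop <- generate_population(brfss_like_spec(), n = 400, seed = 4)
#' amp <- ampute(pop, "MAR", seed = 4)
#' res <- impute_latent(amp$data, m = 2, iterations = 3, seed = 4)
#' res
#' @export
impute_latent <- function(data, schema = NULL, m = 10, iterations = 10,
                          two_step = FALSE, seed = NULL) {
  stopifnot(m >= 1, iterations >= 1)
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
  links <- latent_links(data, schema)
  miss <- vapply(data, is.na, logical(nrow(data)))

  res <- with_seed_maybe(seed, {
    z <- to_latent(data, links)
    trace <- numeric(iterations)
    par <- NULL
    for (it in seq_len(iterations)) {
      par <- update_triangular(z)
      z <- redraw_missing(z, miss, par$mu, par$sigma)
      z <- redraw_observed_categorical(z, data, links, par$mu, par$sigma)
      trace[it] <- if (any(miss)) mean(z[miss]) else NA_real_
    }
    draws <- purrr::map(seq_len(m), function(d) {
      z <<- redraw_missing(z, miss, par$mu, par$sigma)
      completed <- data
      for (j in seq_along(links)) {
        v <- names(links)[j]
        mis <- miss[, j]
        if (!any(mis)) next
        imputed <- back_transform(z[mis, j], links[[j]])
        col <- completed[[v]]
        col[mis] <- imputed
        completed[[v]] <- col
      }
      completed
    })
    list(draws = draws, trace = trace)
  })
  completed <- res$draws
  if (two_step) {
    completed <- purrr::map(completed, collapse_semicontinuous,
                            original = orig, schema = schema0, map = map)
  }
  new_imputation_result(
    "multiple",
    method = if (two_step) "latent_two_step" else "latent",
    completed = completed,
    diagnostics = list(iterations = iterations, trace = res$trace)
  )
}
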