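# Independent oracles used to cross-check the package's own numerics.

# Intercept calibration by successive grid refinement (independent of the
# package's bisection).
grid_calibrate <- function(X, slopes, target) {
  s <- if (ncol(as.matrix(X))) drop(as.matrix(X) %*% slopes) else
    rep(0, nrow(as.matrix(X)))
  lo <- -10
  hi <- 10
  b <- NA_real_
  for (step in c(0.1, 1e-3, 1e-5, 1e-7)) {
    grid <- seq(lo, hi, by = step)
    dev <- vapply(grid, function(p) abs(mean(plogis(p + s)) - target),
                  numeric(1))
    b <- grid[which.min(dev)]
    lo <- b - step
    hi <- b + step
  }
  b
}

# Exhaustive nearest-predicted-neighbor hot deck: least-squares fit via
# lm(), then for every missing case the observed y whose fitted value is
# closest to its prediction.
brute_force_pmm <- function(y_obs, X_obs, X_mis) {
  df <- as.data.frame(X_obs)
  fit <- stats::lm(y_obs ~ ., data = df)
  yhat_obs <- unname(stats::fitted(fit))
  yhat_mis <- unname(stats::predict(fit, newdata = as.data.frame(X_mis)))
  vapply(yhat_mis, function(h) y_obs[which.min(abs(yhat_obs - h))],
         numeric(1))
}

# Weighted fit by physical row replication: each row is repeated in
# proportion to its weight (x scale), then an unweighted reference fit is
# run on the expanded data.
replication_logistic <- function(y, X, w, scale = 1000) {
  reps <- round(w * scale)
  idx <- rep(seq_along(y), reps)
  df <- as.data.frame(X[idx, , drop = FALSE])
  df$y <- y[idx]
  stats::coef(stats::glm(y ~ ., data = df, family = stats::binomial()))
}

replication_linear <- function(y, X, w, scale = 1000) {
  reps <- round(w * scale)
  idx <- rep(seq_along(y), reps)
  df <- as.data.frame(X[idx, , drop = FALSE])
  df$y <- y[idx]
  stats::coef(stats::lm(y ~ ., data = df))
}
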