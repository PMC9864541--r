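test_that("complete-case estimates follow listwise deletion", {
  sch <- imp_schema(var_spec("x", "covariate", "continuous"),
                    var_spec("y", "outcome", "continuous"))
  d <- with_schema(tibble::tibble(x = c(1, 2, 3, 4), y = c(1, 2, NA, 4)), sch)
  est <- estimate_complete_case(d, analysis_plan(plan_mean("y")))
  expect_equal(est$estimate, 7 / 3)
  expect_identical(est$n, 3L)

  # no missing data: complete-case equals the full-sample estimate exactly
  pop <- generate_population(small_spec(), n = 400, seed = 2)
  plan <- analysis_plan(plan_mean("y"))
  expect_equal(estimate_complete_case(pop, plan)$estimate,
               true_estimands(pop, plan)$estimate)

  # zero surviving rows is surfaced, not dropped
  d2 <- with_schema(tibble::tibble(x = c(1, 2), y = c(NA_real_, NA_real_)), sch)
  est2 <- estimate_complete_case(d2, analysis_plan(plan_mean("y")))
  expect_true(is.na(est2$estimate))
  expect_identical(est2$note, "no complete cases")
})

test_that("complete-case regression equals a reference fit on the complete rows", {
  withr::with_seed(91, {
    n <- 40
    sch <- imp_schema(var_spec("x", "covariate", "continuous"),
                      var_spec("w", "outcome", "continuous"),
                      var_spec("y", "outcome", "binary", levels = c("n", "p"),
                               prevalence = c(0.5, 0.5)))
    d <- with_schema(tibble::tibble(
      x = rnorm(n),
      w = replace(rnorm(n), sample(n, 12), NA),
      y = factor(sample(c("n", "p"), n, TRUE), levels = c("n", "p"))
    ), sch)
    plan <- analysis_plan(plan_coef("y", c("x", "w"), "logistic", term = "x"))
    est <- estimate_complete_case(d, plan)
    cc <- d[complete.cases(d[c("y", "x", "w")]), ]
    oracle <- coef(glm(I(y == "p") ~ x + w, data = cc, family = binomial()))
    expect_equal(est$estimate, unname(oracle["x"]), tolerance = 1e-6)
    expect_identical(est$n, nrow(cc))
  })
})

test_that("linear and logistic fits agree with reference implementations", {
  # exact line
  x <- c(1, 2, 3, 4, 5)
  cf <- fit_linear(2 * x, cbind(x = x))
  expect_equal(unname(cf), c(0, 2), tolerance = 1e-10)

  # balanced 2x2 table with odds ratio 1: zero slope
  y <- c(1, 0, 1, 0)
  g <- c(1, 1, 0, 0)
  cfl <- fit_logistic(y, cbind(g = g))
  expect_lt(abs(cfl[["g"]]), 1e-8)

  # 12-row mixed design vs. lm()/glm() to 1e-6
  withr::with_seed(93, {
    X <- cbind(a = rnorm(12), b = runif(12))
    yl <- 1 + X[, 1] - 2 * X[, 2] + rnorm(12)
    expect_equal(unname(fit_linear(yl, X)),
                 unname(coef(lm(yl ~ X))), tolerance = 1e-6)
    yb <- rbinom(12, 1, plogis(X[, 1]))
    expect_equal(unname(fit_logistic(yb, X)),
                 unname(coef(glm(yb ~ X, family = binomial()))),
                 tolerance = 1e-6)
  })
})

test_that("pooling averages component estimates and ignores order", {
  pop <- generate_population(small_spec(), n = 300, seed = 97)
  amp <- ampute(pop, "MAR", seed = 97)
  res <- impute_fcs(amp$data, m = 10, iterations = 2, seed = 97)
  plan <- analysis_plan(plan_mean("y"))
  pooled <- pool_multiple(res, plan)
  by_hand <- mean(purrr::map_dbl(res$completed, ~ mean(.x$y)))
  expect_equal(pooled$estimate, by_hand)
  # order invariance
  res_rev <- res
  res_rev$completed <- rev(res$completed)
  expect_equal(pool_multiple(res_rev, plan)$estimate, pooled$estimate)
  # identical datasets pool to the single-dataset estimate
  res_id <- res
  res_id$completed <- rep(res$completed[1], 3)
  expect_equal(pool_multiple(res_id, plan)$estimate, mean(res$completed[[1]]$y))
})

test_that("fractional weights enter descriptive and regression estimates", {
  # hand-worked weighted mean: donors {1,2,3}, recipient half 4 / half 6
  sch <- imp_schema(var_spec("y", "outcome", "continuous"))
  d2 <- with_schema(tibble::tibble(y = c(1, 2, 3, NA, rep(100, 5), 4, 6)), sch)
  res2 <- new_imputation_result(
    "fractional", "fhd", data = d2,
    assignment = tibble::tibble(recipient = 4L, record = 1:2,
                                donor = c(10L, 11L), weight = 0.5)
  )
  ex <- fractional_expand(res2)
  w_mean <- weighted.mean(ex$y, ex$.weight)
  # ten complete rows with weight 1 plus the recipient's two half-weight
  # records carrying donor values 4 and 6
  hand <- (1 + 2 + 3 + 100 * 5 + 4 + 6 + 0.5 * 4 + 0.5 * 6) / 11
  expect_equal(w_mean, hand)

  # weighted logistic fit vs. physical row replication (x1000)
  withr::with_seed(101, {
    n <- 60
    X <- cbind(x = rnorm(n))
    y <- rbinom(n, 1, plogis(0.5 + X[, 1]))
    w <- sample(c(0.2, 0.5, 1), n, TRUE)
    mine <- fit_logistic(y, X, weights = w)
    oracle <- replication_logistic(y, X, w, scale = 1000)
    expect_equal(unname(mine), unname(oracle), tolerance = 1e-3)
    minl <- fit_linear(y, X, weights = w)
    oracl <- replication_linear(y, X, w, scale = 1000)
    expect_equal(unname(minl), unname(oracl), tolerance = 1e-3)
  })

  # unit weights reproduce the unweighted fit exactly
  withr::with_seed(103, {
    X <- cbind(x = rnorm(30))
    y <- rbinom(30, 1, 0.5)
    expect_equal(fit_logistic(y, X, weights = rep(1, 30)),
                 fit_logistic(y, X), tolerance = 1e-10)
  })
})

test_that("all estimators coincide on fully observed data", {
  pop <- generate_population(small_spec(), n = 500, seed = 107)
  plan <- analysis_plan(plan_mean("y"),
                        plan_coef("y", c("x1", "g"), "linear", term = "x1"))
  full <- true_estimands(pop, plan)$estimate
  cc <- estimate_complete_case(pop, plan)$estimate
  mi <- pool_multiple(impute_fcs(pop, m = 2, iterations = 1, seed = 1),
                      plan)$estimate
  fr <- fractional_estimate(impute_fhd(pop, seed = 1), plan)$estimate
  expect_equal(cc, full)
  expect_equal(mi, full)
  expect_equal(fr, full)
})
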