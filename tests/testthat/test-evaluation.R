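test_that("a zero missing rate makes every method reproduce the truth", {
  pop <- generate_population(small_spec(), n = 500, seed = 109)
  plan <- analysis_plan(plan_mean("y"))
  truth <- true_estimands(pop, plan)$estimate
  cfg <- list(amputation_config("y", c("x1", "x2"), target_rate = 0))
  est <- run_replicate(pop, plan, "MAR", c("complete_case", "fcs", "fhd", "latent"),
                       seed = 109, configs = cfg,
                       method_args = list(fcs = list(m = 2, iterations = 1),
                                          latent = list(m = 2, iterations = 2)))
  expect_equal(est$estimate, rep(truth, 4))
})

test_that("replicates replay deterministically and match a manual pipeline", {
  pop <- generate_population(small_spec(), n = 600, seed = 113)
  plan <- analysis_plan(plan_mean("y"))
  args <- list(fcs = list(m = 2, iterations = 2))
  r1 <- run_replicate(pop, plan, "MAR", "fcs", seed = 113, method_args = args)
  r2 <- run_replicate(pop, plan, "MAR", "fcs", seed = 113, method_args = args)
  expect_identical(r1, r2)
  # step-by-step manual invocation with the same derived substreams
  amp <- ampute(pop, "MAR", seed = imputesim:::derive_seed(113, 1))
  res <- impute_fcs(amp$data, m = 2, iterations = 2,
                    seed = imputesim:::derive_seed(113, 2, 2))
  manual <- pool_multiple(res, plan)$estimate
  expect_equal(r1$estimate, manual)
})

test_that("metric summaries satisfy their identities and the sign conventions", {
  # a degenerate estimator equal to the truth has zero B, SE and RMSE
  est <- tibble::tibble(replicate = 1:10, method = "m", id = "q",
                        estimate = rep(4.2, 10))
  truth <- tibble::tibble(id = "q", estimate = 4.2)
  s <- summarise_replicates(est, truth)
  expect_equal(s$B, 0)
  expect_equal(s$SE, 0)
  expect_equal(s$RMSE, 0)

  # negative bias prints a positive relative bias (absolute convention)
  z <- scale(seq_len(50))[, 1]
  est2 <- tibble::tibble(replicate = 1:50, method = "m", id = "q",
                         estimate = (46.893 - 0.2458) + 0.0131 * z)
  truth2 <- tibble::tibble(id = "q", estimate = 46.893)
  s2 <- summarise_replicates(est2, truth2)
  expect_equal(round(s2$RB, 4), 0.5242)
  expect_gt(s2$RB, 0)
  # metric identity pre-rounding
  expect_equal(s2$RMSE^2, s2$B^2 + s2$SE^2, tolerance = 1e-12)
  expect_gte(s2$RMSE, abs(s2$B))
  expect_gte(s2$RMSE, s2$SE)

  # zero truth: relative measures undefined but flagged
  est3 <- tibble::tibble(replicate = 1:5, method = "m", id = "q",
                         estimate = rnorm(5))
  s3 <- summarise_replicates(est3, tibble::tibble(id = "q", estimate = 0))
  expect_true(is.na(s3$RB))
  expect_match(s3$note, "Q = 0")

  # undefined replicate estimates are dropped with disclosure
  est4 <- tibble::tibble(replicate = 1:6, method = "m", id = "q",
                         estimate = c(1, 2, NA, 4, NA, 5))
  s4 <- summarise_replicates(est4, tibble::tibble(id = "q", estimate = 3))
  expect_identical(s4$R_effective, 4L)
  expect_equal(s4$E, 3)
})

test_that("reports round-trip through CSV at four decimals", {
  pop <- generate_population(small_spec(), n = 400, seed = 127)
  plan <- analysis_plan(plan_mean("y"))
  mc <- monte_carlo(pop, plan, "MCAR", "complete_case", R = 5, seed = 127)
  dir <- withr::local_tempdir()
  tab <- report_table(mc, dir = dir)
  expect_true(file.exists(file.path(dir, "report.csv")))
  expect_true(file.exists(file.path(dir, "report.txt")))
  back <- readr::read_csv(file.path(dir, "report.csv"), show_col_types = FALSE)
  expect_equal(back$B, round(mc$B, 4))
  expect_equal(back$RMSE, round(mc$RMSE, 4))
  # empty summaries render a header-only table
  empty <- summarise_replicates(
    tibble::tibble(replicate = integer(), method = character(),
                   id = character(), estimate = numeric()),
    tibble::tibble(id = character(), estimate = numeric())
  )
  expect_identical(nrow(report_table(empty)), 0L)
})

test_that("complete-case means are unbiased under forced MCAR", {
  pop <- generate_population(small_spec(), n = 2000, seed = 131)
  plan <- analysis_plan(plan_mean("y"))
  mc <- monte_carlo(pop, plan, "MCAR", "complete_case", R = 200, seed = 131)
  mc_se <- mc$SE / sqrt(mc$R_effective)
  expect_lt(abs(mc$B), 3 * mc_se)
})

test_that("method failures are retained as undefined estimates", {
  # a nominal outcome is outside the chained-equation method family, so the
  # fcs rows come back undefined while complete-case rows stay defined
  sch <- imp_schema(
    var_spec("x", "covariate", "continuous"),
    var_spec("f", "outcome", "nominal", levels = c("a", "b", "c"),
             prevalence = c(0.4, 0.3, 0.3))
  )
  pop <- generate_population(population_spec(sch, diag(2)), n = 300, seed = 137)
  plan <- analysis_plan(plan_proportion("f", "a"))
  est <- run_replicate(pop, plan, "MCAR", c("complete_case", "fcs"),
                       seed = 137)
  expect_false(is.na(est$estimate[est$method == "complete_case"]))
  expect_true(is.na(est$estimate[est$method == "fcs"]))
})

test_that("summaries expose tidy, glance and autoplot", {
  pop <- generate_population(small_spec(), n = 300, seed = 139)
  mc <- monte_carlo(pop, analysis_plan(plan_mean("y")), "MCAR",
                    "complete_case", R = 3, seed = 139)
  expect_s3_class(tidy(mc), "tbl_df")
  g <- glance(mc)
  expect_identical(g$R, 3)
  p <- autoplot(mc)
  expect_s3_class(p, "ggplot")
})
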