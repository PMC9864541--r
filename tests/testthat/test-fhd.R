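make_fhd_schema <- function(...) imp_schema(...)

test_that("discretization keeps levels, cuts quantiles, and isolates zeros", {
  sch <- imp_schema(
    var_spec("b", "covariate", "binary", levels = c("n", "y"),
             prevalence = c(0.5, 0.5)),
    var_spec("u", "covariate", "continuous"),
    var_spec("s", "outcome", "semicontinuous", zero_mass = 0.5,
             mean = 0, sd = 1)
  )
  withr::with_seed(3, {
    n <- 9000
    d <- with_schema(tibble::tibble(
      b = factor(sample(c("n", "y"), n, TRUE), levels = c("n", "y")),
      u = runif(n),
      s = c(0, 0, 0, 1.1, 2.2, 3.3, rep(0, n - 6))
    ), sch)
    disc <- fhd_discretize(d, n_bins = 3)
    # binary codes are the level codes
    expect_identical(disc$codes[, "b"], as.integer(d$b))
    # uniform continuous: each tercile holds about a third
    freq <- as.numeric(table(disc$codes[, "u"])) / n
    expect_identical(length(freq), 3L)
    expect_lt(max(abs(freq - 1 / 3)), 0.02)
  })

  # hand-binned semicontinuous example: zeros own a code, positives split
  sch2 <- imp_schema(var_spec("s", "outcome", "semicontinuous",
                              zero_mass = 0.5, mean = 0, sd = 1))
  d2 <- with_schema(tibble::tibble(s = c(0, 0, 0, 1.1, 2.2, 3.3)), sch2)
  disc2 <- fhd_discretize(d2, n_bins = 2)
  # median of positives is 2.2; first bin (1.1, 2.2], second (3.3)
  expect_identical(unname(disc2$codes[, "s"]), c(1L, 1L, 1L, 2L, 2L, 3L))

  # fewer distinct values than bins: bins reduced and logged
  sch3 <- imp_schema(var_spec("u", "covariate", "continuous"))
  d3 <- with_schema(tibble::tibble(u = rep(c(1, 2), 10)), sch3)
  disc3 <- fhd_discretize(d3, n_bins = 3)
  expect_true("u" %in% disc3$bin_notes)
})

test_that("cell collapsing guarantees the donor minimum and matches brute force", {
  sch <- imp_schema(
    var_spec("u", "covariate", "continuous"),
    var_spec("y", "outcome", "binary", levels = c("n", "y"),
             prevalence = c(0.5, 0.5))
  )
  # 12 rows; u spreads over 3 terciles; two recipients missing y
  d <- with_schema(tibble::tibble(
    u = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    y = factor(c("n", "y", "n", "y", "n", "y", "n", "y", "n", "y", NA, NA),
               levels = c("n", "y"))
  ), sch)
  disc <- fhd_discretize(d, n_bins = 3)
  coll <- fhd_collapse(disc, M = 5)
  counts <- imputesim:::eligible_counts(coll$codes, coll$donor_rows,
                                        coll$recip_rows)
  expect_true(all(counts >= 5))

  # brute force over single merges: the applied first merge is one that
  # maximizes the post-merge minimum donor count
  cands <- list(c(2, 1, "u"), c(3, 2, "u"), c(2, 1, "y"))
  brute <- vapply(cands, function(cd) {
    codes <- disc$codes
    v <- cd[3]
    col <- codes[, v]
    col[!is.na(col) & col == as.integer(cd[1])] <- as.integer(cd[2])
    codes[, v] <- col
    min(imputesim:::eligible_counts(codes, coll$donor_rows, coll$recip_rows))
  }, numeric(1))
  expect_identical(coll$merges$min_donors_after[1], max(brute))

  # no-op when every recipient already has enough donors
  coll1 <- fhd_collapse(disc, M = 1)
  expect_identical(nrow(coll1$merges), 0L)
  expect_identical(coll1$codes, disc$codes)

  # degenerate: a single complete row forces M down to 1
  d1 <- with_schema(tibble::tibble(
    u = c(1, 2, 3),
    y = factor(c("n", NA, NA), levels = c("n", "y"))
  ), sch)
  expect_warning(coll_d <- fhd_collapse(fhd_discretize(d1, n_bins = 2), M = 5),
                 "reduced")
  expect_identical(coll_d$M, 1L)
})

test_that("a hand-worked fractional assignment reproduces weights and joint donors", {
  sch <- imp_schema(
    var_spec("g", "covariate", "binary", levels = c("a", "b"),
             prevalence = c(0.5, 0.5)),
    var_spec("y1", "outcome", "continuous"),
    var_spec("y2", "outcome", "continuous")
  )
  # rows 1-4 complete donors in cell g=a; rows 5 complete in g=b;
  # row 6 misses both outcomes, observed g=a
  d <- with_schema(tibble::tibble(
    g = factor(c("a", "a", "a", "a", "b", "a"), levels = c("a", "b")),
    y1 = c(1, 2, 3, 4, 9, NA),
    y2 = c(10, 20, 30, 40, 90, NA)
  ), sch)
  res <- impute_fhd(d, donors = 2, n_bins = 2, seed = 1)
  asg <- res$assignment
  expect_identical(nrow(asg), 2L)
  expect_identical(unique(asg$recipient), 6L)
  expect_equal(asg$weight, c(0.5, 0.5))
  expect_equal(sum(asg$weight), 1)
  # joint-donor integrity: both imputed variables come from the same row
  ex <- fractional_expand(res)
  recs <- ex[ex$.source_row == 6, ]
  for (i in seq_len(nrow(recs))) {
    donor_row <- asg$donor[i]
    expect_identical(recs$y1[i], d$y1[donor_row])
    expect_identical(recs$y2[i], d$y2[donor_row])
  }
  # weighted mean agrees with hand arithmetic
  est <- fractional_estimate(res, analysis_plan(plan_mean("y1")))
  hand <- (sum(d$y1[1:5]) + sum(asg$weight * d$y1[asg$donor])) / 6
  expect_equal(est$estimate, hand)
})

test_that("fractional results satisfy the structural invariants", {
  pop <- generate_population(small_spec(), n = 1200, seed = 29)
  amp <- ampute(pop, "MAR", seed = 29)
  res <- impute_fhd(amp$data, donors = 5, seed = 29)
  asg <- res$assignment
  # weight conservation per recipient
  wsum <- tapply(asg$weight, asg$recipient, sum)
  expect_true(all(abs(wsum - 1) < 1e-12))
  # hot-deck support and observed-cell preservation
  ex <- fractional_expand(res)
  obs_vals <- pop$y[!is.na(amp$data$y)]
  imputed <- ex$y[is.na(amp$data$y[ex$.source_row])]
  expect_true(all(imputed %in% obs_vals))
  comp_rows <- ex$.source_row[ex$.weight == 1]
  expect_identical(ex$y[ex$.weight == 1], pop$y[comp_rows])
  # a fully observed dataset has no recipients and reproduces the
  # unweighted estimate exactly
  res0 <- impute_fhd(pop, donors = 5, seed = 1)
  expect_identical(nrow(res0$assignment), 0L)
  est0 <- fractional_estimate(res0, analysis_plan(plan_mean("y")))
  expect_equal(est0$estimate, mean(pop$y))
})

test_that("the fractional mean is unbiased under random missingness in one cell", {
  # single incomplete variable, no covariates: one universal cell
  sch <- imp_schema(var_spec("y", "outcome", "continuous", mean = 5, sd = 2))
  biases <- withr::with_seed(57, {
    vapply(1:200, function(r) {
      y <- rnorm(2000, 5, 2)
      d <- with_schema(tibble::tibble(y = y), sch)
      mis <- rbinom(2000, 1, 0.4) == 1
      d$y[mis] <- NA
      res <- impute_fhd(d, donors = 5, seed = r)
      fractional_estimate(res, analysis_plan(plan_mean("y")))$estimate -
        mean(y)
    }, numeric(1))
  })
  mc_se <- sd(biases) / sqrt(length(biases))
  expect_lt(abs(mean(biases)), 3 * mc_se)
})
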