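# imputesim

Monte-Carlo benchmarking of imputation methods for multivariate missing
data in survey-like, mixed-type datasets.

Epidemiologists analyzing public-health surveys routinely face several
incomplete variables at once — biomarkers, utilization counts, treatment
indicators — each with its own set of correlated, fully observed
demographic covariates. `imputesim` is for methodologists who want to know
how the standard imputation families behave in that regime before trusting
them on real data. It packages the whole simulation loop:

1. **Generate** a complete "full sample" from a Gaussian copula with
   known margins and a factor-structured latent correlation
   (`generate_population()`, with packaged `brfss_like_spec()` /
   `nhanes_like_spec()` fixtures shaped like diabetes-module and
   cardiovascular survey extracts).
2. **Ampute** outcomes through a logistic selection model
   (`ampute()`): for row *i*,
   P(missing) = expit(φ₀ + φ₁x₁ + … + φₙxₙ) with covariate slopes
   φⱼ ∈ {−1, +1}, an optional self-mask term on the standardized outcome
   itself (φ = 0.1 small-MNAR, φ = 3 large-MNAR, absent under MAR), and
   φ₀ calibrated by bisection so mean(P) equals the target missing rate
   (40% per variable by default).
3. **Impute** with three independently implemented method families behind
   one contract: fully conditional specification with predictive mean
   matching and Bayesian logistic regression (`impute_fcs()`), fractional
   hot-deck imputation with imputation cells, automatic cell collapsing,
   joint donor assignment and fractional weights 1/M (`impute_fhd()`), and
   a latent multivariate-normal joint model with probit links
   (`impute_latent()`). A two-step option handles semicontinuous variables
   (zero/positive indicator + skewed positive part).
4. **Estimate and score** (`monte_carlo()`): means, proportions and
   regression coefficients are computed per method, pooled (multiple
   imputation) or fractionally weighted (hot deck), and compared to the
   full-sample truth Q over R replicates via
   B = E(Q̄) − Q, SE = sd(Q̄ᵣ), RMSE = √(B² + SE²), and their relative
   forms RB, RSE, RRMSE in percent.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(imputesim)

pop  <- generate_population(brfss_like_spec(), n = 2000, seed = 1)
plan <- analysis_plan(plan_mean("age_dx"))

mc <- monte_carlo(
  pop, plan, mechanism = "MAR",
  methods = c("complete_case", "fcs", "latent"),
  R = 20, seed = 1,
  method_args = list(fcs    = list(m = 2, iterations = 4),
                     latent = list(m = 3, iterations = 5))
)
report_table(mc)
```

```
# A tibble: 3 × 8
  estimand    method             B `RB (%)`     SE `RSE (%)`  RMSE `RRMSE (%)`
  <chr>       <chr>          <dbl>    <dbl>  <dbl>     <dbl> <dbl>       <dbl>
1 mean_age_dx complete_case -1.84     3.67  0.0955     0.190 1.84        3.67
2 mean_age_dx fcs            0.239    0.476 0.363      0.722 0.434       0.865
3 mean_age_dx latent        -0.362    0.72  0.247      0.492 0.438       0.872
```

Age at diagnosis is amputed MAR through covariates that correlate with it,
so listwise deletion loses the older-diagnosed respondents and the
complete-case mean is biased low by almost two years (B = −1.84,
RMSE = 1.84). Both imputers recover most of that gap (RMSE ≈ 0.43); the
remaining spread is Monte-Carlo noise at R = 20. Production runs use the
default R = 1000.

See `vignettes/imputation-benchmark.Rmd` for the models, the calibration
details, the two-step semicontinuous procedure, and the design decisions.

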