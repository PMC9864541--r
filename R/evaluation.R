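method_registry <- c("complete_case", "fcs", "fcs_two_step", "fhd",
                     "latent", "latent_two_step")

apply_method <- function(method, amputed, schema, plan, seed, args = list()) {
  a <- function(name, default) args[[name]] %||% default
  switch(method,
    complete_case = estimate_complete_case(amputed, plan),
    fcs = estimate_imputation(
      impute_fcs(amputed, schema, m = a("m", 10), iterations = a("iterations", 20),
                 k_donors = a("k_donors", 5), seed = seed), plan),
    fcs_two_step = estimate_imputation(
      impute_fcs(amputed, schema, m = a("m", 10), iterations = a("iterations", 20),
                 k_donors = a("k_donors", 5), two_step = TRUE, seed = seed), plan),
    fhd = estimate_imputation(
      impute_fhd(amputed, schema, donors = a("donors", 5),
                 n_bins = a("n_bins", 3), seed = seed), plan),
    latent = estimate_imputation(
      impute_latent(amputed, schema, m = a("m", 10),
                    iterations = a("iterations", 10), seed = seed), plan),
    latent_two_step = estimate_imputation(
      impute_latent(amputed, schema, m = a("m", 10),
                    iterations = a("iterations", 10), two_step = TRUE,
                    seed = seed), plan),
    abort(sprintf("unknown method '%s'", method))
  )
}

#' Run one Monte-Carlo replicate
#'
#' Draws one amputation realization and applies every requested method to
#' the same amputed dataset, computing the plan's estimands per method. A
#' method failure on the replicate is recorded as an undefined estimate;
#' the replicate is retained. Per-method seeds are derived from the
#' replicate seed for replay.
#'
#' @param data Fully observed tibble.
#' @param plan An [analysis_plan()].
#' @param mechanism Amputation mechanism (see [ampute()]).
#' @param methods Character vector from `complete_case`, `fcs`,
#'   `fcs_two_step`, `fhd`, `latent`, `latent_two_step`.
#' @param schema Optional schema.
#' @param seed Integer seed for this replicate.
#' @param configs,target_rate Passed to [ampute()].
#' @param method_args Named list of per-method parameter lists, e.g.
#'   `list(fcs = list(m = 5, iterations = 5))`.
#' @return Tibble `method`, `id`, `estimate`, `n`.
#' @export
run_replicate <- function(data, plan, mechanism, methods, schema = NULL,
                          seed = NULL, configs = NULL, target_rate = 0.4,
                          method_args = list()) {
  schema <- get_schema(data, schema)
  bad <- setdiff(methods, method_registry)
  if (length(bad)) abort(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  amp <- ampute(data, mechanism, schema, configs = configs,
                target_rate = target_rate,
                seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  purrr::imap_dfr(setNames(methods, methods), function(mth, nm) {
    est <- tryCatch(
      apply_method(mth, amp$data, schema, plan,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, 2, match(mth, method_registry)),
                   args = method_args[[mth]] %||% list()),
      error = function(e) {
        tibble::tibble(id = plan$id, estimate = NA_real_, n = NA_integer_,
                       note = conditionMessage(e))
      }
    )
    dplyr::mutate(est[c("id", "estimate", "n")], method = mth, .before = 1)
  })
}

#' Summarise Monte-Carlo replicate estimates into performance metrics
#'
#' For each method-by-estimand cell: the Monte-Carlo mean of the defined
#' replicate estimates E, bias B = E - Q, standard error SE (the standard
#' deviation among replicate estimates), RMSE = sqrt(B^2 + SE^2), and the
#' relative measures RB = 100 |B| / |Q|, RSE = 100 SE / |Q|,
#' RRMSE = 100 RMSE / |Q| (undefined when Q = 0, reported `NA` with a
#' note). Undefined replicate estimates are excluded, with the surviving
#' count reported as `R_effective`.
#'
#' @param estimates Tibble with columns `replicate`, `method`, `id`,
#'   `estimate` (one row per replicate x method x estimand).
#' @param truth Tibble `id`, `estimate` of full-sample values Q.
#' @return Tibble of class `mc_summary`.
#' @export
summarise_replicates <- function(estimates, truth) {
  q <- setNames(truth$estimate, truth$id)
  out <- estimates |>
    dplyr::group_by(.data$method, .data$id) |>
    dplyr::summarise(
      R_effective = sum(!is.na(.data$estimate)),
      E = mean(.data$estimate, na.rm = TRUE),
      SE = stats::sd(.data$estimate, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      Q = unname(q[.data$id]),
      B = .data$E - .data$Q,
      RMSE = sqrt(.data$B^2 + .data$SE^2),
      RB = ifelse(.data$Q == 0, NA_real_, 100 * abs(.data$B) / abs(.data$Q)),
      RSE = ifelse(.data$Q == 0, NA_real_, 100 * .data$SE / abs(.data$Q)),
      RRMSE = ifelse(.data$Q == 0, NA_real_, 100 * .data$RMSE / abs(.data$Q)),
      note = ifelse(.data$Q == 0, "relative measures undefined (Q = 0)",
                    NA_character_)
    ) |>
    dplyr::select("method", "id", "Q", "E", "B", "RB", "SE", "RSE", "RMSE",
                  "RRMSE", "R_effective", "note")
  class(out) <- c("mc_summary", class(out))
  out
}

#' Monte-Carlo evaluation of imputation methods
#'
#' The full harness: computes the full-sample truth Q for every estimand,
#' then runs `R` independent replicates — each re-drawing both the
#' amputation realization and the imputation randomness — and summarises
#' bias, standard error and RMSE per method and estimand
#' ([summarise_replicates()]).
#'
#' @inheritParams run_replicate
#' @param R Number of replicates (default 1000).
#' @param seed Master seed; replicate seeds are derived substreams.
#' @param keep_replicates Attach the replicate-level estimates as the
#'   `"replicates"` attribute.
#' @return An `mc_summary` tibble with attributes `mechanism`, `R`,
#'   `truth` (and optionally `replicates`).
#' @examples
#' pop <- generate_population(brfss_like_spec(), n = 800, seed = 5)
#' plan <- analysis_plan(plan_mean("age_dx"))
#' mc <- monte_carlo(pop, plan, "MAR", c("complete_case", "fcs"), R = 3,
#'                   seed = 5, method_args = list(fcs = list(m = 2, iterations = 2)))
#' mc
#' @export
monte_carlo <- function(data, plan, mechanism, methods, R = 1000,
                        schema = NULL, seed = NULL, configs = NULL,
                        target_rate = 0.4, method_args = list(),
                        keep_replicates = FALSE) {
  stopifnot(R >= 2)
  schema <- get_schema(data, schema)
  truth <- true_estimands(data, plan, schema)
  reps <- purrr::map_dfr(seq_len(R), function(r) {
    run_replicate(data, plan, mechanism, methods, schema,
                  seed = if (is.null(seed)) NULL else derive_seed(seed, 7, r),
                  configs = configs, target_rate = target_rate,
                  method_args = method_args) |>
      dplyr::mutate(replicate = r, .before = 1)
  })
  out <- summarise_replicates(reps, truth)
  attr(out, "mechanism") <- mechanism
  attr(out, "R") <- R
  attr(out, "truth") <- truth
  if (keep_replicates) attr(out, "replicates") <- reps
  out
}

#' Render a Monte-Carlo summary as a report table
#'
#' One row per method, columns B, RB (%), SE, RSE (%), RMSE, RRMSE (%),
#' values rounded to 4 decimals (the unrounded summary is left untouched).
#' Optionally writes a CSV and an aligned plain-text rendering.
#'
#' @param summary An `mc_summary` from [monte_carlo()].
#' @param dir Optional output directory for `report.csv` / `report.txt`.
#' @param digits Rounding for display (default 4).
#' @return The rounded report tibble, invisibly when writing.
#' @export
report_table <- function(summary, dir = NULL, digits = 4) {
  tab <- summary |>
    dplyr::transmute(
      estimand = .data$id, method = .data$method,
      B = round(.data$B, digits), `RB (%)` = round(.data$RB, digits),
      SE = round(.data$SE, digits), `RSE (%)` = round(.data$RSE, digits),
      RMSE = round(.data$RMSE, digits), `RRMSE (%)` = round(.data$RRMSE, digits)
    )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(tab, file.path(dir, "report.csv"), na = "")
    writeLines(utils::capture.output(print(as.data.frame(tab), row.names = FALSE)),
               file.path(dir, "report.txt"))
    return(invisible(tab))
  }
  tab
}

#' @exportS3Method generics::tidy
tidy.mc_summary <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.mc_summary <- function(x, ...) {
  tibble::tibble(
    mechanism = attr(x, "mechanism") %||% NA_character_,
    R = attr(x, "R") %||% NA_integer_,
    methods = dplyr::n_distinct(x$method),
    estimands = dplyr::n_distinct(x$id)
  )
}

#' Plot a Monte-Carlo summary
#'
#' Bias (with a sign) and RMSE per method, faceted by estimand — the
#' graphical analogue of the report tables.
#'
#' @param object An `mc_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mc_summary <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("method", "id", "B", "SE", "RMSE") |>
    tidyr::pivot_longer(c("B", "SE", "RMSE"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric, levels = c("B", "SE", "RMSE")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~id, scales = "free_y") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "estimand units", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
print.mc_summary <- function(x, ...) {
  mech <- attr(x, "mechanism")
  if (!is.null(mech)) {
    cat(sprintf("<mc_summary: mechanism %s, R = %s>\n", mech,
                attr(x, "R") %||% "?"))
  }
  NextMethod()
}
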