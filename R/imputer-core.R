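#' Split a semicontinuous column into indicator and positive part
#'
#' The two-part representation used by the 2-step imputation procedure: a
#' binary indicator (zero vs. positive) and a continuous positive part
#' defined only where the indicator is positive. Missing cells propagate to
#' both parts; merging is the exact inverse on observed cells.
#'
#' @param x Nonnegative numeric vector (NAs allowed).
#' @return A tibble with columns `indicator` (factor `zero`/`positive`) and
#'   `positive` (numeric, `NA` where zero or missing).
#' @export
split_semicontinuous <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("semicontinuous values must be nonnegative")
  ind <- ifelse(is.na(x), NA_character_, ifelse(x > 0, "positive", "zero"))
  tibble::tibble(
    indicator = factor(ind, levels = c("zero", "positive")),
    positive = ifelse(!is.na(x) & x > 0, x, NA_real_)
  )
}

#' @rdname split_semicontinuous
#' @param pair A tibble as returned by `split_semicontinuous()`.
#' @export
merge_semicontinuous <- function(pair) {
  out <- rep(NA_real_, nrow(pair))
  zero <- !is.na(pair$indicator) & pair$indicator == "zero"
  pos <- !is.na(pair$indicator) & pair$indicator == "positive"
  out[zero] <- 0
  out[pos] <- pair$positive[pos]
  out
}

# Expand every semicontinuous variable of a dataset into its two-part
# representation and return the transformed data, the transformed schema
# (indicator = binary outcome pair, positive part = log-linked continuous),
# and the mapping needed to fold results back.
expand_semicontinuous <- function(data, schema) {
  semi <- schema$name[schema$vtype == "semicontinuous"]
  if (!length(semi)) {
    return(list(data = data, schema = schema, map = NULL))
  }
  data2 <- data
  rows <- vector("list", nrow(schema))
  for (i in seq_len(nrow(schema))) {
    v <- schema[i, ]
    if (v$vtype != "semicontinuous") {
      rows[[i]] <- v
      next
    }
    pair <- split_semicontinuous(data[[v$name]])
    ind_name <- paste0(v$name, "..ind")
    pos_name <- paste0(v$name, "..pos")
    data2[[v$name]] <- NULL
    data2[[ind_name]] <- pair$indicator
    data2[[pos_name]] <- pair$positive
    rows[[i]] <- dplyr::bind_rows(
      var_spec(ind_name, v$role, "binary",
               levels = c("zero", "positive"),
               prevalence = c(v$zero_mass, 1 - v$zero_mass)),
      var_spec(pos_name, v$role, "continuous",
               mean = v$mean, sd = v$sd, transform = "log")
    )
  }
  schema2 <- imp_schema(rows)
  data2 <- data2[schema2$name]
  attr(data2, "schema") <- schema2
  list(data = data2, schema = schema2, map = semi)
}

# Fold a completed two-part dataset back to the original schema: exact
# zeros where the (imputed) indicator is zero, the (imputed) positive part
# elsewhere; originally observed cells are restored verbatim.
collapse_semicontinuous <- function(completed, original, schema, map) {
  out <- completed
  for (v in map) {
    ind_name <- paste0(v, "..ind")
    pos_name <- paste0(v, "..pos")
    merged <- merge_semicontinuous(tibble::tibble(
      indicator = completed[[ind_name]],
      positive = completed[[pos_name]]
    ))
    obs <- !is.na(original[[v]])
    merged[obs] <- original[[v]][obs]
    out[[ind_name]] <- NULL
    out[[pos_name]] <- NULL
    out[[v]] <- merged
  }
  out <- out[schema$name]
  attr(out, "schema") <- schema
  out
}

#' Imputation result container
#'
#' All imputers return this object. Multiple imputation stores `m` completed
#' datasets; fractional hot-deck stores the (still incomplete) input plus a
#' donor assignment table with fractional weights. `tidy()` returns the
#' completed data in long form (multiple) or the assignment table
#' (fractional); `glance()` returns one diagnostics row.
#'
#' @param kind `"multiple"` or `"fractional"`.
#' @param method Method label.
#' @param completed List of completed tibbles (multiple imputation).
#' @param data Original incomplete tibble (fractional).
#' @param assignment Tibble `(recipient, record, donor, weight)` (fractional).
#' @param diagnostics Named list of method diagnostics.
#' @return An object of class `imputation_result`.
#' @export
new_imputation_result <- function(kind = c("multiple", "fractional"), method,
                                  completed = NULL, data = NULL,
                                  assignment = NULL, diagnostics = list()) {
  kind <- match.arg(kind)
  if (kind == "multiple") {
    stopifnot(length(completed) >= 1)
    for (d in completed) {
      if (anyNA(d)) abort("completed datasets must have zero missing cells")
    }
  } else {
    stopifnot(!is.null(data), !is.null(assignment))
  }
  structure(
    list(kind = kind, method = method, completed = completed, data = data,
         assignment = assignment, diagnostics = diagnostics),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  if (x$kind == "multiple") {
    cat(sprintf("<imputation_result: %s, %d completed dataset(s) of %d rows>\n",
                x$method, length(x$completed), nrow(x$completed[[1]])))
  } else {
    cat(sprintf(
      "<imputation_result: %s, fractional, %d recipient(s), %d record(s)>\n",
      x$method, dplyr::n_distinct(x$assignment$recipient), nrow(x$assignment)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.imputation_result <- function(x, ...) {
  if (x$kind == "fractional") return(x$assignment)
  purrr::imap_dfr(x$completed, function(d, i) {
    d |>
      dplyr::mutate(.imp = i, .row = dplyr::row_number()) |>
      dplyr::mutate(dplyr::across(-c(".imp", ".row"), as.character)) |>
      tidyr::pivot_longer(-c(".imp", ".row"),
                          names_to = "variable", values_to = "value")
  })
}

#' @exportS3Method generics::glance
glance.imputation_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, kind = x$kind,
    m = if (x$kind == "multiple") length(x$completed) else NA_integer_,
    iterations = x$diagnostics$iterations %||% NA_integer_,
    cells_collapsed = x$diagnostics$cells_collapsed %||% NA_integer_
  )
}

# Reference-coded, standardized predictor matrix built from a complete
# working copy, excluding the target column. Zero-variance columns (which
# can arise transiently during chained-equation sweeps) are dropped rather
# than rejected; an all-constant design degrades to intercept-only.
encode_predictors <- function(working, schema, exclude) {
  vars <- setdiff(schema$name, exclude)
  cols <- list()
  for (v in vars) {
    x <- working[[v]]
    if (is.factor(x)) {
      for (l in levels(x)[-1]) {
        cx <- as.numeric(x == l)
        if (stats::sd(cx) > 0) cols[[paste0(v, "_", l)]] <- cx
      }
    } else {
      s <- stats::sd(x)
      if (is.finite(s) && s > 0) cols[[v]] <- (x - mean(x)) / s
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = nrow(working), ncol = 0))
  }
  do.call(cbind, cols)
}

#' Partition a conditional-model design by the target's original mask
#'
#' Builds the response vector and the reference-coded/standardized
#' predictor matrix for one incomplete variable from the current (complete)
#' working copy, split into the rows where the target was originally
#' observed and those where it was originally missing.
#'
#' @param data Original dataset (defines the mask via `NA`s in `target`).
#' @param working Complete working copy (same rows).
#' @param target Name of the variable being imputed.
#' @param schema Schema for the working copy.
#' @return List with `y_obs`, `X_obs`, `X_mis`, `obs` (logical mask).
#' @export
design_for_imputation <- function(data, working, target, schema = NULL) {
  schema <- get_schema(working, schema)
  obs <- !is.na(data[[target]])
  if (!any(obs)) abort(sprintf("'%s': no donors/cases to fit", target))
  X <- encode_predictors(working, schema, exclude = target)
  if (ncol(X) > 0) {
    keep <- apply(X[obs, , drop = FALSE], 2, stats::sd) > 0
    if (!any(keep)) {
      abort(sprintf("'%s': zero-variance design on observed rows", target))
    }
    X <- X[, keep, drop = FALSE]
  }
  list(
    y_obs = data[[target]][obs],
    X_obs = X[obs, , drop = FALSE],
    X_mis = X[!obs, , drop = FALSE],
    obs = obs
  )
}
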