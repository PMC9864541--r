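#' Read and write mixed-type datasets as CSV with a schema sidecar
#'
#' The on-disk interchange format: a plain CSV (missing cells empty) plus a
#' YAML sidecar carrying the schema, so types and level sets survive the
#' round trip.
#'
#' @param data Tibble with an attached schema (or `schema` supplied).
#' @param path CSV path; the sidecar defaults to `<path>.schema.yml`.
#' @param schema Optional schema.
#' @param schema_path Sidecar path override.
#' @return `write_mixed_csv()` the input invisibly; `read_mixed_csv()` a
#'   tibble with the schema attached.
#' @export
write_mixed_csv <- function(data, path, schema = NULL,
                            schema_path = paste0(path, ".schema.yml")) {
  schema <- get_schema(data, schema)
  readr::write_csv(data, path, na = "")
  write_schema_yaml(schema, schema_path)
  invisible(data)
}

#' @rdname write_mixed_csv
#' @export
read_mixed_csv <- function(path, schema_path = paste0(path, ".schema.yml")) {
  schema <- read_schema_yaml(schema_path)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  out <- purrr::map2(schema$name, schema$vtype, function(nm, vt) {
    x <- raw[[nm]]
    if (is.null(x)) abort(sprintf("column '%s' missing from %s", nm, path))
    if (is_categorical(vt)) {
      factor(x, levels = schema_row(schema, nm)$levels[[1]])
    } else {
      as.numeric(x)
    }
  }) |> setNames(schema$name) |> tibble::as_tibble()
  attr(out, "schema") <- schema
  out
}

schema_to_list <- function(schema) {
  purrr::map(seq_len(nrow(schema)), function(i) {
    v <- schema[i, ]
    out <- list(name = v$name, role = v$role, vtype = v$vtype,
                mean = v$mean, sd = v$sd, transform = v$transform)
    if (!is.null(v$levels[[1]])) {
      out$levels <- as.list(v$levels[[1]])
      out$prevalence <- as.list(v$prevalence[[1]])
    }
    if (is.finite(v$zero_mass)) out$zero_mass <- v$zero_mass
    out
  })
}

schema_from_list <- function(lst) {
  rows <- purrr::map(lst, function(v) {
    var_spec(v$name, v$role, v$vtype,
             levels = if (!is.null(v$levels)) unlist(v$levels),
             prevalence = if (!is.null(v$prevalence)) unlist(v$prevalence),
             zero_mass = v$zero_mass %||% NA_real_,
             mean = v$mean %||% 0, sd = v$sd %||% 1,
             transform = v$transform %||% "identity")
  })
  imp_schema(rows)
}

#' Serialize a schema (or population spec) to YAML
#'
#' @param schema An [imp_schema()].
#' @param path Output path.
#' @export
write_schema_yaml <- function(schema, path) {
  yaml::write_yaml(list(variables = schema_to_list(schema)), path)
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  schema_from_list(yaml::read_yaml(path)$variables)
}

#' Serialize a population spec to YAML (schema + correlation + defaults)
#'
#' @param spec A [population_spec()].
#' @param path Output path.
#' @export
write_population_spec <- function(spec, path) {
  lst <- list(
    n = spec$n, seed = spec$seed,
    correlation = unname(apply(spec$correlation, 1, as.list)),
    variables = schema_to_list(spec$schema)
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_population_spec
#' @export
read_population_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  schema <- schema_from_list(lst$variables)
  corr <- do.call(rbind, purrr::map(lst$correlation, unlist))
  dimnames(corr) <- NULL
  population_spec(schema, corr, n = lst$n, seed = lst$seed)
}

#' Write a fractional imputation in long format
#'
#' One CSV row per (recipient, fractional record): recipient row index,
#' record number, donor row index and fractional weight.
#'
#' @param result A fractional [new_imputation_result()].
#' @param path Output CSV path.
#' @export
write_fractional <- function(result, path) {
  stopifnot(result$kind == "fractional")
  readr::write_csv(result$assignment, path)
  invisible(path)
}
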