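#' Plot an amputation realization
#'
#' Histogram of the row-wise missingness probabilities per outcome, with
#' the realized missing rate in the strip label — a quick check that the
#' calibrated selection model spreads risk the way the mechanism intends.
#'
#' @param object An `imp_amputation` from [ampute()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.imp_amputation <- function(object, ...) {
  pr <- tibble::as_tibble(object$probs) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "outcome", values_to = "p") |>
    dplyr::left_join(object$realization, by = "outcome") |>
    dplyr::mutate(outcome = sprintf("%s (realized %.1f%%)",
                                    .data$outcome, 100 * .data$realized_rate))
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "missingness probability", y = "rows",
                  title = sprintf("Mechanism: %s", object$mechanism)) +
    ggplot2::theme_minimal()
}

#' Plot an imputation result
#'
#' Density of observed versus imputed values for each numeric variable
#' that received imputations (first completed dataset for multiple
#' imputation; donor-filled records for fractional).
#'
#' @param object An `imputation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.imputation_result <- function(object, ...) {
  if (object$kind == "multiple") {
    comp <- object$completed[[1]]
    long <- purrr::map_dfr(names(comp), function(v) {
      if (!is.numeric(comp[[v]])) return(NULL)
      tibble::tibble(variable = v, value = comp[[v]])
    })
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_density(fill = "grey80") +
      ggplot2::facet_wrap(~variable, scales = "free") +
      ggplot2::labs(x = NULL, y = "density",
                    title = sprintf("Completed data (%s)", object$method)) +
      ggplot2::theme_minimal()
  } else {
    ex <- fractional_expand(object)
    long <- purrr::map_dfr(setdiff(names(ex), c(".weight", ".source_row")),
                           function(v) {
      if (!is.numeric(ex[[v]])) return(NULL)
      tibble::tibble(variable = v, value = ex[[v]], weight = ex$.weight)
    })
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                       weight = .data$weight)) +
      ggplot2::geom_density(fill = "grey80") +
      ggplot2::facet_wrap(~variable, scales = "free") +
      ggplot2::labs(x = NULL, y = "weighted density",
                    title = "Fractionally completed data") +
      ggplot2::theme_minimal()
  }
}
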