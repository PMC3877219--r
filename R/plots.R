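# ggplot2 visualisations for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trace plot of a refinement run
#'
#' Shows log-posterior, prior energy and (when data were used) the shift
#' RMSD along the saved samples.
#'
#' @param object A `shift_refinement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.shift_refinement <- function(object, ...) {
  tr <- object$trace |>
    tidyr::pivot_longer(
      cols = dplyr::any_of(c("log_posterior", "energy", "shift_rmsd")),
      names_to = "quantity", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Monte Carlo step", y = NULL,
                  title = "Refinement trace")
}

#' Observed-vs-calculated RDC plot for an alignment-tensor fit
#'
#' @param object An `alignment_tensor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.alignment_tensor <- function(object, ...) {
  ggplot2::ggplot(object$rdc, ggplot2::aes(x = .data$d, y = .data$d_calc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "observed RDC (Hz)", y = "back-calculated RDC (Hz)",
      title = sprintf("Alignment tensor fit (Q = %.3f)", object$q)
    )
}

#' Predicted-vs-experimental shift comparison plot
#'
#' @param predicted Tibble from [predict_shifts()] or [ensemble_shifts()]
#'   (uses column `total` or `mean`).
#' @param experimental Tibble with `resno` and `shift`.
#' @return A ggplot object.
#' @export
plot_shift_comparison <- function(predicted, experimental) {
  pv <- if ("total" %in% names(predicted)) "total" else "mean"
  m <- dplyr::inner_join(predicted, experimental, by = "resno")
  ggplot2::ggplot(m, ggplot2::aes(x = .data$shift, y = .data[[pv]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "experimental shift (ppm)", y = "predicted shift (ppm)")
}
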