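#' Plot spectra
#'
#' Line plot of every spectrum against wavelength, optionally coloured by a
#' metadata column.
#'
#' @param ds a [spectral_dataset()].
#' @param colour_by optional metadata column (`"cow_id"`).
#' @param alpha line transparency.
#' @return a ggplot object.
#' @export
plot_spectra <- function(ds, colour_by = NULL, alpha = 0.4) {
  stopifnot(inherits(ds, "spectral_dataset"))
  X <- ds$intensities
  colnames(X) <- as.character(ds$wavelengths_nm)
  long <- dplyr::bind_cols(ds$meta, tibble::as_tibble(X)) |>
    tidyr::pivot_longer(-c("sample_id", "cow_id"),
                        names_to = "wavelength_nm", values_to = "value") |>
    dplyr::mutate(wavelength_nm = as.numeric(.data$wavelength_nm))
  aes <- if (is.null(colour_by)) {
    ggplot2::aes(.data$wavelength_nm, .data$value, group = .data$sample_id)
  } else {
    ggplot2::aes(.data$wavelength_nm, .data$value, group = .data$sample_id,
                 colour = .data[[colour_by]])
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(x = "wavelength (nm)", y = ds$mode,
                  title = ds$instrument_label) +
    ggplot2::theme_minimal()
}

#' RMSECV against the number of latent variables
#'
#' @param object a [cross_validate()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$n_latent, .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "latent variables", y = "RMSECV",
                  title = object$chain) +
    ggplot2::theme_minimal()
}

#' Predicted against reference scatter plot
#'
#' @param object an [evaluate_predictions()] result.
#' @param ... unused.
#' @return a ggplot object with the identity line.
#' @export
autoplot.eval_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$reference, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("reference %s (%% w/w)", object$component),
      y = "predicted (% w/w)",
      title = sprintf("%s: RMSEP = %.3f, R²p = %.2f",
                      object$spectrometer, object$rmsep, object$r2p)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
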