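#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the spectra of a dataset
#'
#' One line per spectrum over the wavenumber grid, drawn high-to-low
#' wavenumber as is conventional for vibrational spectra, coloured by
#' sample age.
#'
#' @param ds Spectral dataset tibble.
#' @param colour_by Metadata column used for the colour scale.
#' @return A ggplot object.
#' @export
plot_spectra <- function(ds, colour_by = "age_months") {
  long <- ds |>
    tidyr::pivot_longer(dplyr::matches("^[0-9.]+$"),
                        names_to = "wavenumber", values_to = "absorbance") |>
    dplyr::mutate(wavenumber = as.numeric(.data$wavenumber))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                     group = interaction(.data$sample_id,
                                                         .data[[colour_by]]),
                                     colour = .data[[colour_by]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "absorbance (a.u.)") +
    ggplot2::theme_minimal()
}

#' @describeIn run_als Plot the resolved component spectra.
#' @param object,... An `mcr_fit`; further arguments ignored.
#' @export
autoplot.mcr_fit <- function(object, ...) {
  wn <- object$wavenumbers %||% seq_len(nrow(object$S_hat))
  long <- tibble::tibble(
    wavenumber = rep(wn, ncol(object$S_hat)),
    component = rep(colnames(object$S_hat), each = length(wn)),
    intensity = as.vector(object$S_hat)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$intensity,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "intensity (a.u.)",
                  title = sprintf("Resolved spectra (LoF %.2f%%)",
                                  object$lof * 100)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_rate_constants Plot observed concentrations with the
#'   fitted kinetic curves.
#' @param object,... A `kinetic_fit`; further arguments ignored.
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  aug <- augment(object)
  grid_t <- seq(0, max(aug$time) * 1.02, length.out = 200)
  curves <- if (!is.null(object$k21)) {
    dplyr::bind_rows(
      dplyr::mutate(profile_long(grid_t, object$k1, object$k21, object$c0),
                    scope = "tablets"),
      dplyr::mutate(profile_long(grid_t,
                                 if (object$shared_k1) object$k1
                                 else object$fit_substances$k1,
                                 object$k22, object$c0),
                    scope = "substances")
    )
  } else {
    dplyr::mutate(profile_long(grid_t, object$k1, object$k2, object$c0),
                  scope = "data")
  }
  ggplot2::ggplot(aug, ggplot2::aes(.data$time, .data$observed,
                                    colour = .data$component)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$scope), alpha = 0.7) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$time, .data$concentration,
                                    linetype = .data$scope)) +
    ggplot2::labs(x = "age (months)", y = "concentration (fraction)") +
    ggplot2::theme_minimal()
}

profile_long <- function(times, k1, k2, c0) {
  two_step_profile(times, two_step_model(k1, k2, c0)) |>
    tidyr::pivot_longer(-"time", names_to = "component",
                        values_to = "concentration")
}

#' @describeIn run_pipeline Plot the final resolved spectra and joint
#'   kinetic fit of a pipeline run.
#' @param object,... A `pipeline_report`; further arguments ignored.
#' @export
autoplot.pipeline_report <- function(object, ...) {
  autoplot(object$steps$step3$kinetics)
}
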