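#' Plot ensemble state populations
#'
#' @param pops data.frame from [ensemble_populations()].
#' @return a ggplot object.
#' @export
plot_populations <- function(pops) {
  require_ggplot()
  pops$state <- factor(paste0("S", pops$state))
  ggplot2::ggplot(pops, ggplot2::aes(x = .data$time_fs,
                                     y = .data$population,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$population - .data$se,
                                      ymax = .data$population + .data$se,
                                      fill = .data$state),
                         alpha = 0.2, colour = NA) +
    ggplot2::labs(x = "time / fs", y = "population") +
    ggplot2::theme_minimal()
}

#' Plot an absorption spectrum
#'
#' @param spec list from [ensemble_spectrum()] or a data.frame with
#'   energy_ev/intensity.
#' @return a ggplot object.
#' @export
plot_spectrum <- function(spec) {
  require_ggplot()
  df <- if (is.data.frame(spec)) spec else spec$spectrum
  ggplot2::ggplot(df, ggplot2::aes(x = .data$energy_ev,
                                   y = .data$intensity)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "energy / eV", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a grid error map
#'
#' @param map data.frame from [prediction_error_map()] or
#'   [error_difference_map()].
#' @return a ggplot object.
#' @export
plot_error_map <- function(map) {
  require_ggplot()
  val <- if ("delta" %in% names(map)) "delta" else "log10_error"
  ggplot2::ggplot(map, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                    fill = .data[[val]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "deeppink4") +
    ggplot2::labs(x = "mode 1 / Bohr", y = "mode 2 / Bohr", fill = val) +
    ggplot2::theme_minimal()
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
}
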