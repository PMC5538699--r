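#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tidal ventilation image
#'
#' Raster display in anatomical orientation: anterior at the top, the
#' animal's right on the left-hand side.
#'
#' @param object a `tidal_image`
#' @param ... unused
#' @export
autoplot.tidal_image <- function(object, ...) {
  n <- nrow(object$pixels)
  d <- tidyr::expand_grid(row = seq_len(n), col = seq_len(n))
  d$value <- as.vector(t(object$pixels))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * Z)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "right → left", y = "posterior ← anterior",
                  title = sprintf("Tidal image (%s)", object$masks_applied)) +
    ggplot2::theme_minimal()
}

#' Plot an anteroposterior ventilation profile
#'
#' @param object a `vent_profile`
#' @param ... additional profiles to overlay, named
#' @export
autoplot.vent_profile <- function(object, ...) {
  extra <- list(...)
  d <- dplyr::mutate(object, series = "profile")
  for (nm in names(extra)) {
    d <- dplyr::bind_rows(d, dplyr::mutate(extra[[nm]], series = nm))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$vd, y = .data$band,
                                  colour = .data$series)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "ventilation fraction (%)",
                  y = "band (anterior → posterior)") +
    ggplot2::theme_minimal()
}

#' Plot per-variant RMSE distributions of a model evaluation
#'
#' @param object a `model_evaluation`
#' @param ... unused
#' @export
autoplot.model_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$rmse,
                  ggplot2::aes(x = .data$variant, y = .data$rmse)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = "reconstruction variant", y = "profile RMSE (%)") +
    ggplot2::theme_minimal()
}

#' Plot sweep correlations by setting
#'
#' @param object a `sweep_result`
#' @param ... unused
#' @export
autoplot.sweep_result <- function(object, ...) {
  d <- dplyr::filter(object$results, !is.na(.data$correlation))
  d$label <- paste0(d$algorithm, " ", d$reference, " ", d$background,
                    " nf=", d$nf)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$correlation,
                                  y = stats::reorder(.data$label,
                                                     .data$correlation,
                                                     mean))) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$subject))) +
    ggplot2::labs(x = "2D correlation with reference tidal image",
                  y = NULL, colour = "subject") +
    ggplot2::theme_minimal()
}
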