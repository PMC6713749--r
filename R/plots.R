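#' Plot strain curves over the cardiac cycle
#'
#' Longitudinal, circumferential and radial aggregate strain per frame, in
#' the layout conventional for LV strain reporting (negative longitudinal
#' and circumferential strain during systole).
#'
#' @param object a [strain_curves()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.strain_curves <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(frame = object$frame, direction = "longitudinal",
                   strain = object$E_L),
    tibble::tibble(frame = object$frame, direction = "circumferential",
                   strain = object$E_C),
    tibble::tibble(frame = object$frame, direction = "radial",
                   strain = object$E_R))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$strain,
                                     colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "frame", y = "strain",
                  title = "Directional strain over the cardiac cycle") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot median eigenvalue curves
#'
#' The three per-frame median principal strains (sorted ascending), the
#' eigenvalue-curve validation protocol.
#'
#' @param curves a [strain_curves()] tibble.
#' @return a ggplot object.
#' @export
plot_eigenvalue_curves <- function(curves) {
  long <- dplyr::bind_rows(lapply(1:3, function(k) {
    tibble::tibble(frame = curves$frame,
                   eigenvalue = paste0("eig", k),
                   value = curves[[paste0("eig", k)]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value,
                                     colour = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "frame", y = "median principal strain",
                  title = "Eigenvalue curves over the cardiac cycle") +
    ggplot2::theme_minimal()
}
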