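#' Plot a speed or angle trace
#'
#' Line plot of the trace over time with illuminated episodes shaded.
#'
#' @param object A `speed_trace` or `angle_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.speed_trace <- function(object, ...) {
  trace_plot(object, "speed_um_s", "mean speed (µm/s)")
}

#' @rdname autoplot.speed_trace
#' @export
autoplot.angle_trace <- function(object, ...) {
  trace_plot(object, "angle_rad", "mean deviation angle (rad)")
}

trace_plot <- function(object, ycol, ylab) {
  on <- episode_spans(object)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_s, y = .data[[ycol]]))
  if (nrow(on) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = on, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      fill = "gold", alpha = 0.25)
  }
  p + ggplot2::geom_line(colour = "grey25") +
    ggplot2::labs(x = "time (s)", y = ylab) +
    ggplot2::theme_minimal()
}

# contiguous illuminated spans from a trace's intensity annotation
episode_spans <- function(trace) {
  lit <- trace$intensity_uW_mm2 > 0
  if (!any(lit)) return(tibble::tibble(t_start = numeric(), t_end = numeric()))
  r <- rle(lit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(t_start = trace$time_s[starts[keep]],
                 t_end = trace$time_s[ends[keep]])
}

#' Plot a PIV velocity field
#'
#' Arrow plot of the valid velocity vectors on the interrogation grid.
#'
#' @param object A `piv_field`.
#' @param arrow_scale Arrow length per um/s (in um of plot space); default
#'   scales the median speed to one grid step.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.piv_field <- function(object, arrow_scale = NULL, ...) {
  v <- object[object$valid, ]
  spd <- sqrt(v$vx_um_s^2 + v$vy_um_s^2)
  arrow_scale <- arrow_scale %||%
    (attr(object, "step_um") / max(median(spd), 1e-12))
  ggplot2::ggplot(v, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x_um + arrow_scale * .data$vx_um_s,
                   yend = .data$y_um + arrow_scale * .data$vy_um_s,
                   colour = sqrt(.data$vx_um_s^2 + .data$vy_um_s^2)),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(name = "|v| (µm/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a strain trace
#'
#' @param object A `strain_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strain_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as.data.frame(object),
                              cols = c("gamma_xx", "gamma_yy"),
                              names_to = "component", values_to = "strain")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$strain,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "cumulative strain") +
    ggplot2::theme_minimal()
}

#' Plot a threshold dataset with fitted models
#'
#' Threshold intensity versus region length, with the confinement-model
#' prediction and (optionally) the generic inverse-square fit overlaid.
#'
#' @param object A `threshold_dataset`.
#' @param fit Optional `stability_fit`.
#' @param generic Optional `generic_scaling_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_dataset <- function(object, fit = NULL, generic = NULL,
                                       ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$L_um,
                                            y = .data$I_threshold)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "region length L (µm)",
                  y = "threshold intensity") +
    ggplot2::theme_minimal()
  Ls <- seq(min(object$L_um), max(object$L_um), length.out = 200)
  if (!is.null(fit)) {
    W <- approx(object$L_um, object$W_um, xout = Ls, rule = 2)$y
    H <- approx(object$L_um, object$H_um, xout = Ls, rule = 2)$y
    curve <- tibble::tibble(L = Ls, I = predict_threshold(Ls, W, H, fit))
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(x = .data$L, y = .data$I),
                                colour = "red")
  }
  if (!is.null(generic)) {
    curve <- tibble::tibble(
      L = Ls, I = generic$params["gA"] / Ls^2 + generic$params["gC"])
    p <- p + ggplot2::geom_line(data = curve,
                                ggplot2::aes(x = .data$L, y = .data$I),
                                colour = "grey40", linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
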