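#' Plot a simulated circuit trajectory
#'
#' One line per species over time, with the piecewise-constant input
#' signal shaded in the background.
#'
#' @param object A `circuit_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.circuit_trajectory <- function(object, ...) {
  long <- tidy(object)
  sig <- attr(object, "signal")
  bounds <- unique(c(0, sig$breakpoints[sig$breakpoints < max(object$time)],
                     max(object$time)))
  shading <- tibble::tibble(
    xmin = bounds[-length(bounds)], xmax = bounds[-1],
    level = signal_at(sig, bounds[-length(bounds)]))
  ggplot2::ggplot(long) +
    ggplot2::geom_rect(
      data = shading,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, alpha = .data$level),
      fill = "grey70", show.legend = FALSE) +
    ggplot2::scale_alpha_continuous(range = c(0, 0.25)) +
    ggplot2::geom_line(ggplot2::aes(.data$time, .data$level,
                                    colour = .data$species)) +
    ggplot2::labs(x = "time (a.u.)", y = "level (a.u.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation diagram
#'
#' Stable branches solid, unstable dashed, folds as vertical dotted
#' lines.
#'
#' @param object A `bifurcation_diagram`.
#' @param species Species on the y axis (default first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bifurcation_diagram <- function(object, species = NULL, ...) {
  pts <- object$points
  if (is.null(species))
    species <- setdiff(names(pts), c("param", "stable", "max_re_eig"))[1]
  p <- ggplot2::ggplot(pts,
                       ggplot2::aes(.data$param, .data[[species]])) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$stable), size = 1) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "stable",
                                           `FALSE` = "unstable")) +
    ggplot2::labs(x = object$parameter, y = species, shape = NULL,
                  subtitle = paste0("switching: ", object$reversibility)) +
    ggplot2::theme_minimal()
  if (length(object$folds))
    p <- p + ggplot2::geom_vline(xintercept = object$folds,
                                 linetype = "dotted")
  p
}

#' Plot the three SOX10->MITF input-function models
#'
#' Overlays the linear, saturated and sigmoidal response curves over a
#' SOX10 grid, with the phenotype zones of a [phenotype_map()] shaded on
#' the MITF axis.
#'
#' @param specs Named list of [input_function_spec()] objects.
#' @param sox10_grid Input grid.
#' @param map Optional `phenotype_map` for zone shading.
#' @return A ggplot.
#' @export
plot_input_functions <- function(specs = list(
                                   linear = input_function_spec("linear"),
                                   saturated =
                                     input_function_spec("saturated"),
                                   sigmoidal =
                                     input_function_spec("sigmoidal")),
                                 sox10_grid = seq(0, 2, length.out = 201),
                                 map = NULL) {
  curves <- purrr::imap_dfr(specs, function(sp, nm)
    tibble::tibble(model = nm, sox10 = sox10_grid,
                   mitf = input_response(sp, sox10_grid)))
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(.data$sox10, .data$mitf,
                                    colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "SOX10 level (a.u.)", y = "MITF level (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(map)) {
    bands <- tibble::tibble(
      ymin = c(-Inf, map$boundaries), ymax = c(map$boundaries, Inf),
      zone = factor(map$labels, levels = map$labels))
    p <- p + ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE,
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$ymin,
                   ymax = .data$ymax, fill = .data$zone),
      alpha = 0.12) +
      ggplot2::labs(fill = "phenotype")
  }
  p
}
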