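# ggplot2 views of the main result types.

#' @export
autoplot.wb_trajectory <- function(object, vars = NULL, ...) {
  if (is.null(vars))
    vars <- intersect(c("V", "K_out", "Na_in"), names(object))
  long <- tidyr::pivot_longer(object[, c("t", vars)], -"t",
                              names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t / 1000, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y",
                        strip.position = "left") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wb_sim <- function(object, ...) {
  autoplot(object$trajectory, ...) +
    ggplot2::labs(title = sprintf("I_app = %g, I_max = %g: %s",
                                  object$params$I_app, object$params$I_max,
                                  object$regime))
}

#' @export
autoplot.wb_eq_branch <- function(object, ...) {
  bif <- attr(object, "bifurcations")
  gg <- ggplot2::ggplot(object,
                        ggplot2::aes(x = .data$K_out, y = .data$V,
                                     group = .data$curve,
                                     linetype = .data$stability)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::labs(x = "[K+]out (mM)", y = "V (mV)") +
    ggplot2::theme_minimal()
  if (nrow(bif))
    gg <- gg + ggplot2::geom_point(
      data = bif, ggplot2::aes(x = .data$K_out, y = .data$V,
                               shape = .data$type),
      inherit.aes = FALSE, size = 3, colour = "red")
  gg
}

#' @export
autoplot.wb_hysteresis <- function(object, ...) {
  br <- object$branches
  gg <- ggplot2::ggplot(br,
                        ggplot2::aes(x = .data$K_out, y = .data$dKdt * 1000,
                                     colour = .data$branch,
                                     alpha = .data$valid)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = "[K+]out (mM)", y = "d[K+]out/dt (mM/s)",
                  title = sprintf("reduced slow subsystem, I_app = %g, I_max = %g",
                                  object$I_app, object$params$I_max)) +
    ggplot2::theme_minimal()
  if (nrow(object$markers))
    gg <- gg + ggplot2::geom_vline(
      data = object$markers,
      ggplot2::aes(xintercept = .data$K_out),
      linetype = "dashed", colour = "grey40")
  if (nrow(object$fixed_points))
    gg <- gg + ggplot2::geom_point(
      data = object$fixed_points,
      ggplot2::aes(x = .data$K_out, y = 0), inherit.aes = FALSE,
      shape = 21, size = 3, fill = "black")
  gg
}

#' @export
autoplot.wb_regime_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$I_max, y = .data$I_app,
                               fill = .data$regime)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "I_max (uA/cm2)", y = "I_app (uA/cm2)") +
    ggplot2::theme_minimal()
}
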