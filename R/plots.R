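#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's result
#' objects; `plot_state()` draws a top (x, y) or side (x, z) projection of a
#' particle state with rods highlighted.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plots
#' @export
autoplot.delta_f_curve <- function(object, ...) {
  p <- attr(object, "params")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$C_1, y = .data$dF)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = attr(object, "min_C1"),
                      y = attr(object, "min_dF"), colour = "red") +
    ggplot2::labs(
      x = expression(C[1] ~ (1 / r[rod])),
      y = expression(Delta * F ~ (k[B] * T ~ r[rod]^-2 ~ "per area")),
      title = sprintf("Hexagonal vs striped array: phi = %.2g, C_side = %.2g",
                      p$phi_rod, p$C_side))
}

#' @rdname plots
#' @export
autoplot.kappa_fit <- function(object, ...) {
  sp <- object$spectrum
  sp$fit <- object$kT * object$area /
    (object$kappa * sp$q^4 + object$gamma * sp$q^2)
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$S)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (1/sigma)", y = expression("<|h"[q] * "|"^2 * ">"),
                  title = sprintf("kappa/kT = %.2f +/- %.2f",
                                  object$kappa / object$kT,
                                  object$se / object$kT))
}

#' @rdname plots
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  ggplot2::ggplot(object$msd, ggplot2::aes(x = .data$lag_time, y = .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 4 * object$D, intercept = 0,
                         colour = "red", linetype = 2) +
    ggplot2::labs(x = "lag time", y = "in-plane MSD (sigma^2)",
                  title = sprintf("D = %.3g sigma^2/time", object$D))
}

#' @rdname plots
#' @export
autoplot.rod_protocol <- function(object, ...) {
  obs <- object$obs
  cols <- intersect(c("mean_cluster_size", "z_cl", "n_tubules"), names(obs))
  long <- tidyr::pivot_longer(obs[, c("time_tau", cols)], -"time_tau")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_tau, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "t (tau)", y = NULL)
}

#' @rdname plots
#' @param state A `particle_state`.
#' @param view `"top"` (x, y) or `"side"` (x, z).
#' @export
plot_state <- function(state, view = c("top", "side")) {
  view <- match.arg(view)
  ycol <- if (view == "top") "y" else "z"
  ggplot2::ggplot(state, ggplot2::aes(x = .data$x, y = .data[[ycol]],
                                      colour = .data$type)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c(membrane = "skyblue3",
                                            rod = "red3")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (sigma)", y = sprintf("%s (sigma)", ycol))
}
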