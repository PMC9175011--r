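#' Plot a reference solution
#'
#' @param object A `rop_reference`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rop_reference <- function(object, ...) {
  df <- tibble(x = object$grid, u = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$u)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(
      x = "scaled position", y = expression(U[alpha](x)),
      title = sprintf("Reference solution, alpha = %g (peak %.3f, mass %.2f)",
                      object$alpha, object$peak, object$mass)) +
    ggplot2::theme_minimal()
}

#' Plot a single-tube fit
#'
#' Observations with the fitted profile `lambda * U_alpha(mu * x)` overlaid.
#'
#' @param object A `tube_fit`.
#' @param n_curve Number of points used to draw the fitted curve.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tube_fit <- function(object, n_curve = 400, ...) {
  ref <- resolve_reference(NULL, object$constants)
  xs <- seq(min(object$data$x), max(object$data$x), length.out = n_curve)
  curve <- tibble(
    x = xs,
    y = evaluate_profile(object$lambda, object$mu, xs, ref = ref,
                         constants = object$constants))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(
      x = "membrane position (um)", y = "ROP1 intensity",
      title = sprintf("lambda = %.3f, mu = %.3f, knf = %.3f, kpf = %.3f",
                      object$lambda, object$mu, object$knf, object$kpf)) +
    ggplot2::theme_minimal()
}

#' Plot a population fit
#'
#' Scatter of the per-tube shape estimates with the population mean and its
#' confidence ellipse axis summaries.
#'
#' @param object A `population_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.population_fit <- function(object, ...) {
  est <- per_tube_estimates(object)
  centre <- tibble(mu = object$theta0[["mu"]],
                   lambda = object$theta0[["lambda"]])
  ggplot2::ggplot(est, ggplot2::aes(x = .data$mu, y = .data$lambda)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = centre, colour = "#b2182b", size = 3,
                        shape = 4, stroke = 1.2) +
    ggplot2::labs(
      x = expression(hat(mu)[i]), y = expression(hat(lambda)[i]),
      title = sprintf("Population of %d tubes: rho(lambda, mu) = %.2f",
                      object$m, object$rho_shape)) +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of tube profiles
#'
#' @param data Long data frame with `tube_id`, `x`, `y`.
#' @return A ggplot with one line per tube.
#' @export
plot_tubes <- function(data) {
  stopifnot(all(c("tube_id", "x", "y") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$tube_id)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.4) +
    ggplot2::labs(x = "membrane position (um)", y = "ROP1 intensity") +
    ggplot2::theme_minimal()
}
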