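#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a segment's component trajectory and loadings
#'
#' Score panel: the PC1 session trajectory with its BCa intervals (a
#' plastic segment shows overlapping baseline/control intervals and a
#' non-overlapping post-training interval). Loading panel: per-metric PC1
#' loadings with intervals; intervals excluding zero mark significant
#' metric contributions.
#'
#' @param object A `segment_asca_boot`.
#' @param ... Unused.
#' @return A ggplot object (two facets: scores and loadings).
#' @export
autoplot.segment_asca_boot <- function(object, ...) {
  d <- object$ci |>
    dplyr::mutate(label = factor(.data$label,
                                 levels = c(object$model$sessions,
                                            object$model$metrics)),
                  kind = factor(.data$kind, levels = c("score", "loading")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::facet_wrap(~kind, scales = "free_x") +
    ggplot2::labs(
      title = sprintf("%s, segment %s (PC1: %.0f%% of time-effect variance)",
                      object$model$tract,
                      paste(range(object$model$segment), collapse = "-"),
                      100 * object$model$explained_variance[1]),
      x = NULL, y = "PC1 value (95% BCa CI)") +
    ggplot2::theme_minimal()
}

#' Plot the Monte Carlo null count distribution
#'
#' Histogram of simulated false-positive counts with the observed count
#' marked; the p-value is the mass at or beyond the line.
#'
#' @param object An `mc_null`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_null <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$count, y = .data$n_iterations)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$config$observed,
                        colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "false-positive segments per iteration",
                  y = "iterations",
                  title = sprintf("Monte Carlo null: P(count >= %d) = %.4f",
                                  object$config$observed, object$p)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted learning curve
#'
#' Session means with the fitted power-law curve.
#'
#' @param object A `learning_curve_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.learning_curve_fit <- function(object, ...) {
  grid <- tibble::tibble(s = seq(min(object$means$s), max(object$means$s),
                                 length.out = 100))
  grid$y <- (object$c %||% 0) + object$a * grid$s^object$b
  ggplot2::ggplot(object$means, ggplot2::aes(x = .data$s, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "training session", y = "mean balance time (s)",
                  title = sprintf("a = %.2f, b = %.2f", object$a, object$b)) +
    ggplot2::theme_minimal()
}

#' Plot a robust regression fit
#'
#' Scatter of response versus the (single) predictor with the MM regression
#' line; point size reflects the robustness weight (down-weighted outliers
#' shrink).
#'
#' @param object A `robust_fit` with one predictor.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.robust_fit <- function(object, ...) {
  mf <- stats::model.frame(object$fit)
  abort_if(ncol(mf) != 2, "autoplot supports single-predictor fits")
  d <- tibble::tibble(x = mf[[2]], y = mf[[1]], w = object$weights)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$w), alpha = 0.7,
                        show.legend = FALSE) +
    ggplot2::geom_abline(intercept = object$coef$estimate[1],
                         slope = object$coef$estimate[2],
                         colour = "steelblue") +
    ggplot2::scale_size(range = c(0.5, 2.5)) +
    ggplot2::labs(x = names(mf)[2], y = names(mf)[1],
                  title = sprintf("b = %.2f, robust R2 = %.2f",
                                  object$coef$estimate[2], object$r2)) +
    ggplot2::theme_minimal()
}
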