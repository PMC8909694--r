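#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot selection-frequency profiles of a cross-validation ensemble
#'
#' @param object A `cv_result`.
#' @param top Show at most this many regulators (default 20).
#' @param ... Unused.
#' @return A ggplot bar chart of selection frequencies.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, top = 20, ...) {
  df <- utils::head(object$frequencies, top)
  df$regulator <- factor(df$regulator, levels = rev(df$regulator))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$regulator)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = paste0("selection frequency (n = ", object$n_models, " models)"),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the direct/indirect count curves of a lambda sweep
#'
#' Mirrors the tuning diagnostic: total selected direct and indirect
#' regulators per lambda on a log axis, with the tuned crossing marked.
#'
#' @param object A `lambda_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lambda_sweep
#' @export
autoplot.lambda_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$sweep[, c("lambda", "n_direct", "n_indirect")],
    cols = c("n_direct", "n_indirect"),
    names_to = "part", values_to = "count"
  )
  df$part <- ifelse(df$part == "n_direct", "direct (regression)",
                    "indirect (modularity)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$count,
                                   colour = .data$part)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$lambda_star, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c("direct (regression)" = "firebrick",
                                            "indirect (modularity)" = "navy")) +
    ggplot2::labs(x = expression(lambda), y = "total selections",
                  colour = NULL,
                  subtitle = paste0("lambda* = ",
                                    signif(object$lambda_star, 4))) +
    ggplot2::theme_minimal()
}

#' Plot mean held-out performance against lambda
#'
#' @param sweep A `lambda_sweep`.
#' @return A ggplot object.
#' @export
plot_performance <- function(sweep) {
  stopifnot(inherits(sweep, "lambda_sweep"))
  ggplot2::ggplot(sweep$sweep,
                  ggplot2::aes(x = .data$lambda, y = .data$mean_performance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sweep$lambda_star, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "mean held-out Pearson r") +
    ggplot2::theme_minimal()
}
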