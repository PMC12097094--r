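# ggplot2 views of the main result types

#' Plot a fitted EC~IC decay with its training pairs
#'
#' Scatter of observed (IC, EC) pairs with the fitted curve
#' `A * exp(-IC / tau)` overlaid.
#'
#' @param object An [fit_ec_ic()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ecic_fit <- function(object, ...) {
  grid <- tibble(ic = seq(0, max(object$data$ic), length.out = 200))
  grid$ec <- object$A * exp(-grid$ic / object$tau)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ic, y = .data$ec)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "interaction-frequency change (IC)",
      y = "expression change (EC)",
      title = sprintf("EC = %.3g exp(-IC / %.3g)", object$A, object$tau)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a virtual-4C profile
#'
#' @param profile Output of [virtual_4c()].
#' @param viewpoint Optional region tibble; drawn as a shaded band.
#' @return A ggplot object.
#' @export
plot_virtual_4c <- function(profile, viewpoint = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(
      x = sprintf("position on %s (bp)", profile$chrom[1]),
      y = "contact with viewpoint"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(viewpoint)) {
    p <- p + ggplot2::annotate("rect",
      xmin = viewpoint$start, xmax = viewpoint$end,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick"
    )
  }
  p
}

#' Plot scored variant-gene pairs
#'
#' Observed EC against IC, coloured by 3DFunc score, with the fitted decay
#' curve.
#'
#' @param scored Output of [score_pairs()].
#' @param fit The [fit_ec_ic()] model used for scoring.
#' @return A ggplot object.
#' @export
plot_scored_pairs <- function(scored, fit) {
  grid <- tibble(ic = seq(0, max(scored$ic), length.out = 200))
  grid$ec <- fit$A * exp(-grid$ic / fit$tau)
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$ic, y = .data$ec, colour = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, inherit.aes = FALSE, ggplot2::aes(x = .data$ic, y = .data$ec)) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "IC", y = "EC", colour = "score") +
    ggplot2::theme_minimal()
}
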