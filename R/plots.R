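#' Plot stage-1 versus stage-3 efficiency
#'
#' One point per unit: across-period mean TE before (x) and after (y) the
#' environmental adjustment, with the diagonal for reference. Units above
#' the diagonal were held back by an unfavourable environment or bad luck in
#' stage 1; units below it looked better than their management warranted.
#'
#' @param object A [three_stage_dea()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.three_stage_result <- function(object, ...) {
  m1 <- object$summary$stage1$unit_means
  m3 <- object$summary$stage3$unit_means
  d <- dplyr::inner_join(m1, m3, by = "unit", suffix = c("_stage1", "_stage3"))
  ggplot2::ggplot(d, ggplot2::aes(.data$mean_stage1, .data$mean_stage3,
                                  label = .data$unit)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1.02), ylim = c(0, 1.02)) +
    ggplot2::labs(x = "Stage-1 mean TE (raw inputs)",
                  y = "Stage-3 mean TE (adjusted inputs)",
                  title = "Efficiency before and after environmental adjustment") +
    ggplot2::theme_minimal()
}

#' Plot an SFA slack frontier fit
#'
#' Composed residuals against fitted slack, coloured by the JLMS
#' inefficiency share `u / (|u| + |v|)`: points whose residual the model
#' attributes mostly to inefficiency show dark.
#'
#' @param object An [sfa_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sfa_fit <- function(object, ...) {
  dc <- sfa_decompose(object)
  dc$share <- dc$u / pmax(abs(dc$u) + abs(dc$v), 1e-12)
  ggplot2::ggplot(dc, ggplot2::aes(.data$.fitted, .data$.resid,
                                   colour = .data$share)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "grey80", high = "black",
                                   name = "ineff. share") +
    ggplot2::labs(x = "Fitted slack (z' beta)", y = "Composed residual",
                  title = sprintf("Half-normal frontier: gamma = %.2f",
                                  object$gamma)) +
    ggplot2::theme_minimal()
}

#' Plot a correlation screen
#'
#' Heatmap of the pairwise Pearson correlations from [pearson_screen()].
#'
#' @param object A [pearson_screen()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_screen <- function(object, ...) {
  rmat <- attr(object, "r_matrix")
  d <- tibble::as_tibble(as.table(rmat), .name_repair = "minimal")
  names(d) <- c("var1", "var2", "r")
  ggplot2::ggplot(d, ggplot2::aes(.data$var1, .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Input-output Pearson screen") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
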