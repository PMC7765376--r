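#' Heatmap of a synergy surface
#'
#' Tile heatmap of a [delta_bliss()] or [excess_hsa()] surface on the dose
#' grid (log-spaced axes shown as ordered factors). Blue = negative =
#' synergy, red = positive = antagonism.
#'
#' @param object A `synergy_surface` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synergy_surface <- function(object, ...) {
  metric <- attr(object, "metric")
  value_col <- if (metric == "delta_bliss") "delta" else "excess"
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    doseA = factor(format(.data$doseA * 1e9, digits = 3), ordered = TRUE,
                   levels = format(sort(unique(.data$doseA)) * 1e9, digits = 3)),
    doseB = factor(format(.data$doseB * 1e9, digits = 3), ordered = TRUE,
                   levels = format(sort(unique(.data$doseB)) * 1e9, digits = 3))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$doseB, y = .data$doseA,
                                   fill = .data[[value_col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(
      x = "drug B dose (nM)", y = "drug A dose (nM)",
      fill = if (metric == "delta_bliss") "delta Bliss" else "excess HSA",
      title = if (metric == "delta_bliss") {
        "Deviation from Bliss independence"
      } else {
        "Excess over highest single agent"
      },
      subtitle = "negative (blue) = synergy"
    ) +
    ggplot2::theme_minimal()
}

#' Median-effect fit over its data
#'
#' Plots observed fraction affected against dose (log scale) with the fitted
#' median-effect curve `fa = (D/Dm)^m / (1 + (D/Dm)^m)`.
#'
#' @param object A `medfit`.
#' @param doses,fa The data the fit was made on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.medfit <- function(object, doses, fa, ...) {
  pos <- doses > 0
  curve_d <- exp(seq(log(min(doses[pos])), log(max(doses[pos])), length.out = 100))
  ratio <- (curve_d / object$Dm)^object$m
  curve <- tibble::tibble(dose = curve_d, fa = ratio / (1 + ratio))
  ggplot2::ggplot(tibble::tibble(dose = doses[pos], fa = fa[pos]),
                  ggplot2::aes(x = .data$dose, y = .data$fa)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "#2166AC") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (M)", y = "fraction affected",
                  title = sprintf("Median-effect fit: Dm = %.3g nM, m = %.2f",
                                  object$Dm * 1e9, object$m)) +
    ggplot2::theme_minimal()
}

#' Hit fraction per mechanism-of-action class
#'
#' @param class_summary Output of [aggregate_by_class()].
#' @return A ggplot bar chart of per-class hit fractions annotated with
#'   hits/tested counts.
#' @export
plot_class_summary <- function(class_summary) {
  df <- dplyr::mutate(class_summary,
                      moa_class = stats::reorder(.data$moa_class, .data$hit_fraction))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$moa_class, y = .data$hit_fraction)) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$n_hits, "/", .data$n_tested)),
                       hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "hit fraction",
                  title = "Synergy hits by mechanism-of-action class") +
    ggplot2::theme_minimal()
}
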