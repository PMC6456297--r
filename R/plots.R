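# ggplot2 views of the main result types.

#' MA plot of a tile comparison
#'
#' log2 fold change against mean signal, with the conventional +/-2
#' guide lines.
#'
#' @param object A `tile_comparison` from [tile_log2fc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tile_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = log2(.data$mean_signal + 1),
                                       y = .data$log2fc)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::labs(x = "log2(mean signal + 1)", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Metagene profile plot
#'
#' Mean log2 fold change (with standard-error ribbon) around the
#' highest-signal tiles.
#'
#' @param object A `metagene_profile` from [top_tile_metagene()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$mean_log2fc)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_log2fc - .data$se_log2fc,
      ymax = .data$mean_log2fc + .data$se_log2fc), alpha = 0.3) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "tile offset from anchor", y = "mean log2 fold change") +
    ggplot2::theme_minimal()
}

#' Distance-distribution plot
#'
#' Empirical cumulative distributions of the distance to the nearest
#' feature for the query and background sets.
#'
#' @param object A `distance_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_comparison <- function(object, ...) {
  ggplot2::ggplot(object$distances,
                  ggplot2::aes(x = .data$distance, colour = .data$set)) +
    ggplot2::stat_ecdf() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance to nearest feature (bp)",
                  y = "cumulative fraction",
                  title = object$summary$label) +
    ggplot2::theme_minimal()
}

#' Sperm-vs-soma delta scatter of shared DMRs
#'
#' @param object A `persistence_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.persistence_report <- function(object, ...) {
  ggplot2::ggplot(object$persistent,
                  ggplot2::aes(x = .data$delta_sperm, y = .data$delta_soma)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "sperm methylation delta (points)",
                  y = "soma methylation delta (points)",
                  title = "persistent (concordant-hyper) DMRs") +
    ggplot2::theme_minimal()
}
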