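#' Quantile-quantile plot of burden-scan p-values
#'
#' Observed versus expected -log10 p-values under the uniform null, with
#' the identity line; the standard inflation diagnostic for a genome-wide
#' scan.
#'
#' @param scan A `vt_scan`, or a numeric vector of p-values.
#' @return A ggplot object.
#' @export
plot_qq <- function(scan) {
  p <- if (inherits(scan, "vt_scan")) scan$results$perm_p else scan
  p <- sort(p)
  df <- tibble::tibble(
    expected = -log10(seq_along(p) / (length(p) + 1)),
    observed = -log10(p)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](italic(p))),
      y = expression(Observed ~ -log[10](italic(p)))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_qq
#' @param object A `vt_scan`.
#' @param ... Unused.
#' @export
autoplot.vt_scan <- function(object, ...) plot_qq(object)

#' Scatter plot of a PC-based gene ranking
#'
#' PC1 against the ranking component, highlighting a gene set (typically
#' the known risk genes used to orient the component).
#'
#' @param ranking A `pc_ranking` from [pc_ranking()].
#' @param highlight Character vector of genes to highlight.
#' @return A ggplot object.
#' @export
plot_pc_ranking <- function(ranking, highlight = character()) {
  df <- dplyr::mutate(
    tibble::as_tibble(ranking),
    set = ifelse(.data$gene %in% highlight, "highlighted", "background")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc_score,
                                   colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(background = "grey60", highlighted = "firebrick")
    ) +
    ggplot2::labs(x = "PC1", y = "ranking component") +
    ggplot2::theme_minimal()
}

#' @rdname plot_pc_ranking
#' @param object A `pc_ranking`.
#' @param ... Passed on as `highlight`.
#' @export
autoplot.pc_ranking <- function(object, ...) plot_pc_ranking(object, ...)
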