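#' Tidy a genome-wide burden scan
#'
#' @param x A `vt_scan` from [genomewide_scan()].
#' @param ... Unused.
#' @return The per-gene results tibble, ordered by permutation p-value.
#' @export
tidy.vt_scan <- function(x, ...) {
  dplyr::arrange(x$results, .data$perm_p, .data$gene)
}

#' One-row summary of a genome-wide burden scan
#'
#' @param x A `vt_scan`.
#' @param ... Unused.
#' @return Tibble with `n_tests`, `n_cases`, `n_controls`, `lambda_gc`,
#'   `bonferroni_threshold`, `n_significant` (FDR flags).
#' @export
glance.vt_scan <- function(x, ...) {
  tibble::tibble(
    n_tests = x$n_tests, n_cases = x$n_cases, n_controls = x$n_controls,
    lambda_gc = x$lambda_gc, bonferroni_threshold = x$bonferroni_threshold,
    n_significant = sum(x$results$significant)
  )
}

#' @export
print.vt_scan <- function(x, ...) {
  cat(sprintf(
    "Variable-threshold burden scan: %d tests (%d cases / %d controls)\n",
    x$n_tests, x$n_cases, x$n_controls
  ))
  cat(sprintf("  genomic-control lambda: %.3f\n", x$lambda_gc))
  cat(sprintf("  Bonferroni threshold:   %.3g\n", x$bonferroni_threshold))
  cat(sprintf("  genes at FDR < 0.1:     %d\n", sum(x$results$significant)))
  print(utils::head(tidy(x), 10))
  invisible(x)
}
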