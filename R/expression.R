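new_expr_matrix <- function(tbl, cell_counts, enriched_genes = NULL) {
  out <- tibble::as_tibble(tbl)
  attr(out, "cell_counts") <- cell_counts
  if (!is.null(enriched_genes)) attr(out, "enriched_genes") <- enriched_genes
  class(out) <- c("expr_matrix", class(out))
  out
}

#' Per-type cell counts of an expression matrix
#' @param m An `expr_matrix`.
#' @return Named integer vector of cells per retained cell type.
#' @export
cell_counts <- function(m) attr(m, "cell_counts")

expr_values <- function(m) {
  x <- as.matrix(m[, setdiff(names(m), "gene"), drop = FALSE])
  rownames(x) <- m$gene
  x
}

#' Fraction of expressing cells per gene and cell type
#'
#' Summarizes a single-cell count matrix to the fraction of cells of each
#' type with a nonzero count for each gene — the relative-expression metric
#' used for clustering and PC ranking. Cell types with fewer than
#' `min_cells` cells are dropped (small types give unstable fractions).
#'
#' @param counts Data frame with a `gene` column and one column of
#'   non-negative counts per cell.
#' @param cell_annotation Data frame with columns `cell` (matching the count
#'   columns) and `cell_type`.
#' @param min_cells Minimum cells per retained type.
#' @return An `expr_matrix`: tibble with `gene` plus one fraction column per
#'   retained cell type; per-type cell counts in `attr(, "cell_counts")`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2"),
#'                          c1 = c(0, 2), c2 = c(1, 0), c3 = c(0, 5), c4 = c(3, 1))
#' ann <- tibble::tibble(cell = c("c1", "c2", "c3", "c4"),
#'                       cell_type = "endothelial")
#' fraction_expressing(counts, ann, min_cells = 4)
fraction_expressing <- function(counts, cell_annotation, min_cells = 70) {
  counts <- tibble::as_tibble(counts)
  cells <- setdiff(names(counts), "gene")
  if (!all(cells %in% cell_annotation$cell)) {
    stop_bad_arg("every count column must be annotated in `cell_annotation`")
  }
  x <- as.matrix(counts[, cells, drop = FALSE])
  if (any(x < 0)) stop_bad_arg("counts must be non-negative")
  types <- cell_annotation$cell_type[match(cells, cell_annotation$cell)]
  keep_types <- names(which(table(types) >= min_cells))
  if (length(keep_types) == 0L) {
    stop_bad_arg(sprintf("no cell type has at least %d cells", min_cells))
  }
  frac <- vapply(keep_types, function(tp) {
    cols <- which(types == tp)
    rowMeans(x[, cols, drop = FALSE] > 0)
  }, numeric(nrow(counts)))
  n_cells <- vapply(keep_types, function(tp) sum(types == tp), integer(1))
  new_expr_matrix(
    dplyr::bind_cols(tibble::tibble(gene = counts$gene), tibble::as_tibble(frac)),
    n_cells
  )
}

#' Rank genes by a principal component of their cell-type profiles
#'
#' Standardizes the cell-type columns (z-score by default), fits a PCA over
#' all genes, and ranks every gene by its score on the chosen component
#' (the second component typically separates genes with coordinated
#' endothelial expression from the bulk). The component's sign is oriented
#' so the known gene set's mean score is positive, making "top of the
#' component" well defined; the rank percentile is descending (percentile
#' 0.01 = top 1%).
#'
#' @param m An `expr_matrix` with at least 3 cell types and 10 genes.
#' @param known_genes Character vector used to orient the component sign.
#' @param pc Which component to rank on (default 2).
#' @param scaling `"zscore"` (default) or `"none"`.
#' @return A `pc_ranking`: tibble with `gene`, `pc1`, `pc_score` (the chosen
#'   component), and `rank_percentile`; variance explained in
#'   `attr(, "var_explained")`.
#' @export
pc_ranking <- function(m, known_genes, pc = 2, scaling = c("zscore", "none")) {
  scaling <- match.arg(scaling)
  x <- expr_values(m)
  if (ncol(x) < 3 || nrow(x) < 10) {
    stop_bad_arg("need at least 3 cell types and 10 genes")
  }
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) stop_bad_arg("constant expression matrix")
  if (scaling == "zscore") {
    keep <- sds > 0
    x <- scale(x[, keep, drop = FALSE])
  }
  fit <- prcomp(x, center = scaling == "none", scale. = FALSE)
  scores <- fit$x
  if (pc > ncol(scores)) stop_bad_arg("requested component not available")
  s <- scores[, pc]
  known <- rownames(x) %in% known_genes
  if (any(known) && mean(s[known]) < 0) s <- -s
  out <- tibble::tibble(
    gene = rownames(x),
    pc1 = scores[, 1],
    pc_score = s,
    rank_percentile = rank(-s, ties.method = "average") / length(s)
  )
  attr(out, "var_explained") <- fit$sdev^2 / sum(fit$sdev^2)
  class(out) <- c("pc_ranking", class(out))
  out
}

#' Top-quantile enrichment of a gene set
#'
#' Tests whether a candidate gene set is over-represented in the top `q`
#' quantile of a gene ranking: observed count in the top quantile, expected
#' `|set| x q`, their ratio, and a one-sided binomial tail
#' `P(X >= observed | n = |set|, q)`.
#'
#' @param ranking A `pc_ranking` (or any tibble with `gene` and
#'   `rank_percentile`).
#' @param gene_set Character vector, a subset of the ranked genes.
#' @param q Top quantile (default 0.05).
#' @return One-row tibble: `n_set`, `observed`, `expected`, `enrichment`,
#'   `p_value`.
#' @export
#' @examples
#' # 7 of 12 known genes in the top 5%:
#' rk <- tibble::tibble(gene = sprintf("g%02d", 1:100),
#'                      rank_percentile = (1:100) / 100)
#' topq_enrichment(rk, c(sprintf("g%02d", 1:7), sprintf("g%02d", 60:64)))
topq_enrichment <- function(ranking, gene_set, q = 0.05) {
  if (length(gene_set) == 0L) stop_bad_arg("empty gene set")
  if (q <= 0 || q > 1) stop_bad_arg("`q` must be in (0, 1]")
  if (!all(gene_set %in% ranking$gene)) {
    stop_bad_arg("gene set must be a subset of the ranked universe")
  }
  inset <- ranking[ranking$gene %in% gene_set, , drop = FALSE]
  observed <- sum(inset$rank_percentile <= q)
  expected <- length(gene_set) * q
  tibble::tibble(
    n_set = length(gene_set),
    observed = observed,
    expected = expected,
    enrichment = observed / expected,
    p_value = pbinom(observed - 1, length(gene_set), q, lower.tail = FALSE)
  )
}
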