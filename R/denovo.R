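#' Built-in demonstration trinucleotide mutation-rate table
#'
#' A complete 192-row table of per-site, per-generation mutation
#' probabilities keyed by trinucleotide context (5' base, reference base,
#' 3' base) and alternate base. The table is synthetic: a uniform base rate
#' with a fold increase for CpG transitions (C>T with a 3' G, and the
#' reverse-strand equivalent G>A with a 5' C), which captures the dominant
#' feature of real context tables. Study-specific tables are supplied as TSV
#' via [read_rate_table()].
#'
#' @param base_rate Per-site per-generation rate for non-CpG changes.
#' @param cpg_boost Fold increase for CpG transitions.
#' @return Tibble with columns `context` (3 bases), `alt`, `mu`.
#' @export
#' @examples
#' demo_rate_table()
demo_rate_table <- function(base_rate = 1.2e-08, cpg_boost = 10) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(p5 = bases, ref = bases, p3 = bases, alt = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  cpg <- (grid$ref == "C" & grid$p3 == "G" & grid$alt == "T") |
    (grid$ref == "G" & grid$p5 == "C" & grid$alt == "A")
  tibble::tibble(
    context = paste0(grid$p5, grid$ref, grid$p3),
    alt = grid$alt,
    mu = base_rate * ifelse(cpg, cpg_boost, 1)
  ) %>% dplyr::arrange(.data$context, .data$alt)
}

check_rate_table <- function(rates) {
  rates <- tibble::as_tibble(rates)
  if (!all(c("context", "alt", "mu") %in% names(rates))) {
    stop_bad_arg("rate table needs columns context, alt, mu")
  }
  if (any(rates$mu < 0)) stop_bad_arg("rates must be non-negative")
  if (any(substr(rates$context, 2, 2) == rates$alt)) {
    stop_bad_arg("rate table contains ref == alt entries")
  }
  key <- paste(rates$context, rates$alt)
  full <- paste(demo_rate_table()$context, demo_rate_table()$alt)
  if (!all(full %in% key)) {
    stop_bad_arg("rate table must cover all 192 context/alt combinations")
  }
  rates
}

# cached codon -> amino acid map (one-letter, "*" for stop)
codon_aa_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bases <- c("A", "C", "G", "T")
      codons <- apply(expand.grid(bases, bases, bases), 1, paste0, collapse = "")
      cache <<- setNames(
        vapply(codons, function(cd) seqinr::translate(strsplit(cd, "")[[1]]), ""),
        codons
      )
    }
    cache
  }
})

class_rate_column <- function(class) {
  switch(class,
    SYN = "syn_rate", MIS = "mis_rate", NON = "non_rate",
    LGD = "lgd_rate", DMis = "dmis_rate", LGD_plus_DMis = "lgd_dmis_rate",
    stop_bad_arg(sprintf("unknown variant class '%s'", class))
  )
}

#' Per-gene mutation rates by consequence class
#'
#' Accrues the context-specific mutation probability of every possible
#' single-nucleotide substitution at every coding site of each gene to the
#' consequence class of that substitution (synonymous, missense, nonsense by
#' codon translation). The gene sequence must carry one flanking base on
#' each side so every coding site has a trinucleotide context. Derived
#' classes follow the field's conventions for likely gene-disrupting (LGD)
#' and deleterious missense (D-Mis) rates, neither of which is a pure
#' substitution class:
#'
#' * `lgd_rate = non_rate * lgd_factor` — frameshift indels and splice
#'   variants are modelled as a fixed multiple of the nonsense rate;
#' * `dmis_rate = mis_rate * dmis_fraction` — the fraction of missense
#'   changes expected to exceed the deleteriousness cutoff.
#'
#' A `mappable_fraction` column, when present, scales all of a gene's rates
#' (only uniquely mappable coding sequence contributes to expectations).
#'
#' @param genes Gene models ([simulate_gene_models()] or
#'   [read_gene_models()]).
#' @param rates Mutation-rate table (see [demo_rate_table()]).
#' @param dmis_fraction Fraction of the missense rate counted as D-Mis.
#' @param lgd_factor Multiple of the nonsense rate counted as LGD.
#' @return Tibble: `gene`, `syn_rate`, `mis_rate`, `non_rate`, `lgd_rate`,
#'   `dmis_rate`, `lgd_dmis_rate`, `total_rate`.
#' @export
gene_class_rates <- function(genes, rates, dmis_fraction = 0.2,
                             lgd_factor = 2) {
  rates <- check_rate_table(rates)
  aa <- codon_aa_map()
  mu_lookup <- setNames(rates$mu, paste0(rates$context, rates$alt))
  bases <- c("A", "C", "G", "T")
  per_gene <- purrr::map2(genes$sequence, genes$gene, function(seq, g) {
    chars <- strsplit(seq, "")[[1]]
    if (!all(chars %in% bases)) {
      stop_bad_arg(sprintf("ambiguous base in sequence of %s", g))
    }
    L <- length(chars) - 2L
    if (L < 3L || L %% 3L != 0L) {
      stop_bad_arg(sprintf("coding sequence of %s is not a whole number of codons", g))
    }
    cds <- chars[2:(L + 1L)]
    pos <- seq_len(L)
    codon_idx <- (pos - 1L) %/% 3L
    pos_in_codon <- (pos - 1L) %% 3L + 1L
    codons <- paste0(cds[codon_idx * 3L + 1L], cds[codon_idx * 3L + 2L],
                     cds[codon_idx * 3L + 3L])
    context <- paste0(chars[pos], chars[pos + 1L], chars[pos + 2L])
    ref_aa <- aa[codons]
    out <- c(SYN = 0, MIS = 0, NON = 0)
    for (alt in bases) {
      sel <- cds != alt
      if (!any(sel)) next
      mu <- unname(mu_lookup[paste0(context[sel], alt)])
      mutated <- codons[sel]
      substr(mutated, pos_in_codon[sel], pos_in_codon[sel]) <- alt
      alt_aa <- aa[mutated]
      cls <- ifelse(alt_aa == ref_aa[sel], "SYN",
                    ifelse(alt_aa == "*", "NON", "MIS"))
      agg <- tapply(mu, cls, sum)
      out[names(agg)] <- out[names(agg)] + agg
    }
    out
  })
  mat <- do.call(rbind, per_gene)
  mf <- if ("mappable_fraction" %in% names(genes)) genes$mappable_fraction else 1
  tibble::tibble(
    gene = genes$gene,
    syn_rate = unname(mat[, "SYN"]) * mf,
    mis_rate = unname(mat[, "MIS"]) * mf,
    non_rate = unname(mat[, "NON"]) * mf
  ) %>% dplyr::mutate(
    lgd_rate = .data$non_rate * lgd_factor,
    dmis_rate = .data$mis_rate * dmis_fraction,
    lgd_dmis_rate = .data$lgd_rate + .data$dmis_rate,
    total_rate = .data$syn_rate + .data$mis_rate + .data$non_rate
  )
}

#' Expected de novo variant count for a gene set
#'
#' `m0 = 2 x n_trios x` sum of the class rate over the (optionally
#' restricted) gene set: two transmitted haploid genomes per trio, each
#' mutating at the summed per-generation class rate.
#'
#' @param gene_rates Output of [gene_class_rates()].
#' @param class One of `"SYN"`, `"MIS"`, `"NON"`, `"LGD"`, `"DMis"`,
#'   `"LGD_plus_DMis"`.
#' @param n_trios Number of trios.
#' @param gene_set Optional character vector restricting the sum (e.g. genes
#'   highly expressed in developing lung/heart).
#' @param exclude Optional character vector of genes removed from the sum.
#' @return Expected count `m0` (double).
#' @export
expected_count <- function(gene_rates, class, n_trios, gene_set = NULL,
                           exclude = NULL) {
  check_count(n_trios, "n_trios", positive = FALSE)
  col <- class_rate_column(class)
  keep <- rep(TRUE, nrow(gene_rates))
  if (!is.null(gene_set)) keep <- keep & gene_rates$gene %in% gene_set
  if (!is.null(exclude)) keep <- keep & !(gene_rates$gene %in% exclude)
  2 * n_trios * sum(gene_rates[[col]][keep])
}

#' Exact Poisson test for an observed count against an expectation
#'
#' One-sided: `P(X >= m1)` under `Poisson(m0)`. Two-sided: the
#' total-probability convention — the sum of `Poisson(k; m0)` over every
#' `k` whose probability does not exceed that of the observed count (the
#' convention of standard exact-test implementations), capped at 1.
#'
#' @param m1 Observed count (non-negative integer).
#' @param m0 Expected count (> 0).
#' @param sided `"two_sided"` (default) or `"greater"`.
#' @return p-value in (0, 1\].
#' @export
#' @examples
#' exact_poisson_test(29, 11.85) # ~2.5e-5
exact_poisson_test <- function(m1, m0, sided = c("two_sided", "greater")) {
  sided <- match.arg(sided)
  check_count(m1, "m1", positive = FALSE)
  if (!is.numeric(m0) || m0 <= 0) stop_bad_arg("`m0` must be positive")
  if (sided == "greater") {
    return(ppois(m1 - 1, m0, lower.tail = FALSE))
  }
  d <- dpois(m1, m0) * (1 + 1e-07)
  upper <- ceiling(m0 + 30 * sqrt(m0) + 30)
  ks <- 0:upper
  dd <- dpois(ks, m0)
  # density beyond `upper` is monotonically below d; fold it into the sum
  min(1, sum(dd[dd <= d]) + ppois(upper, m0, lower.tail = FALSE))
}

# round half away from zero, then floor at 0
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarize a de novo burden comparison
#'
#' The burden arithmetic for an observed/expected de novo count pair:
#' enrichment `m1/m0`, two-sided exact Poisson p-value, the estimated number
#' of risk variants `round(m1 - m0)` (half away from zero, floored at 0),
#' and the attributable fraction (estimated risk variants per trio).
#'
#' @param m1 Observed count.
#' @param m0 Expected count.
#' @param n_trios Number of trios (for the attributable fraction; `NA` to
#'   skip).
#' @param class,gene_set_label Bookkeeping labels carried into the output.
#' @param sided Sidedness of the exact Poisson test.
#' @return One-row tibble: `class`, `gene_set`, `m1`, `m0`, `enrichment`,
#'   `p_value`, `est_risk_variants`, `attributable_fraction`.
#' @export
#' @examples
#' denovo_burden_summary(29, 11.85, n_trios = 124)
denovo_burden_summary <- function(m1, m0, n_trios = NA_integer_,
                                  class = NA_character_,
                                  gene_set_label = NA_character_,
                                  sided = "two_sided") {
  est <- max(0, round_half_away(m1 - m0))
  tibble::tibble(
    class = class, gene_set = gene_set_label, m1 = m1, m0 = m0,
    enrichment = m1 / m0,
    p_value = exact_poisson_test(m1, m0, sided),
    est_risk_variants = as.integer(est),
    attributable_fraction = est / n_trios
  )
}

#' De novo burden test over a gene set
#'
#' Counts observed de novo variants of a class within a gene set (minus any
#' excluded known risk genes), computes the expected count from the
#' background mutation model over the same gene set, and summarizes
#' enrichment and significance. By default excluded genes are *not* removed
#' from the expectation (the expectation describes the whole set before any
#' knowledge of where variants landed); set `exclude_from_expected = TRUE`
#' to remove them from both sides.
#'
#' @param observed Tibble of filtered, classified de novo variants with
#'   columns `gene` and `class` (`SYN`, `MIS`, `LGD`, `DMis`).
#' @param gene_rates Output of [gene_class_rates()].
#' @param class Class to test; `LGD_plus_DMis` counts observed `LGD` and
#'   `DMis` records, `MIS` counts `MIS` and `DMis`.
#' @param n_trios Number of trios.
#' @param gene_set Optional restriction (e.g. the highly expressed set).
#' @param exclude Genes excluded from the observed count.
#' @param exclude_from_expected Also remove `exclude` from `m0`.
#' @param gene_set_label Label carried into the output.
#' @return One-row tibble, see [denovo_burden_summary()].
#' @export
denovo_burden <- function(observed, gene_rates, class, n_trios,
                          gene_set = NULL, exclude = NULL,
                          exclude_from_expected = FALSE,
                          gene_set_label = if (is.null(gene_set)) "all_genes" else "gene_set") {
  col <- class_rate_column(class) # validates the class
  obs_classes <- switch(class,
    LGD_plus_DMis = c("LGD", "DMis"),
    MIS = c("MIS", "DMis"),
    class
  )
  obs <- observed[observed$class %in% obs_classes, , drop = FALSE]
  if (!is.null(gene_set)) obs <- obs[obs$gene %in% gene_set, , drop = FALSE]
  if (!is.null(exclude)) obs <- obs[!(obs$gene %in% exclude), , drop = FALSE]
  m1 <- nrow(obs)
  m0 <- expected_count(
    gene_rates, class, n_trios, gene_set = gene_set,
    exclude = if (exclude_from_expected) exclude else NULL
  )
  denovo_burden_summary(m1, m0, n_trios, class, gene_set_label)
}
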