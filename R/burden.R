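#' Case-enrichment burden statistic for a 2x2 carrier table
#'
#' Returns `-log10` of the one-sided (case-enrichment) tail probability of
#' observing at least `a` case carriers among `a + b` total carriers, given
#' `nA` cases and `nB` controls. The default is the exact hypergeometric
#' tail (the label-permutation distribution of the carrier count); a
#' one-sided binomial tail with success probability `nA / (nA + nB)` is
#' available as an alternative inner statistic.
#'
#' @param a,b Case and control carrier counts (vectorized).
#' @param nA,nB Numbers of cases and controls.
#' @param statistic `"hypergeometric"` (default) or `"binomial"`.
#' @return `-log10` tail probability; 0 when no carriers, larger = more
#'   case-enriched.
#' @export
#' @examples
#' burden_statistic(3, 0, 10, 10) # -log10(0.10526...)
burden_statistic <- function(a, b, nA, nB,
                             statistic = c("hypergeometric", "binomial")) {
  statistic <- match.arg(statistic)
  if (nA <= 0 || nB <= 0) stop_bad_arg("nA and nB must be positive")
  if (any(a > nA) || any(b > nB)) stop_bad_arg("carrier counts exceed sample sizes")
  p <- if (statistic == "hypergeometric") {
    phyper(a - 1, nA, nB, a + b, lower.tail = FALSE)
  } else {
    pbinom(a - 1, a + b, nA / (nA + nB), lower.tail = FALSE)
  }
  -log10(pmax(p, .Machine$double.xmin))
}

# Per-carrier qualification matrix over candidate thresholds.
# thresholds: descending unique REVEL scores; for the LGD-plus-D-Mis
# configuration an Inf sentinel threshold (LGD carriers only) is prepended.
vt_qual_matrix <- function(has_lgd, revel, config) {
  ts <- sort(unique(revel[!is.na(revel)]), decreasing = TRUE)
  if (config == "LGD_plus_DMis") ts <- c(Inf, ts)
  if (length(ts) == 0L) return(NULL)
  rv <- ifelse(is.na(revel), -Inf, revel)
  qual <- outer(rv, ts, ">=")
  if (config == "LGD_plus_DMis") qual <- qual | has_lgd
  storage.mode(qual) <- "double"
  list(thresholds = ts, qual = qual)
}

vt_perm_p <- function(qual, tot, obs_max, nA, nB, B, statistic,
                      early_stop = 50L, chunk = 200L) {
  m <- nrow(qual)
  exceed <- 0L
  done <- 0L
  while (done < B && exceed < early_stop) {
    nb <- min(chunk, B - done)
    # permuted labels: k case labels among the m carriers is hypergeometric;
    # which carriers receive them is a uniform subset
    k <- rhyper(nb, nA, nB, m)
    P <- matrix(0, nb, m)
    for (j in seq_len(nb)) {
      if (k[j] > 0L) P[j, sample.int(m, k[j])] <- 1
    }
    A <- P %*% qual
    stat <- burden_statistic(as.vector(A),
                             rep(tot, each = nb) - as.vector(A),
                             nA, nB, statistic)
    mx <- apply(matrix(stat, nrow = nb), 1, max)
    exceed <- exceed + sum(mx >= obs_max - 1e-12)
    done <- done + nb
  }
  (1 + exceed) / (done + 1)
}

#' Variable-threshold burden test for one gene
#'
#' Searches the unique REVEL scores of a gene's missense variants for the
#' cutoff that maximizes the case-control burden statistic (for the combined
#' configuration, an LGD-only threshold is also a candidate), then computes
#' a permutation p-value by shuffling case/control labels and *re-maximizing
#' over thresholds inside every permutation*, so the threshold selection is
#' part of the null and the p-value is honest.
#'
#' The permutation p-value carries the add-one correction
#' `(1 + #exceedances) / (B + 1)` and stops early once 50 exceedances have
#' accumulated (the p-value estimate is then already far from any reporting
#' threshold), so the attainable minimum is `1 / (B + 1)`.
#'
#' @param carriers,variants,manifest Cohort tables (see
#'   [simulate_case_control_cohort()]).
#' @param gene Gene id to test.
#' @param config `"LGD_plus_DMis"` (LGD variants plus missense above the
#'   cutoff) or `"DMis_only"`.
#' @param B Number of permutations (>= 1).
#' @param seed Random seed for the permutation stream.
#' @param statistic Inner statistic, see [burden_statistic()].
#' @param early_stop Number of exceedances after which the permutation loop
#'   stops early (`Inf` disables adaptive stopping).
#' @return One-row tibble of class `vt_result`: `gene`, `config`,
#'   `optimal_revel_cutoff`, `case_carriers`, `control_carriers` (at the
#'   optimal cutoff), `n_cases`, `n_controls`, `max_statistic`, `perm_p`.
#' @export
variable_threshold_test <- function(carriers, variants, manifest, gene,
                                    config = c("LGD_plus_DMis", "DMis_only"),
                                    B = 10000L, seed = 1L,
                                    statistic = c("hypergeometric", "binomial"),
                                    early_stop = 50L) {
  config <- match.arg(config)
  statistic <- match.arg(statistic)
  check_count(B, "B")
  nA <- sum(manifest$status == "case")
  nB <- sum(manifest$status == "control")
  gd <- vt_gene_data(carriers, variants, manifest, gene)
  res <- with_seed(seed, vt_test_core(gd, nA, nB, config, B, statistic,
                                      early_stop = early_stop))
  out <- tibble::tibble(
    gene = gene, config = config,
    optimal_revel_cutoff = res$cutoff,
    case_carriers = res$a, control_carriers = res$b,
    n_cases = nA, n_controls = nB,
    max_statistic = res$stat, perm_p = res$p
  )
  class(out) <- c("vt_result", class(out))
  out
}

# collapse a gene's qualifying variants to per-carrier (has_lgd, max_revel),
# in sample order, with case status
vt_gene_data <- function(carriers, variants, manifest, gene) {
  v <- variants[variants$gene == gene, , drop = FALSE]
  splice <- dplyr::coalesce(v$splice_score, 0)
  v$is_lgd <- v$consequence %in% lgd_consequences |
    (v$consequence == "synonymous" & splice >= threshold_default("min_splice_score"))
  v$rv <- ifelse(v$consequence == "missense", v$revel, NA_real_)
  cc <- carriers[carriers$gene == gene, , drop = FALSE]
  cc <- dplyr::inner_join(cc, v[, c("variant_id", "is_lgd", "rv")],
                          by = "variant_id")
  per <- cc %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      has_lgd = any(.data$is_lgd),
      max_revel = suppressWarnings(max(.data$rv, na.rm = TRUE)),
      .groups = "drop"
    ) %>%
    dplyr::mutate(max_revel = ifelse(is.finite(.data$max_revel),
                                     .data$max_revel, NA_real_)) %>%
    dplyr::inner_join(manifest[, c("sample_id", "status")], by = "sample_id")
  per
}

vt_test_core <- function(per, nA, nB, config, B, statistic, early_stop = 50L) {
  empty <- list(cutoff = NA_real_, a = 0L, b = 0L, stat = 0, p = 1)
  if (nrow(per) == 0L) return(empty)
  qm <- vt_qual_matrix(per$has_lgd, per$max_revel, config)
  if (is.null(qm)) {
    if (config != "LGD_plus_DMis" || !any(per$has_lgd)) return(empty)
    qm <- list(thresholds = Inf,
               qual = matrix(as.double(per$has_lgd), ncol = 1))
  }
  is_case <- per$status == "case"
  tot <- colSums(qm$qual)
  a_obs <- as.vector(crossprod(qm$qual, as.double(is_case)))
  stats_obs <- burden_statistic(a_obs, tot - a_obs, nA, nB, statistic)
  best <- which.max(stats_obs)
  p <- vt_perm_p(qm$qual, tot, stats_obs[best], nA, nB, B, statistic,
                 early_stop = early_stop)
  list(
    cutoff = qm$thresholds[best],
    a = as.integer(a_obs[best]),
    b = as.integer(tot[best] - a_obs[best]),
    stat = stats_obs[best], p = p
  )
}

#' Genome-wide variable-threshold burden scan
#'
#' Runs the variable-threshold test for every gene with at least one
#' qualifying variant, under both configurations (LGD plus D-Mis, and D-Mis
#' alone), adjusts all `2 x G` permutation p-values jointly by
#' Benjamini-Hochberg, and reports genes at FDR < `fdr` alongside the
#' genomic-control lambda and the Bonferroni threshold.
#'
#' @inheritParams variable_threshold_test
#' @param cohort List with `manifest`, `variants`, `carriers` (as produced by
#'   [simulate_case_control_cohort()] or assembled from files).
#' @param configs Which test configurations to run.
#' @param fdr FDR reporting threshold (default 0.1).
#' @param alpha Family-wise alpha for the Bonferroni threshold.
#' @return A `vt_scan` object: list with `results` (tibble: gene, config,
#'   optimal_revel_cutoff, case_carriers, control_carriers, max_statistic,
#'   perm_p, q_value, significant), `lambda_gc`, `bonferroni_threshold`,
#'   `n_tests`, `n_cases`, `n_controls`.
#' @export
genomewide_scan <- function(cohort, B = 1000L, seed = 1L,
                            configs = c("LGD_plus_DMis", "DMis_only"),
                            statistic = c("hypergeometric", "binomial"),
                            fdr = threshold_default("fdr_threshold"),
                            alpha = threshold_default("alpha")) {
  statistic <- match.arg(statistic)
  manifest <- cohort$manifest
  nA <- sum(manifest$status == "case")
  nB <- sum(manifest$status == "control")
  genes <- sort(unique(cohort$variants$gene))
  gene_data <- purrr::map(
    genes, ~ vt_gene_data(cohort$carriers, cohort$variants, manifest, .x)
  )
  rows <- purrr::imap(gene_data, function(per, gi) {
    purrr::map(configs, function(cfg) {
      res <- with_seed(
        child_seed(seed, 1000L + gi),
        vt_test_core(per, nA, nB, cfg, B, statistic)
      )
      tibble::tibble(
        gene = genes[gi], config = cfg,
        optimal_revel_cutoff = res$cutoff,
        case_carriers = res$a, control_carriers = res$b,
        max_statistic = res$stat, perm_p = res$p
      )
    })
  })
  results <- dplyr::bind_rows(purrr::flatten(rows))
  n_tests <- nrow(results)
  if (n_tests > 0) {
    results$q_value <- bh_fdr(results$perm_p)
    results$significant <- results$q_value < fdr
  } else {
    results$q_value <- numeric(0)
    results$significant <- logical(0)
  }
  lambda <- if (n_tests >= 10 && any(results$perm_p < 1)) {
    genomic_control_lambda(results$perm_p)
  } else {
    NA_real_
  }
  structure(
    list(
      results = results, lambda_gc = lambda,
      bonferroni_threshold = if (n_tests > 0) bonferroni_threshold(alpha, n_tests) else NA_real_,
      n_tests = n_tests, n_cases = nA, n_controls = nB
    ),
    class = "vt_scan"
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a p-value vector.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(pvals) {
  check_prob(pvals, "pvals")
  stats::p.adjust(pvals, method = "BH")
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests; a scan testing every protein-coding gene
#'   under two configurations uses twice the number of genes (e.g.
#'   `2 x ~19,000`, conventionally rounded to 40,000, giving 1.25e-6).
#' @return `alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 40000)
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop_bad_arg("`alpha` must be in (0, 1)")
  check_count(n_tests, "n_tests")
  alpha / n_tests
}

#' Genomic-control lambda
#'
#' Ratio of the median chi-square(1 df) quantile of the observed p-values to
#' the null median 0.4549; 1 indicates no inflation of the test statistics.
#'
#' @param pvals Numeric vector of at least 10 p-values in (0, 1\].
#' @return Lambda (double).
#' @export
genomic_control_lambda <- function(pvals) {
  check_prob(pvals, "pvals")
  if (length(pvals) < 10) stop_bad_arg("need at least 10 p-values")
  if (all(pvals >= 1)) stop_bad_arg("degenerate p-values (all equal to 1)")
  obs <- qchisq(pvals, df = 1, lower.tail = FALSE)
  median(obs) / qchisq(0.5, df = 1)
}

#' Synonymous-rate calibration check
#'
#' Compares per-sample rare synonymous variant rates between cases and
#' controls: the rate ratio (case mean over control mean) and a two-sided
#' exact Poisson rate test of equality. Synonymous variants are presumed
#' neutral, so a ratio near 1 indicates the filtering has not introduced a
#' case-control batch artifact.
#'
#' @param case_counts,control_counts Per-sample synonymous variant counts,
#'   or single totals together with `n_cases` / `n_controls`.
#' @param n_cases,n_controls Sample counts (default: lengths of the vectors).
#' @return Tibble with `rate_ratio` and `p_value`.
#' @export
synonymous_calibration <- function(case_counts, control_counts,
                                   n_cases = length(case_counts),
                                   n_controls = length(control_counts)) {
  tA <- sum(case_counts)
  tB <- sum(control_counts)
  if (tA < 0 || tB < 0) stop_bad_arg("counts must be non-negative")
  ratio <- (tA / n_cases) / (tB / n_controls)
  # conditional binomial formulation of the two-sample Poisson rate test
  p <- exact_binom_two_sided(tA, tA + tB, n_cases / (n_cases + n_controls))
  tibble::tibble(rate_ratio = ratio, p_value = p)
}

# two-sided exact binomial by the total-probability convention
exact_binom_two_sided <- function(x, n, p) {
  d <- stats::dbinom(x, n, p) * (1 + 1e-07)
  sum(stats::dbinom(0:n, n, p)[stats::dbinom(0:n, n, p) <= d])
}

#' Power of a one-sided two-proportion carrier comparison
#'
#' Power to detect case enrichment of carriers at one-sided significance
#' level `alpha`, for `nA` cases versus `nB` controls, a control carrier
#' frequency `freq`, and a case:control relative risk `rr` (case carrier
#' frequency `freq * rr`). The test whose power is computed is the standard
#' pooled-variance two-proportion z-test.
#'
#' The default `"exact"` method enumerates the binomial distribution of
#' both carrier counts and sums the probability of the z-test's rejection
#' region, which stays accurate at the small carrier counts typical of rare
#' variants; `"normal"` is the closed-form normal approximation, which can
#' be off by a few percentage points in that regime. At `rr = 1` the
#' nominal size `alpha` is returned.
#'
#' @param nA,nB Case and control sample sizes.
#' @param freq Control carrier frequency (fraction).
#' @param rr Relative risk (>= 1); `freq * rr` must be at most 1.
#' @param alpha One-sided significance level.
#' @param method `"exact"` (binomial enumeration) or `"normal"`.
#' @return Power (probability in \[0, 1\]).
#' @export
#' @examples
#' burden_power(1647, 18819, 0.001, 10, alpha = 1.25e-6)
burden_power <- function(nA, nB, freq, rr, alpha = 0.05,
                         method = c("exact", "normal")) {
  method <- match.arg(method)
  check_prob(freq, "freq")
  if (freq * rr > 1) stop_bad_arg("freq x rr exceeds 1")
  if (rr == 1) return(alpha)
  p1 <- freq * rr
  p0 <- freq
  z_crit <- qnorm(1 - alpha)
  if (method == "normal") {
    pbar <- (nA * p1 + nB * p0) / (nA + nB)
    se0 <- sqrt(pbar * (1 - pbar) * (1 / nA + 1 / nB))
    se1 <- sqrt(p1 * (1 - p1) / nA + p0 * (1 - p0) / nB)
    return(pnorm(((p1 - p0) - z_crit * se0) / se1))
  }
  amax <- stats::qbinom(1 - 1e-12, nA, p1)
  bmax <- stats::qbinom(1 - 1e-12, nB, p0)
  a <- 0:amax
  b <- 0:bmax
  ph1 <- a / nA
  ph0 <- b / nB
  pp <- outer(a, b, "+") / (nA + nB)
  z <- outer(ph1, ph0, "-") / sqrt(pp * (1 - pp) * (1 / nA + 1 / nB))
  reject <- !is.na(z) & z > z_crit
  sum(outer(stats::dbinom(a, nA, p1), stats::dbinom(b, nB, p0)) * reject)
}
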