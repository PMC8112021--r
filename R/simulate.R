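#' Build a simulation configuration
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' The defaults describe a reduced-scale analogue of a large international
#' case-control study of idiopathic pulmonary arterial hypertension (order
#' 10^3 cases against 10^4 controls, with ~100 child-parent trios), sized so
#' that a full pipeline run completes in seconds.
#'
#' @param n_cases,n_controls Number of case and control samples.
#' @param n_genes Number of genes simulated for the case-control cohort.
#' @param baseline_carrier_freq Probability that a sample carries a qualifying
#'   rare variant in a given non-risk gene. Carrier frequencies are fractions,
#'   never percentages.
#' @param risk_genes Tibble describing injected risk genes, with columns
#'   `gene` (id within `gene_0001 ... gene_<n_genes>` or any label), `control_freq`
#'   (carrier frequency in controls), `fold` (case:control carrier-frequency
#'   ratio, >= 1), and `score_shift` (probability in \[0,1\] that a risk-gene
#'   case variant is drawn from the high-deleteriousness score component).
#'   `NULL` means a fully null cohort.
#' @param n_trios Number of child-parent trios for de novo simulation.
#' @param expression A list with elements `n_cell_types`, `cells_per_type`,
#'   `n_genes`, `enriched_genes` (count or character vector), `enriched_types`
#'   (count or character vector of cell types), and `enrichment` (fold
#'   increase of the expression propensity of enriched genes in enriched
#'   cell types).
#' @param seed Root random seed. Component generators derive child seeds at
#'   fixed offsets, so identical configurations reproduce outputs exactly.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 100, n_controls = 500, n_genes = 50, seed = 1)
sim_config <- function(n_cases = 500,
                       n_controls = 5000,
                       n_genes = 1000,
                       baseline_carrier_freq = 0.002,
                       risk_genes = NULL,
                       n_trios = 124,
                       expression = list(
                         n_cell_types = 14, cells_per_type = 200,
                         n_genes = 1000, enriched_genes = 12,
                         enriched_types = 3, enrichment = 5
                       ),
                       seed = 1L) {
  check_count(n_cases, "n_cases")
  check_count(n_controls, "n_controls")
  check_count(n_genes, "n_genes")
  check_count(n_trios, "n_trios", positive = FALSE)
  check_prob(baseline_carrier_freq, "baseline_carrier_freq")
  if (!is.null(risk_genes)) {
    risk_genes <- tibble::as_tibble(risk_genes)
    need <- c("gene", "control_freq", "fold", "score_shift")
    if (!all(need %in% names(risk_genes))) {
      stop_bad_arg("`risk_genes` needs columns gene, control_freq, fold, score_shift")
    }
    check_prob(risk_genes$control_freq, "risk_genes$control_freq")
    check_prob(risk_genes$score_shift, "risk_genes$score_shift")
    if (any(risk_genes$fold < 1)) stop_bad_arg("`risk_genes$fold` must be >= 1")
    if (any(risk_genes$control_freq * risk_genes$fold > 1)) {
      stop_bad_arg("risk gene carrier frequency x fold exceeds 1")
    }
  }
  structure(
    list(
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      n_genes = as.integer(n_genes),
      baseline_carrier_freq = baseline_carrier_freq,
      risk_genes = risk_genes, n_trios = as.integer(n_trios),
      expression = expression, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# deleteriousness-score mixture: a benign bulk and a damaging tail, so a
# gene-specific optimal threshold exists for the variable-threshold search
r_revel_null <- function(n) {
  comp <- runif(n) < 0.3
  ifelse(comp, rbeta(n, 6, 3), rbeta(n, 2, 6))
}

r_revel_shifted <- function(n, shift) {
  hot <- runif(n) < shift
  ifelse(hot, rbeta(n, 12, 2), r_revel_null(n))
}

#' Simulate a rare-variant case-control cohort
#'
#' Generates a sample manifest, a per-site variant annotation table, and a
#' sample-by-variant carrier table with known ground truth. Every non-risk
#' gene has the same expected carrier frequency in cases and controls; each
#' injected risk gene multiplies its control carrier frequency by its `fold`
#' in cases, with case variants drawn from a right-shifted deleteriousness
#' score distribution so that threshold optimisation has signal to find.
#'
#' Carriers are collapsed: a sample carries at most one qualifying variant
#' per gene. Variant QC fields (allele balance, coverage fraction,
#' mappability, caller consensus) are drawn in the passing range so the
#' cohort survives [apply_inclusion_filters()] unchanged; cohort allele
#' frequencies are computed from realized carrier counts, so per-variant
#' `af_cohort` always equals carriers / (2 x n samples).
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `manifest` (sample_id, status, subclass, sex,
#'   age_onset, mpap, mpcwp, ancestry), `variants` (annotation columns of a
#'   variant record), and `carriers` (sample_id, gene, variant_id), plus
#'   `truth` (per-gene simulated carrier frequencies).
#' @export
#' @examples
#' sim <- simulate_case_control_cohort(
#'   sim_config(n_cases = 50, n_controls = 200, n_genes = 20, seed = 7)
#' )
#' dplyr::count(sim$carriers, gene)
simulate_case_control_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 101L), {
    nA <- config$n_cases
    nB <- config$n_controls
    genes <- sprintf("gene_%04d", seq_len(config$n_genes))

    freq_ctrl <- rep(config$baseline_carrier_freq, config$n_genes)
    fold <- rep(1, config$n_genes)
    shift <- rep(0, config$n_genes)
    names(freq_ctrl) <- names(fold) <- names(shift) <- genes
    if (!is.null(config$risk_genes)) {
      rg <- config$risk_genes
      missing <- setdiff(rg$gene, genes)
      if (length(missing)) {
        # risk genes may extend the universe with their own labels
        genes <- c(genes, missing)
        freq_ctrl <- c(freq_ctrl, setNames(rep(0, length(missing)), missing))
        fold <- c(fold, setNames(rep(1, length(missing)), missing))
        shift <- c(shift, setNames(rep(0, length(missing)), missing))
      }
      freq_ctrl[rg$gene] <- rg$control_freq
      fold[rg$gene] <- rg$fold
      shift[rg$gene] <- rg$score_shift
    }
    freq_case <- freq_ctrl * fold
    check_prob(freq_case, "case carrier frequency (freq x fold)")

    manifest <- tibble::tibble(
      sample_id = c(sprintf("case_%05d", seq_len(nA)),
                    sprintf("ctrl_%05d", seq_len(nB))),
      status = rep(c("case", "control"), c(nA, nB)),
      subclass = c(
        sample(c("IPAH", "APAH", "FPAH", "other"), nA, TRUE,
               prob = c(0.55, 0.35, 0.06, 0.04)),
        rep(NA_character_, nB)
      ),
      sex = sample(c("F", "M"), nA + nB, TRUE, prob = c(0.75, 0.25)),
      ancestry = "EUR",
      age_onset = round(pmax(1, rnorm(nA + nB, 46, 20))),
      mpap = round(pmax(21, rnorm(nA + nB, 51, 14))),
      mpcwp = round(pmax(2, rnorm(nA + nB, 10, 4)))
    )
    manifest$age_onset[manifest$status == "control"] <- NA_real_
    manifest$mpap[manifest$status == "control"] <- NA_real_
    manifest$mpcwp[manifest$status == "control"] <- NA_real_

    case_ids <- manifest$sample_id[manifest$status == "case"]
    ctrl_ids <- manifest$sample_id[manifest$status == "control"]

    per_gene <- purrr::map(seq_along(genes), function(gi) {
      g <- genes[gi]
      k_case <- rbinom(1L, nA, freq_case[g])
      k_ctrl <- rbinom(1L, nB, freq_ctrl[g])
      if (k_case + k_ctrl == 0L) return(NULL)
      carriers <- c(sample(case_ids, k_case), sample(ctrl_ids, k_ctrl))
      is_case <- rep(c(TRUE, FALSE), c(k_case, k_ctrl))
      n <- length(carriers)
      # ~15% LGD-type, remainder missense, matching rare deleterious spectra
      is_lgd <- runif(n) < 0.15
      revel <- ifelse(is_case, r_revel_shifted(n, shift[g]), r_revel_null(n))
      revel[is_lgd] <- NA_real_
      # mild recurrence: carriers share sites drawn from a reduced site pool
      site <- sample(max(1L, ceiling(0.85 * n)), n, replace = TRUE)
      tibble::tibble(
        gene = g, sample_id = carriers, site = site,
        consequence = ifelse(
          is_lgd,
          sample(c("stop_gain", "frameshift", "canonical_splice"), n, TRUE),
          "missense"
        ),
        revel = revel, gene_index = gi
      )
    })
    long <- dplyr::bind_rows(per_gene)

    if (nrow(long) == 0L) {
      variants <- tibble::tibble(
        variant_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(), gene = character(),
        consequence = character(), revel = double(), splice_score = double(),
        af_gnomad = double(), af_cohort = double(), allele_balance = double(),
        frac_samples_dp10 = double(), mappability = double(),
        caller_pass_fraction = double(), variant_type = character()
      )
      carriers <- tibble::tibble(sample_id = character(), gene = character(),
                                 variant_id = character())
    } else {
      site_tbl <- long %>%
        dplyr::group_by(.data$gene, .data$site) %>%
        dplyr::summarise(
          n_carriers = dplyr::n(),
          consequence = dplyr::first(.data$consequence),
          revel = dplyr::first(.data$revel),
          gene_index = dplyr::first(.data$gene_index),
          .groups = "drop"
        ) %>%
        dplyr::mutate(
          variant_id = sprintf("var_%06d", dplyr::row_number()),
          chrom = "chrS",
          pos = .data$gene_index * 100000L + .data$site * 10L,
          ref = sample(c("A", "C", "G", "T"), dplyr::n(), TRUE)
        )
      n_site <- nrow(site_tbl)
      alt_pool <- c("A", "C", "G", "T")
      variants <- site_tbl %>%
        dplyr::mutate(
          alt = purrr::map_chr(.data$ref, ~ sample(setdiff(alt_pool, .x), 1L)),
          splice_score = ifelse(.data$consequence == "synonymous",
                                runif(n_site, 0, 0.4), NA_real_),
          af_gnomad = runif(n_site, 0, 0.5) * 1e-04 * (runif(n_site) < 0.5),
          af_cohort = .data$n_carriers / (2 * (nA + nB)),
          allele_balance = runif(n_site, 0.3, 0.6),
          frac_samples_dp10 = runif(n_site, 0.92, 1),
          mappability = 1,
          caller_pass_fraction = runif(n_site, 0.6, 1),
          variant_type = ifelse(.data$consequence == "frameshift", "indel", "SNV")
        ) %>%
        dplyr::select(
          "variant_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
          "revel", "splice_score", "af_gnomad", "af_cohort", "allele_balance",
          "frac_samples_dp10", "mappability", "caller_pass_fraction",
          "variant_type"
        )
      carriers <- long %>%
        dplyr::left_join(
          site_tbl %>% dplyr::select("gene", "site", "variant_id"),
          by = c("gene", "site")
        ) %>%
        dplyr::select("sample_id", "gene", "variant_id")
    }

    list(
      manifest = manifest,
      variants = variants,
      carriers = carriers,
      truth = tibble::tibble(
        gene = genes, control_freq = unname(freq_ctrl),
        fold = unname(fold), score_shift = unname(shift)
      )
    )
  })
}

#' Simulate gene models with coding sequence context
#'
#' Builds synthetic gene models: a coding sequence (an open reading frame
#' with no internal stop codon) with one flanking base on each side for
#' trinucleotide context, non-overlapping sorted coding intervals in 0-based
#' half-open coordinates, a strand, and a high-lung/heart-expression flag
#' used for gene-set restriction in de novo burden testing.
#'
#' @param n_genes Number of genes.
#' @param n_codons_range Integer range from which each gene's codon count is
#'   drawn uniformly.
#' @param p_highly_expressed Probability a gene is flagged highly expressed
#'   in developing lung/heart.
#' @param seed Random seed.
#' @return A tibble with columns `gene`, `chrom`, `strand`, `highly_expressed`,
#'   `mappable_fraction`, `sequence` (flank + CDS + flank), and `intervals`
#'   (list-column of tibbles with `start`, `end`).
#' @export
simulate_gene_models <- function(n_genes = 50, n_codons_range = c(100L, 400L),
                                 p_highly_expressed = 0.3, seed = 1L) {
  check_count(n_genes, "n_genes")
  with_seed(child_seed(seed, 202L), {
    bases <- c("A", "C", "G", "T")
    codons <- apply(expand.grid(bases, bases, bases), 1, paste0, collapse = "")
    stops <- c("TAA", "TAG", "TGA")
    sense <- setdiff(codons, stops)
    purrr::map_dfr(seq_len(n_genes), function(i) {
      n_codons <- sample(seq(n_codons_range[1], n_codons_range[2]), 1L)
      cds <- paste0(c("ATG", sample(sense, n_codons - 1L, TRUE)), collapse = "")
      seq <- paste0(sample(bases, 1L), cds, sample(bases, 1L))
      len <- nchar(cds)
      n_exons <- sample(1:3, 1L)
      cuts <- sort(sample(seq_len(len - 1L), n_exons - 1L))
      widths <- diff(c(0L, cuts, len))
      starts <- cumsum(c(10000L * i, widths[-n_exons] + 500L))
      tibble::tibble(
        gene = sprintf("gene_%04d", i), chrom = "chrS",
        strand = sample(c("+", "-"), 1L),
        highly_expressed = runif(1) < p_highly_expressed,
        mappable_fraction = 1,
        sequence = seq,
        intervals = list(tibble::tibble(start = starts, end = starts + widths))
      )
    })
  })
}

# corrupt one randomly chosen de novo filter field per artifact record
denovo_filter_violations <- function() {
  list(
    proband_alt_reads = function(e) { e$proband_alt_reads <- 4L; e },
    proband_alt_fraction = function(e) { e$proband_alt_fraction <- 0.1; e },
    proband_gq = function(e) { e$proband_gq <- 40; e },
    parent_ref_reads = function(e) { e$parent1_ref_reads <- 5L; e },
    parent_alt_fraction = function(e) { e$parent2_alt_fraction <- 0.08; e },
    parent_gq = function(e) { e$parent1_gq <- 20; e },
    vqsr = function(e) { e$vqsr_tranche <- 99.9; e },
    fisher_strand = function(e) { e$fisher_strand <- 30; e },
    qual_by_depth = function(e) { e$qual_by_depth <- 1; e },
    population_af = function(e) { e$population_af <- 5e-04; e }
  )
}

#' Simulate trio de novo variants with read-level evidence
#'
#' Draws per-class de novo variant counts from Poisson distributions with
#' means given by the trinucleotide-context background model
#' (`2 x n_trios x` summed class rate over the gene set), assigns variants to
#' genes proportionally to their class rates, and emits one read-evidence
#' record per candidate. A configurable fraction of records is corrupted to
#' violate exactly one de novo filter rule each, for exercising the filter
#' cascade; the returned `true_variants` are the uncorrupted records.
#'
#' @param config A [sim_config()]; supplies `n_trios` and the seed.
#' @param genes Gene models from [simulate_gene_models()].
#' @param rates A mutation-rate table from [demo_rate_table()] or
#'   [read_rate_table()].
#' @param classes Variant classes to simulate.
#' @param artifact_fraction Fraction of emitted evidence records corrupted to
#'   violate exactly one filter.
#' @param dmis_fraction,lgd_factor Passed to [gene_class_rates()] /
#'   [expected_count()].
#' @return List with tibbles `true_variants` and `evidence`.
#' @export
simulate_trios <- function(config, genes, rates,
                           classes = c("SYN", "MIS", "LGD"),
                           artifact_fraction = 0,
                           dmis_fraction = 0.2, lgd_factor = 2) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(genes) == 0L) stop_bad_arg("empty gene list")
  check_prob(artifact_fraction, "artifact_fraction")
  gene_rates <- gene_class_rates(genes, rates,
                                 dmis_fraction = dmis_fraction,
                                 lgd_factor = lgd_factor)
  with_seed(child_seed(config$seed, 303L), {
    recs <- purrr::map_dfr(classes, function(cl) {
      mu_g <- gene_rates[[class_rate_column(cl)]] * genes$mappable_fraction
      m0 <- 2 * config$n_trios * sum(mu_g)
      n <- rpois(1L, m0)
      if (n == 0L) return(NULL)
      gi <- sample.int(nrow(genes), n, replace = TRUE,
                       prob = if (sum(mu_g) > 0) mu_g else NULL)
      tibble::tibble(
        trio_id = sprintf("trio_%03d", sample.int(config$n_trios, n, TRUE)),
        gene = genes$gene[gi], class = cl,
        variant_type = ifelse(cl == "LGD" & runif(n) < 0.5, "indel", "SNV")
      )
    })
    if (nrow(recs) == 0L) {
      recs <- tibble::tibble(trio_id = character(), gene = character(),
                             class = character(), variant_type = character())
    }
    n <- nrow(recs)
    ev <- recs %>% dplyr::mutate(
      variant_id = sprintf("dnv_%05d", seq_len(n)),
      proband_alt_reads = 5L + rpois(n, 12),
      proband_alt_fraction = runif(n, 0.35, 0.6),
      proband_gq = 99,
      parent1_ref_reads = 10L + rpois(n, 20),
      parent1_alt_fraction = runif(n, 0, 0.02),
      parent1_gq = 99,
      parent2_ref_reads = 10L + rpois(n, 20),
      parent2_alt_fraction = runif(n, 0, 0.02),
      parent2_gq = 99,
      vqsr_tranche = runif(n, 90, 98.9),
      fisher_strand = runif(n, 0, 10),
      qual_by_depth = runif(n, 3, 30),
      population_af = 0,
      artifact = runif(n) < artifact_fraction
    )
    viol <- denovo_filter_violations()
    for (i in which(ev$artifact)) {
      f <- viol[[sample.int(length(viol), 1L)]]
      row <- f(as.list(ev[i, ]))
      ev[i, names(row)] <- tibble::as_tibble(row)
    }
    list(
      true_variants = ev %>% dplyr::filter(!.data$artifact) %>%
        dplyr::select("variant_id", "trio_id", "gene", "class", "variant_type"),
      evidence = ev
    )
  })
}

#' Simulate a fraction-of-expressing-cells matrix
#'
#' Generates a genes x cell-types expression summary in which each entry is
#' the realized fraction of cells of that type with nonzero counts, from
#' binomial sampling around a latent per-gene, per-type propensity. Genes in
#' the enriched set have their propensity multiplied by the enrichment factor
#' in the designated cell types (capped below 1), emulating a risk-gene set
#' that is highly expressed in, for example, endothelial cell types.
#'
#' @param config A [sim_config()]; its `expression` element supplies the
#'   dimensions, the enriched set, and the enrichment factor.
#' @return An `expr_matrix`: a tibble with a `gene` column and one column per
#'   cell type, carrying per-type cell counts in `attr(, "cell_counts")`, plus
#'   an `enriched_genes` attribute with the ground-truth set.
#' @export
simulate_expression_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$expression
  if (ex$cells_per_type < 1) stop_bad_arg("cells-per-type must be >= 1")
  with_seed(child_seed(config$seed, 404L), {
    n_types <- ex$n_cell_types
    types <- sprintf("type_%02d", seq_len(n_types))
    enr_types <- if (is.character(ex$enriched_types)) ex$enriched_types
                 else types[seq_len(ex$enriched_types)]
    n_genes <- ex$n_genes
    genes <- sprintf("xgene_%04d", seq_len(n_genes))
    enr_genes <- if (is.character(ex$enriched_genes)) ex$enriched_genes
                 else genes[seq_len(ex$enriched_genes)]
    if (!all(enr_genes %in% genes)) {
      stop_bad_arg("enriched gene set must be a subset of the gene universe")
    }
    base <- rbeta(n_genes, 2, 10)          # per-gene expression propensity
    p <- matrix(rep(base, n_types), nrow = n_genes) *
      matrix(rep(runif(n_types, 0.6, 1.4), each = n_genes), nrow = n_genes)
    enr <- genes %in% enr_genes
    p[enr, types %in% enr_types] <- p[enr, types %in% enr_types] * ex$enrichment
    p <- pmin(p, 0.98)
    frac <- matrix(
      rbinom(length(p), ex$cells_per_type, p) / ex$cells_per_type,
      nrow = n_genes, dimnames = list(NULL, types)
    )
    out <- dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(frac))
    new_expr_matrix(out, setNames(rep(ex$cells_per_type, n_types), types),
                    enriched_genes = enr_genes)
  })
}
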