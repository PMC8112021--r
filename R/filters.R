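lgd_consequences <- c("stop_gain", "frameshift", "canonical_splice",
                      "exon_deletion")

#' Classify variants into burden-test classes
#'
#' Assigns each variant to one of `LGD`, `cryptic_splice_LGD` (counted as LGD
#' downstream), `D-Mis`, `benign_missense`, `synonymous`, or `other`.
#' Stop-gains, frameshift indels, canonical splice variants, and exon
#' deletions are likely gene-disrupting (LGD). Synonymous variants with a
#' splice score of at least `splice_cutoff` are reclassified as cryptic
#' splice LGD. Missense variants are deleterious (`D-Mis`) when their REVEL
#' score reaches `revel_cutoff` (inclusive), benign otherwise; the cutoff may
#' be gene specific (e.g. 0.92 for one gene, 0.22 for another).
#'
#' @param variants Data frame with at least `consequence`, `revel`, and
#'   `splice_score` columns (a variant table from
#'   [simulate_case_control_cohort()] or [read_variant_table()]).
#' @param revel_cutoff Single REVEL cutoff, or a vector recycled against the
#'   rows (so a per-gene cutoff can be joined on beforehand).
#' @param splice_cutoff Cryptic splice score threshold.
#' @return The input as a tibble with an added `class` column.
#' @export
#' @examples
#' classify_variants(
#'   tibble::tibble(
#'     consequence = c("missense", "synonymous", "stop_gain"),
#'     revel = c(0.95, NA, NA), splice_score = c(NA, 0.6, NA)
#'   ),
#'   revel_cutoff = 0.92
#' )
classify_variants <- function(variants, revel_cutoff,
                              splice_cutoff = threshold_default("min_splice_score")) {
  variants <- tibble::as_tibble(variants)
  check_prob(revel_cutoff, "revel_cutoff")
  if (any(variants$consequence == "missense" & is.na(variants$revel))) {
    stop_bad_arg("missense variant without a REVEL score")
  }
  splice <- dplyr::coalesce(variants$splice_score, 0)
  variants %>% dplyr::mutate(class = dplyr::case_when(
    .data$consequence %in% lgd_consequences ~ "LGD",
    .data$consequence == "synonymous" & splice >= splice_cutoff ~ "cryptic_splice_LGD",
    .data$consequence == "missense" & .data$revel >= revel_cutoff ~ "D-Mis",
    .data$consequence == "missense" ~ "benign_missense",
    .data$consequence == "synonymous" ~ "synonymous",
    TRUE ~ "other"
  ))
}

inclusion_rules <- function(max_af_cohort, max_af_gnomad, min_frac_dp10,
                            min_allele_balance, min_caller_pass_fraction) {
  # order fixed to the order the rules are stated in; first failing rule is
  # the one attributed in the audit table
  list(
    af_cohort = function(v) v$af_cohort < max_af_cohort,
    af_gnomad = function(v) v$af_gnomad < max_af_gnomad,
    frac_samples_dp10 = function(v) v$frac_samples_dp10 > min_frac_dp10,
    mappability = function(v) v$mappability == 1,
    allele_balance = function(v) v$allele_balance >= min_allele_balance,
    caller_pass_fraction = function(v) v$caller_pass_fraction >= min_caller_pass_fraction
  )
}

#' Apply cohort variant inclusion filters
#'
#' Keeps a variant iff its cohort allele frequency is below 0.05%, its
#' population (gnomAD-style) frequency is below 0.01%, more than 90% of
#' samples cover the site at depth >= 10, it is uniquely mappable, its
#' allele balance is at least 0.25, and at least 50% of its calls are PASS
#' under the second caller. Frequencies are strict `<` comparisons;
#' coverage is strict `>`; allele balance and caller consensus are `>=`.
#'
#' Rejected variants are attributed to the *first* failing rule in the order
#' above, so the per-rule rejection counts always sum to
#' `nrow(input) - nrow(kept)`. Records with missing values in any filter
#' field are rejected with reason `malformed`.
#'
#' @param variants Variant table (see [classify_variants()] for provenance).
#' @param max_af_cohort,max_af_gnomad,min_frac_dp10,min_allele_balance,min_caller_pass_fraction
#'   Filter thresholds, as fractions; defaults are the registry values in
#'   [default_thresholds()].
#' @return List with `kept` (tibble of passing variants) and `audit` (tibble
#'   of `rule`, `n_rejected`).
#' @export
apply_inclusion_filters <- function(
    variants,
    max_af_cohort = threshold_default("max_af_cohort"),
    max_af_gnomad = threshold_default("max_af_gnomad"),
    min_frac_dp10 = threshold_default("min_frac_dp10"),
    min_allele_balance = threshold_default("min_allele_balance"),
    min_caller_pass_fraction = threshold_default("min_caller_pass_fraction")) {
  variants <- tibble::as_tibble(variants)
  rules <- inclusion_rules(max_af_cohort, max_af_gnomad, min_frac_dp10,
                           min_allele_balance, min_caller_pass_fraction)
  fields <- c("af_cohort", "af_gnomad", "frac_samples_dp10", "mappability",
              "allele_balance", "caller_pass_fraction")
  malformed <- !stats::complete.cases(variants[fields])
  reason <- rep(NA_character_, nrow(variants))
  reason[malformed] <- "malformed"
  for (rule in names(rules)) {
    fails <- !rules[[rule]](variants)
    fails[is.na(fails)] <- FALSE
    reason[is.na(reason) & fails] <- rule
  }
  audit <- tibble::tibble(rule = c(names(rules), "malformed")) %>%
    dplyr::mutate(n_rejected = purrr::map_int(
      .data$rule, ~ sum(reason == .x, na.rm = TRUE)
    ))
  list(
    kept = variants[is.na(reason), , drop = FALSE],
    audit = audit
  )
}

#' Trio de novo filter cascade
#'
#' Applies the full read-evidence filter cascade for candidate de novo calls:
#' the call-quality rules (VQSR tranche at most 99.7 for SNVs and 99.0 for
#' indels, Fisher strand at most 25, quality-by-depth at least 2), the
#' proband rules (at least 5 alternate reads, alternate allele fraction at
#' least 20%, GQ at least 60, population allele frequency at most 0.01%),
#' and the parent rules applied to both parents (at least 10 reference reads,
#' alternate allele fraction strictly below 5%, GQ at least 30).
#'
#' @param evidence Tibble of trio read evidence (one row per candidate call)
#'   with the columns produced by [simulate_trios()].
#' @return The input with added `accept` (logical) and `reasons` (list-column
#'   of character vectors naming every failed rule; empty when accepted).
#' @export
#' @examples
#' ev <- simulate_trios(
#'   sim_config(n_trios = 30, seed = 2),
#'   simulate_gene_models(5, seed = 2), demo_rate_table()
#' )$evidence
#' dplyr::count(call_de_novo(ev), accept)
call_de_novo <- function(evidence) {
  evidence <- tibble::as_tibble(evidence)
  th <- function(n) threshold_default(n)
  checks <- list(
    vqsr = evidence$vqsr_tranche <= ifelse(evidence$variant_type == "indel",
                                           th("max_vqsr_indel"),
                                           th("max_vqsr_snv")),
    fisher_strand = evidence$fisher_strand <= th("max_fisher_strand"),
    qual_by_depth = evidence$qual_by_depth >= th("min_qual_by_depth"),
    proband_alt_reads = evidence$proband_alt_reads >= th("min_proband_alt_reads"),
    proband_alt_fraction = evidence$proband_alt_fraction >= th("min_proband_alt_fraction"),
    proband_gq = evidence$proband_gq >= th("min_proband_gq"),
    population_af = evidence$population_af <= th("max_denovo_population_af"),
    parent_ref_reads = evidence$parent1_ref_reads >= th("min_parent_ref_reads") &
      evidence$parent2_ref_reads >= th("min_parent_ref_reads"),
    parent_alt_fraction = evidence$parent1_alt_fraction < th("max_parent_alt_fraction") &
      evidence$parent2_alt_fraction < th("max_parent_alt_fraction"),
    parent_gq = evidence$parent1_gq >= th("min_parent_gq") &
      evidence$parent2_gq >= th("min_parent_gq")
  )
  fail <- !do.call(cbind, checks)
  evidence %>% dplyr::mutate(
    accept = rowSums(fail) == 0L,
    reasons = purrr::map(seq_len(dplyr::n()), ~ colnames(fail)[fail[.x, ]])
  )
}

#' Count collapsed carriers of qualifying variants in a gene
#'
#' Counts distinct case and control carriers of variants of the requested
#' classes in one gene, at a given REVEL cutoff. Individuals are counted
#' once per gene no matter how many qualifying variants they carry
#' (collapsing convention). `cryptic_splice_LGD` is folded into `LGD`.
#'
#' @param carriers Carrier table (`sample_id`, `gene`, `variant_id`).
#' @param variants Variant table carrying `variant_id`, `gene`,
#'   `consequence`, `revel`, `splice_score`.
#' @param manifest Sample manifest with `sample_id` and `status`.
#' @param gene Gene id to count.
#' @param classes Character subset of `c("LGD", "D-Mis")` (and/or the other
#'   classes emitted by [classify_variants()]).
#' @param revel_cutoff REVEL cutoff defining `D-Mis`.
#' @return Tibble with one row: `gene`, `case_carriers`, `control_carriers`.
#' @export
count_carriers <- function(carriers, variants, manifest, gene,
                           classes = c("LGD", "D-Mis"), revel_cutoff = 0.5) {
  v <- classify_variants(dplyr::filter(variants, .data$gene == .env$gene),
                         revel_cutoff) %>%
    dplyr::mutate(class = ifelse(.data$class == "cryptic_splice_LGD",
                                 "LGD", .data$class)) %>%
    dplyr::filter(.data$class %in% classes)
  hits <- carriers %>%
    dplyr::filter(.data$gene == .env$gene,
                  .data$variant_id %in% v$variant_id) %>%
    dplyr::distinct(.data$sample_id) %>%
    dplyr::inner_join(manifest, by = "sample_id")
  tibble::tibble(
    gene = gene,
    case_carriers = sum(hits$status == "case"),
    control_carriers = sum(hits$status == "control")
  )
}
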