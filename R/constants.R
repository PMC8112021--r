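#' Default analysis thresholds
#'
#' Returns the full set of default filter and test constants used across the
#' package, as a two-column tibble (`name`, `value`). These are the values a
#' typical large rare-variant case-control study would use; every function
#' that consumes one of them exposes it as an argument with the same default,
#' so this table doubles as a machine-checkable registry of defaults.
#'
#' All allele frequencies are fractions, never percentages: `1e-04` means
#' 0.01%.
#'
#' @return A tibble with columns `name` (character) and `value` (double).
#' @export
#' @examples
#' default_thresholds()
default_thresholds <- function() {
  tibble::tribble(
    ~name,                      ~value,
    # cohort inclusion filters (fractions)
    "max_af_cohort",            5e-04,   # cohort AF < 0.05%
    "max_af_gnomad",            1e-04,   # population AF < 0.01%
    "min_frac_dp10",            0.9,     # > 90% of samples with DP >= 10
    "min_mappability",          1,       # uniquely mappable only
    "min_allele_balance",       0.25,
    "min_caller_pass_fraction", 0.5,     # >= 50% of calls PASS second caller
    "rare_af_max",              1e-04,   # "rare" definition: AF <= 0.01%
    # cryptic splice
    "min_splice_score",         0.5,
    # trio de novo filters
    "max_vqsr_snv",             99.7,
    "max_vqsr_indel",           99.0,
    "max_fisher_strand",        25,
    "min_qual_by_depth",        2,
    "min_proband_alt_reads",    5,
    "min_proband_alt_fraction", 0.20,
    "min_proband_gq",           60,
    "max_denovo_population_af", 1e-04,
    "min_parent_ref_reads",     10,
    "max_parent_alt_fraction",  0.05,    # strict: < 5%
    "min_parent_gq",            30,
    # association testing
    "default_permutations",     10000,
    "alpha",                    0.05,
    "bonferroni_n_tests",       40000,
    "fdr_threshold",            0.1,
    # expression ranking
    "min_cells_per_type",       70,
    "top_quantile",             0.05
  )
}

threshold_default <- function(name) {
  tb <- default_thresholds()
  tb$value[match(name, tb$name)]
}
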