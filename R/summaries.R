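#' Summarize carriers of a candidate gene
#'
#' Clinical-table style summary of a carrier group: count, sex ratio,
#' mean +/- SD of diagnostic age and hemodynamics (computed over non-missing
#' values with the n-1 sample SD; SD is reported missing for a single
#' carrier), subclass counts, and — when variant labels are supplied — the
#' number of distinct carriers of each identical nucleotide change
#' (recurrent variants).
#'
#' @param manifest Sample manifest with `sample_id`, `sex`, `subclass`,
#'   `age_onset`, `mpap`, `mpcwp`.
#' @param carrier_ids Character vector of carrier sample ids (must all be in
#'   the manifest).
#' @param variant_labels Optional tibble (`sample_id`, `variant`) used for
#'   recurrent-variant counts.
#' @return One-row tibble with summary columns plus list-columns
#'   `subclass_counts` and `recurrent_variants`.
#' @export
summarize_carriers <- function(manifest, carrier_ids, variant_labels = NULL) {
  if (length(carrier_ids) == 0L) stop_bad_arg("empty carrier list")
  if (!all(carrier_ids %in% manifest$sample_id)) {
    stop_bad_arg("carriers must be a subset of the manifest")
  }
  cc <- manifest[manifest$sample_id %in% carrier_ids, , drop = FALSE]
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) sd(x) else NA_real_)
  }
  age <- msd(cc$age_onset); mpap <- msd(cc$mpap); mpcwp <- msd(cc$mpcwp)
  nf <- sum(cc$sex == "F"); nm <- sum(cc$sex == "M")
  recurrent <- if (!is.null(variant_labels)) {
    variant_labels %>%
      dplyr::filter(.data$sample_id %in% carrier_ids) %>%
      dplyr::distinct(.data$sample_id, .data$variant) %>%
      dplyr::count(.data$variant, name = "n_carriers") %>%
      dplyr::arrange(dplyr::desc(.data$n_carriers))
  } else {
    tibble::tibble(variant = character(), n_carriers = integer())
  }
  tibble::tibble(
    n = nrow(cc), n_female = nf, n_male = nm,
    sex_ratio = if (nm > 0) nf / nm else Inf,
    age_mean = age[["mean"]], age_sd = age[["sd"]],
    mpap_mean = mpap[["mean"]], mpap_sd = mpap[["sd"]],
    mpcwp_mean = mpcwp[["mean"]], mpcwp_sd = mpcwp[["sd"]],
    subclass_counts = list(dplyr::count(cc, .data$subclass)),
    recurrent_variants = list(recurrent)
  )
}

#' Carrier rate within a cohort subclass
#'
#' Fraction of a disease subclass carrying qualifying variants, reported
#' both as a raw fraction and as a percentage rounded to one decimal.
#'
#' @param manifest Sample manifest with `sample_id` and `subclass`.
#' @param carrier_ids Carrier sample ids.
#' @param subclass Subclass label to summarize (e.g. `"IPAH"`, `"FPAH"`).
#' @return One-row tibble: `subclass`, `n_carriers`, `n_subclass`,
#'   `fraction`, `percent` (one decimal).
#' @export
#' @examples
#' mf <- tibble::tibble(sample_id = sprintf("s%03d", 1:191), subclass = "FPAH")
#' cohort_rates(mf, mf$sample_id[1:108], "FPAH")
cohort_rates <- function(manifest, carrier_ids, subclass) {
  members <- manifest$sample_id[!is.na(manifest$subclass) &
                                  manifest$subclass == subclass]
  if (length(members) == 0L) stop_bad_arg("subclass not present in manifest")
  k <- sum(carrier_ids %in% members)
  tibble::tibble(
    subclass = subclass, n_carriers = k, n_subclass = length(members),
    fraction = k / length(members),
    percent = round(100 * k / length(members), 1)
  )
}
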