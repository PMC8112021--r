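# Fixtures built in code and independent oracle implementations used across
# the suite. Oracles deliberately use different algorithms (enumeration,
# brute-force summation, base-R reference tests) than the package paths they
# check.

# ---- transcribed carrier tables (published clinical summaries) -------------

# FBLN2 carriers: sex, age at diagnosis, subclass, nucleotide change, and
# hemodynamics (NA = not recorded)
fbln2_carriers <- function() {
  tibble::tibble(
    sample_id = c("08-018", "17-035", "12-207", "23-001", "29-031",
                  "34-005", "W000210"),
    sex = c("F", "F", "F", "M", "F", "M", "F"),
    subclass = c("IPAH", "APAH", "IPAH", "IPAH", "IPAH", "IPAH", "IPAH"),
    status = "case",
    age_onset = c(70, 41, 44, 66, 57, 69, 52),
    mpap = c(58, 43, NA, 68, 84, 43, 75),
    mpcwp = c(14, 16, NA, 10, 15, 14, 11),
    variant = c("c.2639G>T", "c.2666G>A", "c.2794T>C", "c.2944G>T",
                "c.2944G>T", "c.2944G>T", "c.2944G>T"),
    revel = c(0.94, 0.94, 0.92, 0.95, 0.95, 0.95, 0.95)
  )
}

pdgfd_carriers <- function() {
  tibble::tibble(
    sample_id = c("W000073", "JM950", "E012465", "E014342", "E014400",
                  "E000844", "13-037", "23-025", "E000820", "E010173"),
    sex = c("F", "F", "F", "F", "F", "F", "M", "F", "F", "F"),
    subclass = c("IPAH", "IPAH", "IPAH", "IPAH", "IPAH", "IPAH", "other",
                 "IPAH", "IPAH", "IPAH"),
    status = "case",
    age_onset = c(40, 2, 55, 40, 43, 39, 43, 41, 73, 74),
    mpap = c(73, 39, 52, 57, 57, 51, 47, 64, 48, 32),
    mpcwp = c(NA, NA, 7, 7, 4, 9, 7, NA, 9, 9),
    variant = c("c.166G>A", "c.250C>T", "c.385G>A", "c.385G>A", "c.442G>A",
                "c.770T>C", "c.883C>T", "c.926C>G", "c.961T>A", "c.961T>A"),
    revel = c(0.64, 0.51, 0.262, 0.262, 0.41, 0.62, 0.56, 0.22, 0.34, 0.34)
  )
}

# cohort tables (variants / carriers / manifest) for the FBLN2 rows above,
# embedded in a padded cohort so count_carriers has non-carriers to ignore
fbln2_cohort <- function() {
  carr <- fbln2_carriers()
  sites <- dplyr::distinct(carr, variant, .keep_all = TRUE)
  variants <- tibble::tibble(
    variant_id = sites$variant, chrom = "chr3",
    pos = seq_len(nrow(sites)) * 100L,
    ref = "G", alt = "T", gene = "FBLN2", consequence = "missense",
    revel = sites$revel, splice_score = NA_real_,
    af_gnomad = 2e-05, af_cohort = 1e-04, allele_balance = 0.5,
    frac_samples_dp10 = 0.99, mappability = 1, caller_pass_fraction = 1,
    variant_type = "SNV"
  )
  manifest <- dplyr::bind_rows(
    carr[, c("sample_id", "status", "subclass", "sex", "age_onset",
             "mpap", "mpcwp")],
    tibble::tibble(
      sample_id = sprintf("pad_%03d", 1:20),
      status = rep(c("case", "control"), 10),
      subclass = ifelse(rep(c(TRUE, FALSE), 10), "IPAH", NA),
      sex = "F", age_onset = 50, mpap = 50, mpcwp = 10
    )
  )
  list(
    variants = variants,
    carriers = tibble::tibble(sample_id = carr$sample_id, gene = "FBLN2",
                              variant_id = carr$variant),
    manifest = manifest
  )
}

# ten-record inclusion-filter fixture: one violation of each of the six
# rules plus four clean records
inclusion_fixture <- function() {
  clean <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:10), chrom = "chr1", pos = 1:10,
    ref = "A", alt = "C", gene = "G1", consequence = "missense",
    revel = 0.5, splice_score = NA_real_,
    af_cohort = 1e-04, af_gnomad = 5e-05, frac_samples_dp10 = 0.95,
    mappability = 1, allele_balance = 0.4, caller_pass_fraction = 0.8,
    variant_type = "SNV"
  )
  clean$af_cohort[1] <- 6e-04          # cohort AF rule
  clean$af_gnomad[2] <- 2e-04          # population AF rule
  clean$frac_samples_dp10[3] <- 0.85   # coverage rule
  clean$mappability[4] <- 0            # mappability rule
  clean$allele_balance[5] <- 0.24      # allele-balance rule
  clean$caller_pass_fraction[6] <- 0.4 # caller-consensus rule
  clean
}

# a de novo evidence record passing every filter
passing_evidence <- function(n = 1) {
  tibble::tibble(
    trio_id = sprintf("trio_%03d", seq_len(n)),
    variant_id = sprintf("dnv_%03d", seq_len(n)),
    gene = "G1", class = "MIS", variant_type = "SNV",
    proband_alt_reads = 12L, proband_alt_fraction = 0.45, proband_gq = 99,
    parent1_ref_reads = 30L, parent1_alt_fraction = 0.01, parent1_gq = 99,
    parent2_ref_reads = 30L, parent2_alt_fraction = 0.01, parent2_gq = 99,
    vqsr_tranche = 95, fisher_strand = 5, qual_by_depth = 10,
    population_af = 0
  )
}

# a gene model wrapper around an explicit coding sequence
gene_model_from_seq <- function(seq_with_flanks, gene = "toy",
                                highly_expressed = TRUE) {
  len <- nchar(seq_with_flanks) - 2L
  tibble::tibble(
    gene = gene, chrom = "chrT", strand = "+",
    highly_expressed = highly_expressed, mappable_fraction = 1,
    sequence = seq_with_flanks,
    intervals = list(tibble::tibble(start = 100L, end = 100L + len))
  )
}

# ---- independent oracles ---------------------------------------------------

# brute-force Benjamini-Hochberg step-up from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exhaustive 9-substitution consequence enumeration for a single codon,
# using the standard genetic code spelled out by Biostrings-independent
# base-R translation via seqinr is what the package uses; the oracle keeps
# its own copy of the code as a lookup built from matching codon triples
codon_oracle <- function(codon, flank5, flank3, rate_lookup) {
  aa <- function(cd) seqinr::translate(strsplit(cd, "")[[1]])
  bases <- c("A", "C", "G", "T")
  full <- paste0(flank5, codon, flank3)
  out <- c(SYN = 0, MIS = 0, NON = 0)
  for (i in 1:3) {
    ref <- substr(codon, i, i)
    ctx <- substr(full, i, i + 2)
    for (alt in setdiff(bases, ref)) {
      mutated <- codon
      substr(mutated, i, i) <- alt
      cls <- if (aa(mutated) == aa(codon)) "SYN"
             else if (aa(mutated) == "*") "NON" else "MIS"
      out[cls] <- out[cls] + rate_lookup[paste0(ctx, alt)]
    }
  }
  out
}

rate_lookup_from <- function(rates) {
  stats::setNames(rates$mu, paste0(rates$context, rates$alt))
}

# exhaustive variable-threshold permutation null for tiny cohorts:
# enumerates every assignment of case labels and re-maximizes thresholds
vt_exhaustive_p <- function(has_lgd, revel, carrier_is_case, nA, nB, config) {
  n <- nA + nB
  m <- length(has_lgd)
  stat_at <- function(is_case_carrier) {
    ts <- sort(unique(revel[!is.na(revel)]), decreasing = TRUE)
    if (config == "LGD_plus_DMis") ts <- c(Inf, ts)
    best <- 0
    for (t in ts) {
      qual <- (!is.na(revel) & revel >= t) |
        (config == "LGD_plus_DMis" & has_lgd)
      a <- sum(qual & is_case_carrier)
      b <- sum(qual & !is_case_carrier)
      p <- stats::phyper(a - 1, nA, nB, a + b, lower.tail = FALSE)
      best <- max(best, -log10(max(p, .Machine$double.xmin)))
    }
    best
  }
  obs <- stat_at(carrier_is_case)
  # carriers occupy the first m sample slots; enumerate case-label subsets
  subsets <- utils::combn(n, nA)
  maxima <- apply(subsets, 2, function(cols) stat_at(seq_len(m) %in% cols))
  mean(maxima >= obs - 1e-12)
}
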