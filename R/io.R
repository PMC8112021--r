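# TSV readers/writers for every table the pipeline exchanges. All writers
# encode missing values as "NA"; every reader is the exact inverse of its
# writer (round-trip equality is asserted in the test suite). Allele
# frequencies are stored as fractions; coordinates are 1-based in variant
# tables and 0-based half-open in BED.

#' @rdname cohort_io
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path, na = "NA")
  invisible(path)
}

#' Read and write cohort tables
#'
#' @param variants,manifest,carriers Tables as produced by
#'   [simulate_case_control_cohort()].
#' @param path File path.
#' @name cohort_io
#' @return Readers return tibbles; writers return the path, invisibly.
#' @export
read_variant_table <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                  col_types = readr::cols(
                    variant_id = "c", chrom = "c", ref = "c", alt = "c",
                    gene = "c", consequence = "c", variant_type = "c",
                    pos = "i", .default = "d"
                  ))
}

#' @rdname cohort_io
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, na = "NA")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", status = "c", subclass = "c", sex = "c",
                    ancestry = "c", .default = "d"
                  ))
}

#' @rdname cohort_io
#' @export
write_carrier_table <- function(carriers, path) {
  readr::write_tsv(carriers, path, na = "NA")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_carrier_table <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' Read and write trinucleotide mutation-rate tables
#'
#' The on-disk format is a 3-column TSV (`context`, `alt`, `mu`) covering
#' all 192 context/alternate combinations; `mu` is the per-site
#' per-generation mutation probability.
#'
#' @param rates Rate table tibble.
#' @param path File path.
#' @return [read_rate_table()] returns a validated tibble.
#' @export
write_rate_table <- function(rates, path) {
  readr::write_tsv(check_rate_table(rates), path)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  check_rate_table(readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(context = "c", alt = "c", mu = "d")
  ))
}

#' Read and write gene models as a BED / FASTA pair
#'
#' The BED file holds 0-based half-open coding intervals (one row per
#' interval) with the gene id in the name column, the highly-expressed flag
#' in the score column, and the strand; the FASTA holds the coding sequence
#' with one flanking base on each side, named by gene id.
#'
#' @param genes Gene model tibble ([simulate_gene_models()]).
#' @param bed_path,fasta_path Output paths.
#' @return [read_gene_models()] returns the gene model tibble.
#' @export
write_gene_models <- function(genes, bed_path, fasta_path) {
  bed <- genes %>%
    dplyr::select("gene", "chrom", "strand", "highly_expressed", "intervals") %>%
    tidyr::unnest("intervals") %>%
    dplyr::transmute(
      chrom = .data$chrom, start = .data$start, end = .data$end,
      name = .data$gene, score = as.integer(.data$highly_expressed),
      strand = .data$strand
    )
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  seqinr::write.fasta(
    as.list(genes$sequence), names = genes$gene, file.out = fasta_path,
    as.string = TRUE, nbchar = 80
  )
  invisible(bed_path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(bed_path, fasta_path) {
  bed <- readr::read_tsv(
    bed_path, col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", show_col_types = FALSE
  )
  fa <- seqinr::read.fasta(fasta_path, as.string = TRUE, forceDNAtolower = FALSE)
  seqs <- setNames(toupper(vapply(fa, `[[`, "", 1L)), names(fa))
  bed %>%
    dplyr::arrange(.data$name, .data$start) %>%
    tidyr::nest(intervals = c("start", "end")) %>%
    dplyr::transmute(
      gene = .data$name,
      chrom = .data$chrom,
      strand = .data$strand,
      highly_expressed = .data$score == 1L,
      mappable_fraction = 1,
      sequence = unname(seqs[.data$name]),
      intervals = purrr::map(.data$intervals, tibble::as_tibble)
    )
}

#' Read and write fraction-of-expressing-cells matrices
#'
#' Wide TSV with a `gene` column and one fraction column per cell type; the
#' per-type cell counts travel in a sidecar two-column TSV.
#'
#' @param m An `expr_matrix`.
#' @param path,counts_path Paths for the fraction matrix and the cell-count
#'   sidecar.
#' @return [read_expression_matrix()] returns an `expr_matrix`.
#' @export
write_expression_matrix <- function(m, path, counts_path) {
  readr::write_tsv(tibble::as_tibble(m), path)
  readr::write_tsv(
    tibble::tibble(cell_type = names(cell_counts(m)),
                   n_cells = unname(cell_counts(m))),
    counts_path
  )
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path, counts_path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(gene = "c", .default = "d"))
  cts <- readr::read_tsv(counts_path, show_col_types = FALSE,
                         col_types = readr::cols(cell_type = "c", n_cells = "i"))
  new_expr_matrix(tbl, setNames(cts$n_cells, cts$cell_type))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate -> filter -> burden scan -> de novo burden -> expression ranking
#' -> summaries, optionally writing every intermediate table plus a
#' machine-readable JSON manifest (package version, seed, thresholds) to an
#' output directory. Any stage failure aborts with the stage name.
#'
#' @param config A [sim_config()].
#' @param B Permutations for the burden scan.
#' @param out_dir Output directory (`NULL` to keep everything in memory).
#' @param rates Mutation-rate table.
#' @return List with `cohort`, `filter_audit`, `scan` (a `vt_scan`),
#'   `denovo` (tibble of de novo burden rows), `expression` (a `pc_ranking`),
#'   `enrichment`, and `manifest`.
#' @export
run_pipeline <- function(config, B = 500L, out_dir = NULL,
                         rates = demo_rate_table()) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), class = "vtburden_error")
    })
  }
  cohort <- stage("simulate", simulate_case_control_cohort(config))
  filtered <- stage("filter", apply_inclusion_filters(cohort$variants))
  cohort$variants <- filtered$kept
  scan <- stage("burden", genomewide_scan(cohort, B = B, seed = config$seed))

  genes <- stage("gene_models", simulate_gene_models(
    n_genes = min(config$n_genes, 50L), seed = config$seed
  ))
  gene_rates <- stage("denovo", gene_class_rates(genes, rates))
  trios <- stage("denovo", simulate_trios(config, genes, rates))
  dn_calls <- stage("denovo", call_de_novo(trios$evidence))
  dn_obs <- dn_calls %>% dplyr::filter(.data$accept) %>%
    dplyr::select("gene", "class")
  denovo <- stage("denovo", dplyr::bind_rows(
    denovo_burden(dn_obs, gene_rates, "SYN", config$n_trios),
    denovo_burden(dn_obs, gene_rates, "MIS", config$n_trios),
    denovo_burden(dn_obs, gene_rates, "LGD", config$n_trios)
  ))

  expr <- stage("expression", simulate_expression_matrix(config))
  known <- attr(expr, "enriched_genes")
  ranking <- stage("expression", pc_ranking(expr, known))
  enrichment <- stage("expression", topq_enrichment(ranking, known))

  manifest <- list(
    package = "vtburden",
    version = as.character(utils::packageVersion("vtburden")),
    seed = config$seed, permutations = B,
    thresholds = setNames(as.list(default_thresholds()$value),
                          default_thresholds()$name)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_manifest(cohort$manifest, p("manifest.tsv"))
    write_variant_table(cohort$variants, p("variants.tsv"))
    write_carrier_table(cohort$carriers, p("carriers.tsv"))
    readr::write_tsv(filtered$audit, p("filter_audit.tsv"))
    readr::write_tsv(scan$results, p("burden_results.tsv"))
    readr::write_tsv(denovo, p("denovo_burden.tsv"))
    readr::write_tsv(tibble::as_tibble(ranking), p("pc_ranking.tsv"))
    readr::write_tsv(enrichment, p("topq_enrichment.tsv"))
    jsonlite::write_json(manifest, p("run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(
    cohort = cohort, filter_audit = filtered$audit, scan = scan,
    denovo = denovo, expression = ranking, enrichment = enrichment,
    manifest = manifest
  )
}
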