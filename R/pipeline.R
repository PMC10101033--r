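#' Run the full redundancy / primer-evaluation pipeline
#'
#' Orchestrates: unit splitting with ambiguity sanitization, 16S gene
#' detection (or the pre-extracted-genes bypass), per-genome redundancy
#' statistics with rank aggregation, in silico PCR over every primer pair,
#' matching-amplicon detection and the per-pair coverage metrics, and the
#' cross-primer MA tally. With `out_dir` set, all report tables are written
#' as TSV together with a run log recording the seed and the record counts
#' at every filtering step.
#'
#' @param genomes Genome tibble or FASTA path ([read_genomes()]).
#' @param taxonomy Taxonomy tibble or TSV path ([read_taxonomy()]).
#' @param primers Primer table (default: bundled catalogue).
#' @param genes Optional pre-extracted gene tibble or FASTA path
#'   ([read_genes_fasta()]); bypasses the gene finder.
#' @param known_genes Sequences seeding the finder's reference panel
#'   (default: the synthetic 16S template).
#' @param seed Integer seed (drives ambiguity replacement).
#' @param run_threshold Ambiguity-run exclusion threshold.
#' @param window,density_threshold,min_len,max_len Gene-finder settings.
#' @param ma_tally_threshold Minimum pairs for the cross-primer MA tally.
#' @param out_dir Optional output directory for the TSV report bundle.
#' @return List of class `pipeline_result`: `units`, `sanitization`,
#'   `genes`, `genome_stats`, `redundancy`, `amplicons`, `amplicon_sizes`,
#'   `evaluation`, `ma_groups`, `ma_tally`, `seed`.
#' @export
run_pipeline <- function(genomes, taxonomy, primers = read_primer_pairs(),
                         genes = NULL, known_genes = synthetic_16s_template(),
                         seed = 1L, run_threshold = 10,
                         window = 100, density_threshold = 0.30,
                         min_len = 1200, max_len = 1900,
                         ma_tally_threshold = 10, out_dir = NULL) {
  if (is.character(taxonomy)) {
    if (!file.exists(taxonomy)) abort(sprintf("taxonomy file not found: %s", taxonomy))
    taxonomy <- read_taxonomy(taxonomy)
  } else {
    taxonomy <- read_taxonomy(taxonomy)
  }
  if (is.character(genomes)) {
    if (!file.exists(genomes)) abort(sprintf("genome FASTA not found: %s", genomes))
    genomes <- read_genomes(genomes)
  }
  units <- split_units(genomes, taxonomy, seed = seed, run_threshold = run_threshold)
  sanit <- sanitization_report(units)

  if (is.null(genes)) {
    panel <- build_reference_panel(known_genes)
    genes <- extract_genes(units, panel, window = window,
                           density_threshold = density_threshold,
                           min_len = min_len, max_len = max_len)
  } else if (is.character(genes)) {
    if (!file.exists(genes)) abort(sprintf("genes FASTA not found: %s", genes))
    genes <- read_genes_fasta(genes)
  }
  genes <- genes[genes$unit_id %in% units$unit_id, ]

  genome_stats <- summarize_genomes(genes, units)
  redundancy <- redundancy_table(genome_stats)
  amplicons <- amplify(genes, primers, units = units)
  sizes <- amplicon_size_table(amplicons, units)
  evaluation <- evaluate_primer_pairs(amplicons, units, primers)
  groups <- find_ma_groups(amplicons)
  tally <- cross_primer_ma_tally(attr(evaluation, "ma_flags"),
                                 threshold = ma_tally_threshold)

  result <- structure(
    list(
      units = units, sanitization = sanit, genes = genes,
      genome_stats = genome_stats, redundancy = redundancy,
      amplicons = amplicons, amplicon_sizes = sizes,
      evaluation = evaluation, ma_groups = groups, ma_tally = tally,
      seed = seed
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

#' Per-pair amplicon size and count summary
#'
#' Mean amplicon length, mean amplicons per detected genome unit (g/G) and
#' mean distinct amplicon sequences per unit (gv/G), per domain, with the
#' amplicon length category.
#'
#' @param amplicons Amplicon table (with species/superkingdom columns).
#' @param units Unit table.
#' @return Tibble: `pair_id`, `domain`, `mean_amplicon_length`,
#'   `g_per_genome`, `gv_per_genome`, `length_category`.
#' @export
amplicon_size_table <- function(amplicons, units) {
  if (nrow(amplicons) == 0) {
    return(tibble(pair_id = character(0), domain = character(0),
                  mean_amplicon_length = numeric(0), g_per_genome = numeric(0),
                  gv_per_genome = numeric(0), length_category = character(0)))
  }
  amplicons |>
    dplyr::mutate(domain = superkingdom_domain(.data$superkingdom)) |>
    dplyr::group_by(.data$pair_id, .data$domain, .data$unit_id) |>
    dplyr::summarise(
      mean_len = mean(.data$length_bp),
      n_amp = dplyr::n(),
      n_var = count_variants(.data$sequence),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(
      mean_amplicon_length = mean(.data$mean_len),
      g_per_genome = mean(.data$n_amp),
      gv_per_genome = mean(.data$n_var),
      .groups = "drop"
    ) |>
    dplyr::mutate(length_category = classify_length_category(.data$mean_amplicon_length))
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
  w(dplyr::select(result$units, -"sequence"), "units.tsv")
  w(dplyr::select(result$sanitization, -"replacements"), "sanitization_report.tsv")
  w(dplyr::select(result$genes, -"sequence"), "genes.tsv")
  w(dplyr::select(result$genome_stats, dplyr::everything()), "genome_stats.tsv")
  w(result$redundancy, "redundancy_by_rank.tsv")
  w(result$amplicon_sizes, "amplicon_sizes.tsv")
  w(as_tibble(result$evaluation), "primer_evaluation.tsv")
  if (nrow(result$ma_groups) > 0) {
    w(result$ma_groups |>
        dplyr::mutate(members = purrr::map_chr(
          .data$members, ~ paste(unique(.x$species), collapse = ";"))),
      "ma_groups.tsv")
  }
  flagmat <- attr(result$ma_tally, "flag_matrix", exact = TRUE)
  if (!is.null(flagmat) && nrow(flagmat) > 0) w(flagmat, "ma_flag_matrix.tsv")
  w(result$ma_tally, "ma_tally.tsv")
  log_lines <- c(
    sprintf("amplimatch %s", as.character(utils::packageVersion("amplimatch"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", result$seed),
    sprintf("input chromosomes: %d", nrow(result$sanitization)),
    sprintf("excluded by ambiguity run: %d", sum(result$sanitization$excluded)),
    sprintf("analysis units: %d", nrow(result$units)),
    sprintf("genes detected: %d", nrow(result$genes)),
    sprintf("amplicons: %d", nrow(result$amplicons)),
    sprintf("primer pairs evaluated: %d", dplyr::n_distinct(result$evaluation$pair_id))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d units, %d genes, %d amplicons, %d primer pairs (seed %d)\n",
    nrow(x$units), nrow(x$genes), nrow(x$amplicons),
    dplyr::n_distinct(x$evaluation$pair_id), x$seed
  ))
  invisible(x)
}

#' Recompute the published formula worked examples
#'
#' Re-derives, from the printed per-pair species counts, reference
#' positions and species-band counts bundled with the package, every
#' SC-NMA value, combined two-domain SC-NMA, reported span length and
#' multi-copy species percentage, and compares each against its published
#' value.
#'
#' @param path Optional alternative worked-examples TSV.
#' @return Tibble: `example_id`, `kind`, `computed`, `expected`, `match`.
#' @export
worked_examples_report <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "worked_examples.tsv", package = "amplimatch")
  }
  ex <- readr::read_tsv(path, col_types = readr::cols(
    example_id = readr::col_character(),
    kind = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  computed <- vapply(seq_len(nrow(ex)), function(i) {
    row <- ex[i, ]
    switch(row$kind,
      sc_nma = sc_nma(row$detected, row$ma, row$total),
      sc_nma_overall = sc_nma_overall(row$detected, row$ma, row$total,
                                      row$detected2, row$ma2, row$total2),
      span = as.numeric(paper_span_length(row$f_first, row$r_last)),
      multi_copy_pct = round_half_up((row$total - row$n_single) / row$total * 100, 2),
      abort(sprintf("unknown worked-example kind '%s'", row$kind))
    )
  }, numeric(1))
  tibble(
    example_id = ex$example_id,
    kind = ex$kind,
    computed = computed,
    expected = ex$expected,
    match = abs(computed - ex$expected) < 0.005
  )
}
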