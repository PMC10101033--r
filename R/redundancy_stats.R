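#' Count distinct 16S gene variants
#'
#' A variant is a gene sequence differing by at least one nucleotide from
#' the others; under exact string identity this equals the number of
#' distinct sequences (and is independent of which sequence comes first).
#' Sequences of different lengths are distinct variants.
#'
#' @param gene_seqs Character vector of gene sequences (may be empty).
#' @return Integer count of distinct sequences (0 for empty input).
#' @export
count_variants <- function(gene_seqs) {
  length(unique(gene_seqs))
}

#' Per-unit 16S gene statistics
#'
#' For every analysis unit: total gene count, distinct-variant count,
#' per-strand counts, mean gene length and genome length. Units with no
#' detected genes get zero counts.
#'
#' @param hits Gene-hit tibble from [extract_genes()] (or the bypass path;
#'   a missing `strand` column is tolerated and counted as plus).
#' @param units Unit tibble from [split_units()].
#' @return Tibble with one row per unit: `unit_id`, `genome_id`, taxonomy
#'   ranks, `n_genes`, `n_variants`, `n_plus_strand`, `n_minus_strand`,
#'   `mean_gene_length`, `genome_length`.
#' @export
summarize_genomes <- function(hits, units) {
  stray <- setdiff(unique(hits$unit_id), units$unit_id)
  if (length(stray) > 0) {
    abort(sprintf("gene hits reference unknown unit(s): %s",
                  paste(stray, collapse = ", ")))
  }
  if (!"strand" %in% names(hits)) hits$strand <- "+"
  per_unit <- hits |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_variants = count_variants(.data$sequence),
      n_plus_strand = sum(.data$strand == "+"),
      n_minus_strand = sum(.data$strand == "-"),
      mean_gene_length = mean(nchar(.data$sequence)),
      .groups = "drop"
    )
  units |>
    dplyr::select(dplyr::all_of(c("unit_id", "genome_id", TAXONOMY_RANKS)),
                  genome_length = "length_bp") |>
    dplyr::left_join(per_unit, by = "unit_id") |>
    dplyr::mutate(dplyr::across(
      c("n_genes", "n_variants", "n_plus_strand", "n_minus_strand"),
      ~ dplyr::coalesce(.x, 0L)
    ))
}

rank_index <- function(rank) {
  i <- match(rank, TAXONOMY_RANKS)
  if (is.na(i)) abort(sprintf("unknown rank '%s'", rank))
  i
}

#' Aggregate gene/variant counts to a taxonomic rank
#'
#' Species-level values are means over that species' genome units. Values at
#' ranks above species are, by default, hierarchical means of the immediate
#' child taxa's means (mean-of-means, matching a nested per-rank
#' presentation); `method = "pooled"` averages directly over all genome
#' units under the taxon instead. At strain level the raw per-unit counts
#' are reported and `max_genes`/`min_genes` give the strain-level range
#' (not a mean).
#'
#' @param stats Per-unit table from [summarize_genomes()].
#' @param rank One of the eight ranks.
#' @param method `"mean_of_means"` (default) or `"pooled"`.
#' @return Tibble with `taxon` (label at `rank`, plus the higher-rank
#'   lineage columns), `mean_genes`, `mean_variants`, `n_genomes`,
#'   `max_genes`, `min_genes`.
#' @export
aggregate_redundancy <- function(stats, rank, method = c("mean_of_means", "pooled")) {
  method <- match.arg(method)
  ri <- rank_index(rank)
  lineage <- TAXONOMY_RANKS[seq_len(ri)]
  if (any(is.na(stats[[rank]]))) abort("units with missing taxonomy labels")
  if (rank == "strain") {
    out <- stats |>
      dplyr::group_by(dplyr::across(dplyr::all_of(lineage))) |>
      dplyr::summarise(
        mean_genes = mean(.data$n_genes),
        mean_variants = mean(.data$n_variants),
        n_genomes = dplyr::n(),
        max_genes = max(.data$n_genes),
        min_genes = min(.data$n_genes),
        .groups = "drop"
      )
  } else if (method == "pooled") {
    out <- stats |>
      dplyr::group_by(dplyr::across(dplyr::all_of(lineage))) |>
      dplyr::summarise(
        mean_genes = mean(.data$n_genes),
        mean_variants = mean(.data$n_variants),
        n_genomes = dplyr::n(),
        max_genes = max(.data$n_genes),
        min_genes = min(.data$n_genes),
        .groups = "drop"
      )
  } else {
    # species means first, then collapse one rank at a time by mean of the
    # immediate children's means
    cur <- stats |>
      dplyr::group_by(dplyr::across(dplyr::all_of(TAXONOMY_RANKS[1:7]))) |>
      dplyr::summarise(
        mean_genes = mean(.data$n_genes),
        mean_variants = mean(.data$n_variants),
        n_genomes = dplyr::n(),
        max_genes = max(.data$n_genes),
        min_genes = min(.data$n_genes),
        .groups = "drop"
      )
    lvl <- 7L
    while (lvl > ri) {
      lvl <- lvl - 1L
      cur <- cur |>
        dplyr::group_by(dplyr::across(dplyr::all_of(TAXONOMY_RANKS[seq_len(lvl)]))) |>
        dplyr::summarise(
          mean_genes = mean(.data$mean_genes),
          mean_variants = mean(.data$mean_variants),
          n_genomes = sum(.data$n_genomes),
          max_genes = max(.data$max_genes),
          min_genes = min(.data$min_genes),
          .groups = "drop"
        )
    }
    out <- cur
  }
  dplyr::mutate(out, taxon = .data[[rank]], rank = rank, .before = 1)
}

#' Copy-number summary table across all eight ranks
#'
#' Convenience wrapper producing the nested per-rank means (and strain
#' ranges) for every taxon, one rank per block.
#'
#' @inheritParams aggregate_redundancy
#' @return Tibble stacking [aggregate_redundancy()] over the eight ranks.
#' @export
redundancy_table <- function(stats, method = "mean_of_means") {
  purrr::map_dfr(TAXONOMY_RANKS, function(r) {
    aggregate_redundancy(stats, r, method = method) |>
      dplyr::select(dplyr::any_of(c(
        "rank", "taxon", "mean_genes", "mean_variants",
        "n_genomes", "max_genes", "min_genes"
      )))
  })
}

band_label <- function(x, edges) {
  dplyr::case_when(
    x <= edges[1] ~ sprintf("==%g", edges[1]),
    x <= edges[2] ~ sprintf("%g-%g", edges[1] + 1, edges[2]),
    TRUE ~ sprintf(">%g", edges[2])
  )
}

#' Banded copy-number spectrum over species
#'
#' Tallies species into copy-number bands (default edges 1 and 6: exactly
#' one gene, two to six, seven or more; archaeal communities typically use
#' `edges = c(1, 3)`). Both the species-mean and the species-maximum
#' statistic are tallied, labelled in the `statistic` column. Percentages
#' are over the total species count, rounded half-up to 2 decimals.
#'
#' @param stats Per-unit table from [summarize_genomes()].
#' @param edges Two band edges (default `c(1, 6)`).
#' @param value Count to band: `"genes"` (default) or `"variants"`.
#' @return Tibble: `statistic`, `band`, `n_species`, `pct`, plus a
#'   `pct_more_than_one` attribute-free summary row set.
#' @export
copy_number_spectrum <- function(stats, edges = c(1, 6), value = c("genes", "variants")) {
  value <- match.arg(value)
  col <- if (value == "genes") "n_genes" else "n_variants"
  sp <- stats |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      mean = mean(.data[[col]]),
      max = max(.data[[col]]),
      .groups = "drop"
    )
  total <- nrow(sp)
  purrr::map_dfr(c("mean", "max"), function(stat) {
    lab <- band_label(sp[[stat]], edges)
    lvls <- c(sprintf("==%g", edges[1]),
              sprintf("%g-%g", edges[1] + 1, edges[2]),
              sprintf(">%g", edges[2]))
    tab <- table(factor(lab, levels = lvls))
    tibble(
      statistic = stat,
      band = names(tab),
      n_species = as.integer(tab),
      pct = round_half_up(as.integer(tab) / total * 100, 2)
    )
  })
}

#' Percentage of species with more than one gene per genome
#'
#' @param stats Per-unit table from [summarize_genomes()].
#' @param value `"genes"` or `"variants"`.
#' @return Percentage (species whose mean count exceeds 1), 2 decimals.
#' @export
pct_multi_copy_species <- function(stats, value = "genes") {
  col <- if (value == "genes") "n_genes" else "n_variants"
  sp <- stats |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(mean = mean(.data[[col]]), .groups = "drop")
  round_half_up(sum(sp$mean > 1) / nrow(sp) * 100, 2)
}
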