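make_stats <- function(n_genes, species, genome_prefix = "g",
                       superkingdom = "Bacteria", phylum = "Firmicutes",
                       genus = NULL, n_variants = NULL) {
  genus <- genus %||% vapply(strsplit(species, " "), `[[`, character(1), 1)
  n_variants <- n_variants %||% rep(1L, length(n_genes))
  tibble::tibble(
    unit_id = paste0(genome_prefix, seq_along(n_genes), "_1"),
    genome_id = paste0(genome_prefix, seq_along(n_genes)),
    superkingdom = superkingdom, phylum = phylum, class = "C", order = "O",
    family = "F", genus = genus, species = species,
    strain = paste0(species, " str", seq_along(n_genes)),
    genome_length = 100000L,
    n_genes = as.integer(n_genes), n_variants = as.integer(n_variants),
    n_plus_strand = as.integer(n_genes), n_minus_strand = 0L,
    mean_gene_length = 1500
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("variant counting is exact string identity, order-invariant", {
  expect_equal(count_variants(c("S", "S", "S", "S")), 1L)
  expect_equal(count_variants(c("S", "S", "T")), 2L)
  expect_equal(count_variants(character(0)), 0L)
  expect_equal(count_variants(c("AC", "ACG")), 2L)  # length difference counts
  set.seed(1)
  seqs <- sample(c("A", "B", "C"), 30, replace = TRUE)
  expect_equal(count_variants(seqs), count_variants(rev(seqs)))
})

test_that("per-unit summaries count genes, variants and strands", {
  units <- tibble::tibble(
    unit_id = "u1", genome_id = "g1",
    superkingdom = "Bacteria", phylum = "P", class = "C", order = "O",
    family = "F", genus = "G", species = "G s", strain = "G s",
    sequence = strrep("ACGT", 100), length_bp = 400L
  )
  hits <- tibble::tibble(
    unit_id = "u1", gene_index = 1:5,
    sequence = c("AAA", "AAA", "AAA", "CCC", "GGG"),
    strand = c("+", "+", "+", "-", "-")
  )
  st <- summarize_genomes(hits, units)
  expect_equal(st$n_genes, 5L)
  expect_equal(st$n_variants, 3L)
  expect_equal(st$n_plus_strand, 3L)
  expect_equal(st$n_minus_strand, 2L)
  # 11 identical copies
  h11 <- tibble::tibble(unit_id = "u1", gene_index = 1:11,
                        sequence = rep("AAA", 11), strand = "+")
  expect_equal(summarize_genomes(h11, units)$n_variants, 1L)
  expect_error(summarize_genomes(dplyr::mutate(hits, unit_id = "zz"), units),
               "unknown unit")
})

test_that("species means average over genome units (five 11s and one 10 give 10.83)", {
  st <- make_stats(c(11, 11, 11, 11, 11, 10), rep("Bacillus anthracis", 6))
  agg <- aggregate_redundancy(st, "species")
  expect_equal(round(agg$mean_genes, 2), 10.83)
  expect_equal(agg$mean_genes, 65 / 6)
})

test_that("higher ranks use mean-of-child-means; strain level reports raw ranges", {
  st <- dplyr::bind_rows(
    make_stats(c(2, 2), rep("Alpha one", 2), genome_prefix = "a", genus = "Shared"),
    make_stats(4, "Alpha two", genome_prefix = "b", genus = "Shared")
  )
  gen <- aggregate_redundancy(st, "genus")
  expect_equal(gen$mean_genes, 3)  # mean of species means 2 and 4
  pooled <- aggregate_redundancy(st, "genus", method = "pooled")
  expect_equal(pooled$mean_genes, (2 + 2 + 4) / 3)

  st2 <- make_stats(c(5, 1), rep("Beta uno", 2))
  strain_lvl <- aggregate_redundancy(st2, "strain")
  phylum_lvl <- aggregate_redundancy(st2, "phylum")
  expect_equal(max(strain_lvl$max_genes), 5L)
  expect_equal(min(strain_lvl$min_genes), 1L)
  expect_equal(c(phylum_lvl$max_genes, phylum_lvl$min_genes), c(5L, 1L))
})

test_that("banded spectra reproduce the multi-copy percentages", {
  # 186 bacterial species, 11 with mean one gene
  st <- make_stats(
    c(rep(1, 11), rep(3, 159), rep(8, 16)),
    sprintf("Bacterium sp%03d", 1:186)
  )
  expect_equal(pct_multi_copy_species(st), 94.09)
  spec <- copy_number_spectrum(st, edges = c(1, 6))
  mean_rows <- spec[spec$statistic == "mean", ]
  expect_equal(mean_rows$n_species, c(11L, 159L, 16L))
  expect_equal(mean_rows$pct, c(5.91, 85.48, 8.6))

  # 135 archaeal species, 64 with one gene
  st_a <- make_stats(
    c(rep(1, 64), rep(2, 67), rep(4, 4)),
    sprintf("Archaeon sp%03d", 1:135), superkingdom = "Archaea"
  )
  expect_equal(pct_multi_copy_species(st_a), 52.59)
  spec_a <- copy_number_spectrum(st_a, edges = c(1, 3))
  expect_equal(spec_a$n_species[spec_a$statistic == "mean"], c(64L, 67L, 4L))

  st_one <- make_stats(rep(1, 5), sprintf("Solo sp%d", 1:5))
  expect_equal(pct_multi_copy_species(st_one), 0)
})

test_that("permuting unit order leaves every statistic unchanged", {
  st <- make_stats(c(3, 1, 7, 2), sprintf("Mix sp%d", c(1, 1, 2, 2)))
  shuffled <- st[c(4, 2, 1, 3), ]
  a <- dplyr::arrange(aggregate_redundancy(st, "species"), taxon)
  b <- dplyr::arrange(aggregate_redundancy(shuffled, "species"), taxon)
  expect_equal(as.data.frame(a), as.data.frame(b))
})
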