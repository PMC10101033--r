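amp_row <- function(species, unit_id, seqs, pair_id = "p1") {
  tibble::tibble(
    pair_id = pair_id, unit_id = unit_id,
    gene_index = seq_along(seqs), species = species,
    sequence = seqs, length_bp = nchar(seqs)
  )
}

test_that("MA groups require identical sequences from different species", {
  amps <- dplyr::bind_rows(
    amp_row("Alpha one", "a1_1", c("AAAA", "CCCC")),
    amp_row("Beta two", "b1_1", c("AAAA", "GGGG"))
  )
  groups <- find_ma_groups(amps)
  expect_equal(nrow(groups), 1L)
  expect_equal(groups$sequence, "AAAA")
  expect_equal(groups$n_species, 2L)
  expect_setequal(ma_species(groups)$species, c("Alpha one", "Beta two"))

  # intragenomic redundancy alone never forms a group
  solo <- amp_row("Alpha one", "a1_1", rep("TTTT", 4))
  expect_equal(nrow(find_ma_groups(solo)), 0L)

  # strains of one species sharing an amplicon are not an MA
  strains <- dplyr::bind_rows(
    amp_row("Alpha one", "a1_1", "TTTT"),
    amp_row("Alpha one", "a2_1", "TTTT")
  )
  expect_equal(nrow(find_ma_groups(strains)), 0L)
})

test_that("MA grouping matches brute-force pairwise comparison", {
  amps <- dplyr::bind_rows(
    amp_row("A sp", "a1", c("SSSS", "XXXX")),
    amp_row("B sp", "b1", "SSSS"),
    amp_row("C sp", "c1", "SSSS"),
    amp_row("D sp", "d1", "TTTT"),
    amp_row("E sp", "e1", c("TTTT", "YYYY"))
  )
  groups <- find_ma_groups(amps)
  expect_equal(nrow(groups), 2L)
  expect_equal(nrow(ma_species(groups)), 5L)

  # O(n^2) oracle: a species is flagged iff some other species shares a string
  flagged_oracle <- unique(unlist(lapply(unique(amps$species), function(s) {
    own <- amps$sequence[amps$species == s]
    other <- amps$sequence[amps$species != s]
    if (any(own %in% other)) s else NULL
  })))
  expect_setequal(ma_species(groups)$species, flagged_oracle)
})

test_that("SC-NMA reproduces the published worked values", {
  expect_equal(sc_nma(180, 6, 186), 93.55)
  expect_equal(sc_nma(127, 6, 135), 89.63)
  expect_equal(sc_nma(0, 0, 186), 0)
  expect_equal(sc_nma_overall(180, 6, 186, 129, 6, 135), 92.52)
  expect_equal(sc_nma_overall(176, 28, 186, 86, 20, 135), 66.67)
  expect_error(sc_nma(10, 12, 186), "<=")
  expect_error(sc_nma(10, 2, 0), "positive")
})

test_that("overestimation factors satisfy the stated anchors", {
  # species with 4 copies and no MAs
  amps <- amp_row("Alpha one", "a1_1", rep("QQQQ", 4))
  ofs <- overestimation_factors(amps)
  expect_equal(ofs$of, 4)
  expect_equal(ofs$of_ma, 1)

  # A: 2 copies, B: 3 copies, one shared sequence covering all copies
  shared <- dplyr::bind_rows(
    amp_row("A sp", "a1", rep("SSSS", 2)),
    amp_row("B sp", "b1", rep("SSSS", 3))
  )
  ofs2 <- overestimation_factors(shared)
  a <- ofs2[ofs2$species == "A sp", ]
  b <- ofs2[ofs2$species == "B sp", ]
  expect_equal(a$of, 5)
  expect_equal(a$of_ma, 2.5)
  expect_equal(b$of, 5)
  expect_equal(b$of_ma, 5 / 3)

  # MA-free pairs have mean OF-MA exactly 1; OF >= OF-MA when copies >= 1
  free <- dplyr::bind_rows(
    amp_row("A sp", "a1", rep("AAAA", 3)),
    amp_row("B sp", "b1", rep("CCCC", 2))
  )
  ofs3 <- overestimation_factors(free)
  expect_equal(mean(ofs3$of_ma), 1)
  expect_true(all(ofs3$of >= ofs3$of_ma))
  expect_error(
    overestimation_factors(dplyr::bind_rows(free,
                                            amp_row("C", "c1", "AA", pair_id = "p2"))),
    "single primer pair"
  )
})

test_that("per-pair evaluation wires counts, denominators and the overall row", {
  units <- tibble::tibble(
    unit_id = c("a1_1", "b1_1", "c1_1", "d1_1"),
    genome_id = c("a1", "b1", "c1", "d1"),
    superkingdom = c("Bacteria", "Bacteria", "Archaea", "Archaea"),
    species = c("A sp", "B sp", "C sp", "D sp")
  )
  pairs <- tibble::tibble(
    pair_id = "pp", fwd_seq = "ACGTACGTAC", rev_seq = "ACGTACGTAC",
    domain_scope = "both"
  )
  amps <- dplyr::bind_rows(
    amp_row("A sp", "a1_1", c("MMMM", "MMMM"), pair_id = "pp"),
    amp_row("B sp", "b1_1", "MMMM", pair_id = "pp"),
    amp_row("C sp", "c1_1", "ZZZZ", pair_id = "pp")
  )
  ev <- evaluate_primer_pairs(amps, units, pairs)
  bact <- ev[ev$domain == "bacteria", ]
  expect_equal(bact$n_species_detected, 2L)
  expect_equal(bact$n_species_ma, 2L)
  expect_equal(bact$sc_nma_count, 0L)
  expect_equal(bact$sc_nma_pct, 0)
  arch <- ev[ev$domain == "archaea", ]
  expect_equal(arch$n_species_detected, 1L)
  expect_equal(arch$n_species_ma, 0L)
  expect_equal(arch$of_ma_mean, 1)
  overall <- ev[ev$domain == "overall", ]
  expect_equal(overall$sc_nma_pct, sc_nma_overall(2, 2, 2, 1, 0, 2))
  # internal consistency: count column always equals detected - MA
  expect_equal(ev$sc_nma_count, ev$n_species_detected - ev$n_species_ma)
})

test_that("cross-primer tally thresholds species by number of flagging pairs", {
  flags <- dplyr::bind_rows(
    tibble::tibble(pair_id = sprintf("p%02d", 1:12), species = "Heavy sp"),
    tibble::tibble(pair_id = sprintf("p%02d", 1:9), species = "Light sp")
  )
  tally <- cross_primer_ma_tally(flags, threshold = 10)
  expect_true(tally$flagged[tally$species == "Heavy sp"])
  expect_false(tally$flagged[tally$species == "Light sp"])
  expect_equal(tally$n_pairs_with_ma, c(12L, 9L))
  all_in <- cross_primer_ma_tally(flags, threshold = 1)
  expect_true(all(all_in$flagged))
  mat <- attr(tally, "flag_matrix")
  expect_equal(nrow(mat), 2L)
})
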