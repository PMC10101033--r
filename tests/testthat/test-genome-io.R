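test_that("sanitization replaces ambiguity codes deterministically", {
  clean <- sanitize_sequence("ACGT", seed = 1)
  expect_equal(clean$sequence, "ACGT")
  expect_equal(clean$report$n_replaced, 0L)
  expect_false(clean$report$excluded)

  out <- sanitize_sequence("ARG", seed = 5)
  expect_true(out$sequence %in% c("AAG", "AGG"))
  expect_identical(out, sanitize_sequence("ARG", seed = 5))
  expect_identical(sanitize_sequence("arg", seed = 5)$sequence, out$sequence)

  # every chosen base must come from the code's expansion set
  s <- paste(rep("RYSWKMBDHVN", 4), collapse = "")
  rep5 <- sanitize_sequence(s, seed = 9)$report$replacements[[1]]
  for (i in seq_len(nrow(rep5))) {
    expect_true(rep5$chosen[i] %in% iupac_expand(rep5$original[i]))
  }
  expect_error(sanitize_sequence("ACGX", seed = 1), "non-IUPAC")
})

test_that("ambiguity runs beyond the threshold flag a unit for exclusion", {
  run11 <- paste0("A", strrep("N", 11), "G")
  expect_true(sanitize_sequence(run11, seed = 1)$report$excluded)
  run10 <- paste0("A", strrep("N", 10), "G")
  expect_false(sanitize_sequence(run10, seed = 1)$report$excluded)
  # mixed ambiguity codes count toward one run
  mixed <- paste0("A", strrep("RY", 6), "G")
  expect_true(sanitize_sequence(mixed, seed = 1)$report$excluded)
  expect_false(sanitize_sequence(run11, seed = 1, run_threshold = 12)$report$excluded)
})

test_that("sanitization preserves length and is idempotent on its output", {
  set.seed(3)
  for (i in 1:10) {
    s <- paste(sample(names(amplimatch:::IUPAC_SETS), 200, replace = TRUE),
               collapse = "")
    out <- sanitize_sequence(s, seed = i, run_threshold = 1000)
    expect_equal(nchar(out$sequence), nchar(s))
    again <- sanitize_sequence(out$sequence, seed = i + 1)
    expect_identical(again$sequence, out$sequence)
    expect_equal(again$report$n_replaced, 0L)
  }
})

test_that("taxonomy parsing enforces ranks, uniqueness and strain fallback", {
  tax <- dplyr::bind_rows(
    tax_row("g1", "Streptococcus mutans", strain = "UA159"),
    tax_row("g2", "Xylella yonderi", strain = NA)
  )
  parsed <- read_taxonomy(tax)
  expect_equal(parsed$strain, c("UA159", "Xylella yonderi"))

  expect_error(read_taxonomy(dplyr::bind_rows(tax_row("g1"), tax_row("g1"))),
               "duplicate genome_id")
  expect_error(read_taxonomy(tax[, setdiff(names(tax), "order")]),
               "missing column")
})

test_that("chromosome splitting reproduces the per-genome unit arithmetic", {
  # 497 one-chromosome + 9 two-chromosome + 1 three-chromosome -> 518 units
  make_geno <- function(counts) {
    purrr::map_dfr(seq_along(counts), function(i) {
      tibble::tibble(
        genome_id = sprintf("g%03d", i),
        chrom_id = paste0("c", seq_len(counts[i])),
        sequence = strrep("ACGT", 5)
      )
    })
  }
  counts_b <- c(rep(1, 497), rep(2, 9), 3)
  tax <- purrr::map_dfr(seq_along(counts_b), function(i) {
    tax_row(sprintf("g%03d", i), sprintf("Species sp%03d", i))
  })
  units <- split_units(make_geno(counts_b), tax, seed = 1)
  expect_equal(nrow(units), 518L)

  counts_a <- c(rep(1, 166), rep(2, 10), 5)
  tax_a <- purrr::map_dfr(seq_along(counts_a), function(i) {
    tax_row(sprintf("g%03d", i), sprintf("Archaeon sp%03d", i),
            superkingdom = "Archaea")
  })
  expect_equal(nrow(split_units(make_geno(counts_a), tax_a, seed = 1)), 191L)
})

test_that("excluded chromosomes drop out while their parent genome survives", {
  genomes <- tibble::tibble(
    genome_id = c("g1", "g1", "g2"),
    chrom_id = c("c1", "c2", "c1"),
    sequence = c(strrep("ACGT", 10),
                 paste0("ACGT", strrep("N", 11), "ACGT"),
                 strrep("ACGT", 10))
  )
  tax <- dplyr::bind_rows(tax_row("g1", "Alpha one"), tax_row("g2", "Beta two"))
  units <- split_units(genomes, tax, seed = 2)
  expect_equal(nrow(units), 2L)
  expect_setequal(units$unit_id, c("g1_1", "g2_1"))
  rep_tbl <- sanitization_report(units)
  expect_equal(nrow(rep_tbl), 3L)
  expect_equal(sum(rep_tbl$excluded), 1L)
  # genome whose only chromosome is excluded yields zero units
  solo <- tibble::tibble(genome_id = "g3", chrom_id = "c1",
                         sequence = strrep("N", 20))
  expect_equal(nrow(split_units(solo, tax_row("g3", "Gamma three"), seed = 1)), 0L)
})

test_that("unit lengths are conserved and runs are seed-reproducible", {
  genomes <- tibble::tibble(
    genome_id = "g1", chrom_id = c("c1", "c2"),
    sequence = c("ACGTRYACGTACGT", "GGGTACGTNACGT")
  )
  tax <- tax_row("g1", "Alpha one")
  u1 <- split_units(genomes, tax, seed = 10)
  u2 <- split_units(genomes, tax, seed = 10)
  expect_identical(u1$sequence, u2$sequence)
  expect_equal(sum(u1$length_bp), sum(nchar(genomes$sequence)))
  u3 <- split_units(genomes, tax, seed = 11)
  expect_equal(nchar(u3$sequence), nchar(u1$sequence))
})
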