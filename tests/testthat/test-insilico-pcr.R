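template <- synthetic_16s_template()
pairs <- read_primer_pairs()

test_that("amplification spans leftmost forward to rightmost reverse site", {
  set.seed(21)
  fwd <- "TACGGRAGGCAGCAG"
  rev <- "TCACRRCACGAGCTGWCGAC"
  interior <- random_subject(120)
  gene <- paste0(random_subject(40), "TACGGAAGGCAGCAG", interior,
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString("TCACGACACGAGCTGACGAC"))),
                 random_subject(30))
  amp <- amplify_gene(gene, fwd, rev)
  expect_equal(amp$fwd_start, 40L)
  expect_equal(amp$length_bp, 15 + 120 + 20)
  expect_equal(amp$sequence, substr(gene, 41, 40 + amp$length_bp))

  # gene lacking the reverse site
  expect_null(amplify_gene(paste0(random_subject(40), "TACGGAAGGCAGCAG",
                                  random_subject(60)), fwd, rev))
  # forward site present twice: leftmost used, amplicon maximal
  gene2 <- paste0("TACGGAAGGCAGCAG", random_subject(50), "TACGGGAGGCAGCAG",
                  random_subject(50),
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString("TCACGACACGAGCTGACGAC"))))
  amp2 <- amplify_gene(gene2, fwd, rev)
  expect_equal(amp2$fwd_start, 0L)
  expect_equal(amp2$rev_end, nchar(gene2))
})

test_that("every bundled pair amplifies the synthetic template at its planted window", {
  genes <- tibble::tibble(unit_id = "u1", gene_index = 1L, sequence = template)
  amps <- amplify(genes, pairs)
  expect_equal(nrow(amps), nrow(pairs))
  m <- dplyr::left_join(amps, pairs, by = "pair_id")
  expect_equal(m$fwd_start, m$template_f_first - 1L)
  expect_equal(m$rev_end, m$template_r_last)
})

test_that("reverse-complementing the gene and swapping primer roles mirrors the amplicon", {
  set.seed(22)
  for (i in 1:10) {
    row <- pairs[sample(nrow(pairs), 1), ]
    gene <- template
    amp <- amplify_gene(gene, row$fwd_seq, row$rev_seq)
    rc_gene <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene)))
    amp_rc <- amplify_gene(rc_gene, row$rev_seq, row$fwd_seq)
    expect_false(is.null(amp_rc))
    expect_equal(
      amp_rc$sequence,
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(amp$sequence)))
    )
  }
})

test_that("per-unit amplicon and variant counts respect gene structure", {
  g4 <- tibble::tibble(unit_id = "u1", gene_index = 1:4, sequence = rep(template, 4))
  counts <- amplicon_counts(amplify(g4, pairs[pairs$pair_id == "KP_F048-OP_R030", ]))
  expect_equal(counts$n_amplicons, 4L)
  expect_equal(counts$n_amplicon_variants, 1L)

  # genes differing only outside the amplified window: one amplicon variant
  outside <- template
  substr(outside, 1200, 1200) <- chartr("ACGT", "CGTA", substr(outside, 1200, 1200))
  g2 <- tibble::tibble(unit_id = "u1", gene_index = 1:2,
                       sequence = c(template, outside))
  short_pair <- pairs[pairs$pair_id == "OP_F066-OP_R073", ]  # window 784-893
  counts2 <- amplicon_counts(amplify(g2, short_pair))
  expect_equal(counts2$n_amplicons, 2L)
  expect_equal(counts2$n_amplicon_variants, 1L)
  expect_equal(count_variants(g2$sequence), 2L)
})

test_that("reference positioning reports unique matches or U", {
  loc <- locate_on_reference("TACGGRAGGCAGCAG", template, "forward")
  expect_equal(c(loc$first, loc$last), c(342L, 356L))
  # reverse primer located via reverse complement on forward coordinates
  loc_r <- locate_on_reference("TCACRRCACGAGCTGWCGAC", template, "reverse")
  expect_equal(c(loc_r$first, loc_r$last), c(1060L, 1079L))
  expect_equal(locate_on_reference(strrep("AC", 10), template)$status, "U")
  expect_equal(locate_on_reference(substr(template, 1, 15), template)$first, 1L)
  expect_error(locate_on_reference("N", paste0("AA", "CC"), "forward"), "ambiguous")

  tab <- locate_pairs_on_reference(pairs[pairs$pair_id == "KP_F048-OP_R030", ])
  expect_equal(tab$f_first, "342")
  expect_equal(tab$r_last, "1079")
  expect_equal(tab$span_printed, 737L)
  expect_equal(tab$span_inclusive, 738L)
})

test_that("span convention and length categories match the reporting rules", {
  expect_equal(paper_span_length(342, 1079), 737L)
  expect_equal(paper_span_length(342, 529), 187L)
  expect_equal(paper_span_length(5, 5), 0L)
  expect_error(paper_span_length(10, 9), "precedes")

  expect_equal(classify_length_category(733), "L")
  expect_equal(classify_length_category(c(300, 301, 600, 601)),
               c("S", "M", "M", "L"))
  expect_equal(classify_length_category(c(50, 100)), c("undersized", "S"))
})
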