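#' Amplify one gene with one degenerate primer pair
#'
#' The forward primer is matched as given on the sense gene sequence; the
#' reverse primer is matched as its IUPAC reverse complement. The amplicon
#' runs from the first base of the leftmost forward match to the last base
#' of the rightmost reverse match (both primer-binding sites included),
#' maximizing the amplified span. Matching is exact: no mismatches are
#' tolerated at any primer position.
#'
#' @param gene_seq Sense-oriented gene sequence (A/C/G/T).
#' @param fwd,rev Primer sequences 5'->3' (IUPAC), or precompiled
#'   [iupac_pattern()] objects (`rev` must then be compiled from the reverse
#'   complement already — prefer passing strings unless in a tight loop).
#' @return `NULL` if either primer has no match or the reverse site does not
#'   end beyond the forward start, else a list with `fwd_start`, `rev_end`
#'   (0-based half-open on the gene), `sequence`, `length_bp`.
#' @export
amplify_gene <- function(gene_seq, fwd, rev) {
  fpat <- if (inherits(fwd, "iupac_pattern")) fwd else iupac_pattern(fwd)
  rpat <- if (inherits(rev, "iupac_pattern")) rev else iupac_pattern(iupac_revcomp(rev))
  fhits <- match_primer(gene_seq, fpat)
  if (length(fhits) == 0) return(NULL)
  rhits <- match_primer(gene_seq, rpat)
  if (length(rhits) == 0) return(NULL)
  f0 <- fhits[1] - 1L                          # leftmost forward, 0-based
  rend0 <- max(rhits) + rpat$width - 1L        # rightmost reverse end, half-open
  if (rend0 <= f0) return(NULL)
  list(
    fwd_start = as.integer(f0),
    rev_end = as.integer(rend0),
    sequence = substr(gene_seq, f0 + 1L, rend0),
    length_bp = as.integer(rend0 - f0)
  )
}

#' In silico PCR of all genes against all primer pairs
#'
#' One amplicon at most per gene per pair. Species provenance is joined in
#' when `units` is supplied.
#'
#' @param genes Gene tibble (`unit_id`, `gene_index`, `sequence`) from
#'   [extract_genes()] or [read_genes_fasta()].
#' @param pairs Primer table from [read_primer_pairs()].
#' @param units Optional unit tibble to annotate `species` and
#'   `superkingdom`.
#' @return Amplicon tibble: `pair_id`, `unit_id`, `gene_index`,
#'   `fwd_start`, `rev_end` (0-based half-open on the gene), `length_bp`,
#'   `sequence` (+ `species`, `superkingdom` when units are given).
#' @export
amplify <- function(genes, pairs, units = NULL) {
  out <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    fpat <- iupac_pattern(pairs$fwd_seq[i])
    rpat <- iupac_pattern(iupac_revcomp(pairs$rev_seq[i]))
    amps <- purrr::map(genes$sequence, amplify_gene, fwd = fpat, rev = rpat)
    keep <- !vapply(amps, is.null, logical(1))
    if (!any(keep)) return(NULL)
    dplyr::bind_cols(
      tibble(
        pair_id = pairs$pair_id[i],
        unit_id = genes$unit_id[keep],
        gene_index = genes$gene_index[keep]
      ),
      purrr::map_dfr(amps[keep], ~ tibble(
        fwd_start = .x$fwd_start, rev_end = .x$rev_end,
        length_bp = .x$length_bp, sequence = .x$sequence
      ))
    )
  })
  if (!is.null(units) && nrow(out) > 0) {
    out <- dplyr::left_join(
      out,
      dplyr::select(units, dplyr::all_of(c("unit_id", "species", "superkingdom"))),
      by = "unit_id"
    )
  }
  out
}

#' Per-pair per-unit amplicon counts
#'
#' @param amplicons Output of [amplify()].
#' @return Tibble: `pair_id`, `unit_id`, `n_amplicons`,
#'   `n_amplicon_variants` (distinct amplicon sequences on the unit).
#' @export
amplicon_counts <- function(amplicons) {
  amplicons |>
    dplyr::group_by(.data$pair_id, .data$unit_id) |>
    dplyr::summarise(
      n_amplicons = dplyr::n(),
      n_amplicon_variants = count_variants(.data$sequence),
      .groups = "drop"
    )
}

#' Locate one primer on a reference gene
#'
#' Forward primers are matched as given; reverse primers via their reverse
#' complement, with positions reported on the reference's forward
#' coordinates. Positions are 1-based inclusive. Zero matches yield `"U"`
#' (unaligned); more than one match is an ambiguity error, reported rather
#' than silently resolved.
#'
#' @param primer IUPAC primer string.
#' @param reference Reference gene sequence (plain bases).
#' @param direction `"forward"` or `"reverse"`.
#' @return List with `first`, `last` (integers) and `status` (`"aligned"`)
#'   or `first = last = NA` with `status = "U"`.
#' @export
locate_on_reference <- function(primer, reference, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  query <- if (direction == "reverse") iupac_revcomp(primer) else toupper(primer)
  hits <- match_primer(reference, query)
  if (length(hits) == 0) {
    return(list(first = NA_integer_, last = NA_integer_, status = "U"))
  }
  if (length(hits) > 1) {
    abort(sprintf("primer %s matches the reference at %d positions (%s): ambiguous placement",
                  primer, length(hits), paste(hits, collapse = ", ")))
  }
  list(first = hits, last = hits + nchar(query) - 1L, status = "aligned")
}

#' Locate every primer pair on a reference gene
#'
#' @param pairs Primer table.
#' @param reference Reference gene sequence (defaults to the bundled
#'   synthetic 16S template).
#' @return Tibble: `pair_id`, `f_first`, `f_last`, `r_first`, `r_last`
#'   (character; `"U"` where unaligned), `span_printed` (the reporting
#'   convention, reverse last minus forward first) and `span_inclusive`
#'   (true base count, one more).
#' @export
locate_pairs_on_reference <- function(pairs, reference = synthetic_16s_template()) {
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    f <- locate_on_reference(pairs$fwd_seq[i], reference, "forward")
    r <- locate_on_reference(pairs$rev_seq[i], reference, "reverse")
    aligned <- f$status == "aligned" && r$status == "aligned"
    tibble(
      pair_id = pairs$pair_id[i],
      f_first = if (f$status == "U") "U" else as.character(f$first),
      f_last = if (f$status == "U") "U" else as.character(f$last),
      r_first = if (r$status == "U") "U" else as.character(r$first),
      r_last = if (r$status == "U") "U" else as.character(r$last),
      span_printed = if (aligned) paper_span_length(f$first, r$last) else NA_integer_,
      span_inclusive = if (aligned) r$last - f$first + 1L else NA_integer_
    )
  })
}

#' Reported amplicon span between reference positions
#'
#' The reporting convention for the span between a forward primer's first
#' base and a reverse primer's last base (both 1-based inclusive) is their
#' difference, `r_last - f_first`. Note this is one less than the inclusive
#' base count; the convention is kept because it reproduces the published
#' per-pair length values exactly.
#'
#' @param f_first Forward primer first position (1-based).
#' @param r_last Reverse primer last position (1-based).
#' @return Integer span(s), `r_last - f_first`.
#' @export
paper_span_length <- function(f_first, r_last) {
  if (any(r_last < f_first)) {
    abort("reverse-primer last position precedes forward-primer first position")
  }
  as.integer(r_last - f_first)
}

#' Amplicon length category from a pair's mean amplicon length
#'
#' S for 100-300 bp, M for 301-600 bp, L for more than 600 bp; means below
#' 100 bp fall outside the published bands and are labelled `"undersized"`.
#'
#' @param mean_len Numeric vector of mean amplicon lengths.
#' @return Character vector over `{"S", "M", "L", "undersized"}`.
#' @export
classify_length_category <- function(mean_len) {
  dplyr::case_when(
    mean_len < 100 ~ "undersized",
    mean_len <= 300 ~ "S",
    mean_len <= 600 ~ "M",
    TRUE ~ "L"
  )
}
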