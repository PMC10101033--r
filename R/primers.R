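#' Read a primer-pair table
#'
#' With no argument, loads the primer catalogue bundled with the package:
#' 39 IUPAC-degenerate pairs targeting bacteria, archaea or both, each with
#' its printed reference-gene positions (`ecoli_*`; `"U"` where the primer
#' does not align to the reference) and its position on the package's
#' synthetic 16S template (`template_*`).
#'
#' @param path Optional TSV path with at least `pair_id`, `fwd_id`,
#'   `fwd_seq`, `rev_id`, `rev_seq`, `domain_scope`.
#' @return Tibble of primer pairs.
#' @export
read_primer_pairs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "primer_pairs.tsv", package = "amplimatch")
  }
  pp <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character(),
    most_used = readr::col_logical(),
    length_printed = readr::col_double(),
    template_f_first = readr::col_integer(),
    template_f_last = readr::col_integer(),
    template_r_first = readr::col_integer(),
    template_r_last = readr::col_integer()
  ), progress = FALSE)
  need <- c("pair_id", "fwd_id", "fwd_seq", "rev_id", "rev_seq", "domain_scope")
  missing_cols <- setdiff(need, names(pp))
  if (length(missing_cols) > 0) {
    abort(sprintf("primer table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  for (s in c(pp$fwd_seq, pp$rev_seq)) check_iupac(s, "primer")
  bad_len <- nchar(pp$fwd_seq) < 10 | nchar(pp$fwd_seq) > 30 |
    nchar(pp$rev_seq) < 10 | nchar(pp$rev_seq) > 30
  if (any(bad_len)) {
    abort(sprintf("primer lengths outside 10-30 nt for pair %s",
                  pp$pair_id[which(bad_len)[1]]))
  }
  pp
}

# Template geometry: a synthetic full-length 16S-like gene. Every bundled
# primer pair has an exactly matching binding site planted at template_*
# coordinates; free positions are filled i.i.d. from ACGT under a fixed
# internal seed so the template is a reproducible package constant.
TEMPLATE_LENGTH <- 1550L
TEMPLATE_SEED <- 163L

#' Synthetic full-length 16S rRNA gene template
#'
#' A 1,550-nt synthetic sequence (NOT a real organismal 16S gene) carrying
#' exact binding sites for all 39 bundled primer pairs at coordinates that
#' mimic their positions on the *E. coli* reference where those are defined.
#' The template is solved by intersecting the IUPAC constraints of every
#' planted site (forward primers as given, reverse primers as their reverse
#' complements) and drawing the remaining free positions uniformly from
#' A/C/G/T under a fixed seed, so repeated calls return the same string.
#'
#' @param primer_pairs Primer table ([read_primer_pairs()]); defaults to the
#'   bundled catalogue.
#' @return Single DNA string of length 1,550.
#' @export
synthetic_16s_template <- function(primer_pairs = read_primer_pairs()) {
  pp <- primer_pairs
  constraints <- vector("list", TEMPLATE_LENGTH)
  add_constraint <- function(constraints, seq, first) {
    chars <- check_iupac(seq, "primer")
    for (j in seq_along(chars)) {
      pos <- first + j - 1L
      set <- IUPAC_SETS[[chars[j]]]
      cur <- constraints[[pos]]
      constraints[[pos]] <- if (is.null(cur)) set else intersect(cur, set)
      if (length(constraints[[pos]]) == 0) {
        abort(sprintf("inconsistent primer-site constraints at template position %d", pos))
      }
    }
    constraints
  }
  for (i in seq_len(nrow(pp))) {
    constraints <- add_constraint(constraints, pp$fwd_seq[i], pp$template_f_first[i])
    constraints <- add_constraint(constraints, iupac_revcomp(pp$rev_seq[i]),
                                  pp$template_r_first[i])
  }
  with_seed(TEMPLATE_SEED, {
    bases <- vapply(seq_len(TEMPLATE_LENGTH), function(pos) {
      set <- constraints[[pos]] %||% c("A", "C", "G", "T")
      set[sample.int(length(set), 1L)]
    }, character(1))
    paste(bases, collapse = "")
  })
}

# 1-based inclusive windows on the template that simulated divergence must
# never touch: every planted primer site plus the conserved terminal motifs
# the gene finder anchors on.
template_protected_windows <- function(primer_pairs = read_primer_pairs(),
                                       terminal = 25L) {
  pp <- primer_pairs
  win <- dplyr::bind_rows(
    tibble(first = pp$template_f_first, last = pp$template_f_last),
    tibble(first = pp$template_r_first, last = pp$template_r_last),
    tibble(first = c(1L, TEMPLATE_LENGTH - terminal + 1L),
           last = c(terminal, TEMPLATE_LENGTH))
  )
  dplyr::distinct(win)
}

protected_mask <- function(windows, len = TEMPLATE_LENGTH) {
  mask <- logical(len)
  for (i in seq_len(nrow(windows))) {
    mask[windows$first[i]:windows$last[i]] <- TRUE
  }
  mask
}
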