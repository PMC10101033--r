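#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# IUPAC nucleotide alphabet: each code maps to the set of plain bases it
# stands for. Order inside each set is fixed (alphabetical) so that seeded
# random replacement is reproducible across platforms.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code Single IUPAC character (case-insensitive).
#' @return Character vector of the plain bases (`A`/`C`/`G`/`T`) the code
#'   stands for.
#' @examples
#' iupac_expand("R")
#' @export
iupac_expand <- function(code) {
  code <- toupper(code)
  if (!code %in% names(IUPAC_SETS)) {
    abort(sprintf("'%s' is not an IUPAC nucleotide code", code))
  }
  IUPAC_SETS[[code]]
}

check_iupac <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s contains non-IUPAC character '%s' at position %d",
      what, chars[bad[1]], bad[1]
    ))
  }
  chars
}

#' Reverse complement of an IUPAC (possibly degenerate) DNA sequence
#'
#' Ambiguity codes are complemented set-wise (R <-> Y, K <-> M, ...), so the
#' reverse complement of a degenerate primer matches exactly the reverse
#' complements of the sequences the primer matches.
#'
#' @param seq Character vector of DNA sequences (IUPAC alphabet).
#' @return Character vector of reverse complements, uppercase.
#' @export
iupac_revcomp <- function(seq) {
  vapply(seq, function(s) {
    chars <- check_iupac(s)
    paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Degeneracy of an IUPAC primer
#'
#' The number of plain-base sequences in the Cartesian product of the
#' per-position expansion sets.
#'
#' @param primer IUPAC DNA string.
#' @return Integer degeneracy (product of per-position set sizes).
#' @examples
#' iupac_degeneracy("TCACRRCACGAGCTGWCGAC") # 8
#' @export
iupac_degeneracy <- function(primer) {
  chars <- check_iupac(primer, "primer")
  prod(vapply(chars, function(ch) length(IUPAC_SETS[[ch]]), numeric(1)))
}

#' Compile an IUPAC primer into an exact degenerate matcher
#'
#' Builds a PCRE pattern of per-position character classes. The matcher
#' accepts exactly the strings in the Cartesian product of the primer's
#' per-position base sets: zero mismatches are tolerated anywhere.
#'
#' @param primer IUPAC DNA string, 5'->3'.
#' @return An object of class `iupac_pattern` with elements `primer`,
#'   `regex`, `degeneracy` and `width`.
#' @export
iupac_pattern <- function(primer) {
  chars <- check_iupac(primer, "primer")
  classes <- vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  structure(
    list(
      primer = paste(chars, collapse = ""),
      regex = paste(classes, collapse = ""),
      degeneracy = prod(vapply(chars, function(ch) length(IUPAC_SETS[[ch]]), numeric(1))),
      width = length(chars)
    ),
    class = "iupac_pattern"
  )
}

#' @export
print.iupac_pattern <- function(x, ...) {
  cat(sprintf(
    "<iupac_pattern> %s (width %d, degeneracy %d)\n",
    x$primer, x$width, x$degeneracy
  ))
  invisible(x)
}

#' Find all exact degenerate matches of a primer in a plain-base subject
#'
#' Matches may overlap. The subject must be sanitized DNA (A/C/G/T only);
#' degenerate positions live in the primer, not the subject.
#'
#' @param subject Single DNA string over A/C/G/T.
#' @param primer IUPAC primer string or an [iupac_pattern()] object.
#' @return Integer vector of 1-based match start positions (possibly empty).
#' @export
match_primer <- function(subject, primer) {
  pat <- if (inherits(primer, "iupac_pattern")) primer else iupac_pattern(primer)
  subject <- toupper(subject)
  # lookahead capture gives overlapping match starts
  m <- gregexpr(paste0("(?=", pat$regex, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Brute-force per-offset IUPAC-set scanner. Intentionally naive: compares the
# expansion set of every primer position against the subject base at every
# offset. Serves as the independent oracle for match_primer() in the tests;
# never used by the pipeline itself.
#' Reference brute-force degenerate matcher
#'
#' Slides the primer along the subject and, at every offset, checks that each
#' subject base is a member of the corresponding primer position's IUPAC
#' expansion set. Quadratic and slow by design; used to cross-check the
#' compiled regex matcher.
#'
#' @inheritParams match_primer
#' @return Integer vector of 1-based match start positions.
#' @export
match_primer_bruteforce <- function(subject, primer) {
  pchars <- check_iupac(primer, "primer")
  schars <- strsplit(toupper(subject), "", fixed = TRUE)[[1]]
  np <- length(pchars)
  ns <- length(schars)
  if (np == 0 || ns < np) return(integer(0))
  sets <- lapply(pchars, function(ch) IUPAC_SETS[[ch]])
  hits <- integer(0)
  for (off in seq_len(ns - np + 1)) {
    ok <- TRUE
    for (j in seq_len(np)) {
      if (!schars[off + j - 1] %in% sets[[j]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# round half away from zero, the reporting convention for percentages
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

revcomp_plain <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
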