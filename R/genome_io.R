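#' The eight taxonomic ranks used throughout the package
#'
#' @format Character vector, from superkingdom down to strain.
#' @export
TAXONOMY_RANKS <- c(
  "superkingdom", "phylum", "class", "order",
  "family", "genus", "species", "strain"
)

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's random stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Read a taxonomy table
#'
#' Expects a TSV with a header containing `genome_id` plus the eight rank
#' columns (`superkingdom` ... `strain`). A missing or empty strain label
#' falls back to the species label, mirroring the convention of designating
#' at species level when no strain name exists.
#'
#' @param path Path to the TSV file, or a data frame already in memory.
#' @return A tibble with `genome_id` and the eight rank columns.
#' @export
read_taxonomy <- function(path) {
  tax <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  missing_cols <- setdiff(c("genome_id", TAXONOMY_RANKS), names(tax))
  if (length(missing_cols) > 0) {
    abort(sprintf("taxonomy table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  tax <- dplyr::select(tax, dplyr::all_of(c("genome_id", TAXONOMY_RANKS)))
  dup <- tax$genome_id[duplicated(tax$genome_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate genome_id in taxonomy table: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(tax$species) | tax$species == "")) {
    abort("taxonomy table has rows with an empty species label")
  }
  tax$strain <- dplyr::if_else(
    is.na(tax$strain) | tax$strain == "",
    tax$species, tax$strain
  )
  tax
}

#' Read genome sequences from a multi-record FASTA
#'
#' Record identifiers are `<genome_id><delim><chromosome_id>`; records
#' without the delimiter are treated as single-chromosome genomes whose
#' chromosome id equals the genome id.
#'
#' @param path FASTA file path.
#' @param delim Character separating genome id from chromosome id in record
#'   names (default `"|"`).
#' @return Tibble with columns `genome_id`, `chrom_id`, `sequence`.
#' @export
read_genomes <- function(path, delim = "|") {
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  parts <- stringr::str_split_fixed(ids, stringr::fixed(delim), 2)
  chrom <- ifelse(parts[, 2] == "", parts[, 1], parts[, 2])
  tibble(
    genome_id = parts[, 1],
    chrom_id = chrom,
    sequence = as.character(dss)
  )
}

#' Sanitize ambiguous IUPAC nucleotides in a genome sequence
#'
#' Every non-A/C/G/T IUPAC code is replaced by a uniformly random member of
#' its expansion set (e.g. `R` becomes `A` or `G`), deterministically under
#' `seed`. Sequences holding a run of more than `run_threshold` consecutive
#' ambiguous characters are flagged for exclusion from downstream analysis
#' (runs of exactly `run_threshold` are kept).
#'
#' @param seq Single DNA string over the IUPAC alphabet (case-insensitive).
#' @param seed Integer seed for the replacement draws.
#' @param run_threshold Maximum tolerated ambiguity-run length (default 10).
#' @return List with `sequence` (sanitized, uppercase, A/C/G/T only) and
#'   `report`, a one-row tibble with `n_replaced`, `max_ambiguity_run`,
#'   `excluded` and a `replacements` list-column (0-based `position`,
#'   `original`, `chosen`).
#' @export
sanitize_sequence <- function(seq, seed, run_threshold = 10) {
  chars <- check_iupac(seq)
  ambiguous <- !chars %in% c("A", "C", "G", "T")
  max_run <- 0L
  if (any(ambiguous)) {
    r <- rle(ambiguous)
    max_run <- max(r$lengths[r$values])
  }
  idx <- which(ambiguous)
  chosen <- character(length(idx))
  if (length(idx) > 0) {
    chosen <- with_seed(seed, {
      vapply(chars[idx], function(ch) {
        set <- IUPAC_SETS[[ch]]
        set[sample.int(length(set), 1L)]
      }, character(1), USE.NAMES = FALSE)
    })
    chars[idx] <- chosen
  }
  list(
    sequence = paste(chars, collapse = ""),
    report = tibble(
      n_replaced = length(idx),
      max_ambiguity_run = as.integer(max_run),
      excluded = max_run > run_threshold,
      replacements = list(tibble(
        position = idx - 1L,
        original = strsplit(toupper(seq), "", fixed = TRUE)[[1]][idx],
        chosen = chosen
      ))
    )
  )
}

#' Split genomes into per-chromosome analysis units
#'
#' Each chromosome becomes one analysis unit carrying the parent genome's
#' taxonomy. Sequences are sanitized ([sanitize_sequence()]) in sorted
#' unit-id order with a single base seed, and units whose ambiguity run
#' exceeds `run_threshold` are dropped (the parent genome survives through
#' its remaining units).
#'
#' @param genomes Tibble with `genome_id`, `chrom_id`, `sequence`
#'   (from [read_genomes()] or built in code).
#' @param taxonomy Tibble from [read_taxonomy()].
#' @param seed Integer seed driving ambiguity replacement.
#' @param run_threshold Passed to [sanitize_sequence()].
#' @return Tibble of units: `unit_id`, `genome_id`, the eight rank columns,
#'   `sequence`, `length_bp`. The per-unit sanitization report (including
#'   excluded units) is attached as attribute `"sanitization"` and can be
#'   retrieved with [sanitization_report()].
#' @export
split_units <- function(genomes, taxonomy, seed = 1L, run_threshold = 10) {
  if (nrow(genomes) == 0) abort("no genome sequences supplied")
  bad <- genomes$genome_id[is.na(genomes$sequence) | genomes$sequence == ""]
  if (length(bad) > 0) {
    abort(sprintf("genome '%s' has an empty sequence record", bad[1]))
  }
  unknown <- setdiff(unique(genomes$genome_id), taxonomy$genome_id)
  if (length(unknown) > 0) {
    abort(sprintf("genome_id not present in taxonomy: %s",
                  paste(unknown, collapse = ", ")))
  }
  units <- genomes |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::mutate(unit_id = paste0(.data$genome_id, "_", dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$unit_id)

  sanitized <- purrr::map2(units$sequence, seq_len(nrow(units)), function(s, i) {
    # one base seed, offset per unit in sorted order: machine-independent
    sanitize_sequence(s, seed = as.integer(seed) + i - 1L, run_threshold = run_threshold)
  })
  report <- purrr::map_dfr(sanitized, "report")
  report <- dplyr::bind_cols(
    tibble(unit_id = units$unit_id, genome_id = units$genome_id),
    report
  )
  units$sequence <- purrr::map_chr(sanitized, "sequence")
  units$length_bp <- nchar(units$sequence)
  keep <- !report$excluded
  out <- units[keep, ] |>
    dplyr::left_join(taxonomy, by = "genome_id") |>
    dplyr::select(dplyr::all_of(c(
      "unit_id", "genome_id", TAXONOMY_RANKS, "sequence", "length_bp"
    )))
  attr(out, "sanitization") <- report
  out
}

#' Retrieve the sanitization report attached by [split_units()]
#'
#' @param units Tibble returned by [split_units()].
#' @return Tibble with one row per input chromosome, excluded ones included.
#' @export
sanitization_report <- function(units) {
  rep <- attr(units, "sanitization", exact = TRUE)
  if (is.null(rep)) abort("no sanitization report attached to this table")
  rep
}
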