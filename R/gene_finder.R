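all_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1
  if (n < 1) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1)
}

# IUPAC consensus across equal-length sequences: per position, the smallest
# code covering the union of observed bases
iupac_consensus <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1)
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  code_of <- function(bases) {
    key <- paste(sort(unique(bases)), collapse = "")
    hit <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s) {
      paste(sort(s), collapse = "") == key
    }, logical(1))]
    hit[1]
  }
  paste(apply(mat, 2, code_of), collapse = "")
}

#' Build a 16S reference panel for k-mer-density gene finding
#'
#' The panel holds every k-mer of the known genes (and, separately, of their
#' reverse complements, so candidate strand can be inferred by vote), plus
#' conserved terminal motifs taken as the IUPAC consensus of the first and
#' last `motif_len` nucleotides of the known genes. The motifs provide
#' consistent, homologous gene endpoints during anchoring.
#'
#' @param known_genes Character vector of known full-length 16S sequences,
#'   a FASTA path, or a tibble with a `sequence` column.
#' @param k K-mer size (default 13).
#' @param motif_len Length of the terminal anchor motifs (default 20).
#' @return Object of class `reference_panel`: `kmers_fwd`, `kmers_rc`,
#'   `start_motif`, `end_motif`, `median_len`, `k`.
#' @export
build_reference_panel <- function(known_genes, k = 13, motif_len = 20) {
  seqs <- if (is.data.frame(known_genes)) {
    known_genes$sequence
  } else if (length(known_genes) == 1 && file.exists(known_genes)) {
    as.character(Biostrings::readDNAStringSet(known_genes))
  } else {
    known_genes
  }
  seqs <- toupper(seqs)
  if (length(seqs) == 0) abort("reference panel needs at least one known 16S gene")
  kmers_fwd <- unique(unlist(lapply(seqs, all_kmers, k = k)))
  kmers_rc <- unique(unlist(lapply(revcomp_plain(seqs), all_kmers, k = k)))
  starts <- substr(seqs, 1, motif_len)
  lens <- nchar(seqs)
  ends <- substr(seqs, lens - motif_len + 1, lens)
  structure(
    list(
      kmers_fwd = kmers_fwd,
      kmers_rc = kmers_rc,
      start_motif = iupac_consensus(starts),
      end_motif = iupac_consensus(ends),
      median_len = stats::median(lens),
      k = as.integer(k)
    ),
    class = "reference_panel"
  )
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf(
    "<reference_panel> %d-mers: %d fwd / %d rc; motifs %s ... %s; median gene %g bp\n",
    x$k, length(x$kmers_fwd), length(x$kmers_rc),
    x$start_motif, x$end_motif, x$median_len
  ))
  invisible(x)
}

#' Scan a genome sequence for 16S-like candidate segments
#'
#' Slides a window over the k-mer starts of the sequence and keeps maximal
#' runs whose fraction of panel k-mers reaches `density_threshold`;
#' candidates closer than `window` are merged. Strand is inferred from the
#' majority orientation of matched k-mers (k-mers present on both strands of
#' the panel do not vote).
#'
#' @param sequence Single sanitized DNA string.
#' @param panel A [build_reference_panel()] object.
#' @param window Window size in k-mer starts (default 100).
#' @param density_threshold Minimum matched-k-mer fraction (default 0.30).
#' @return Tibble of candidates: `start`, `end` (0-based half-open genomic
#'   coordinates), `strand`, `density`.
#' @export
scan_candidates <- function(sequence, panel, window = 100, density_threshold = 0.30) {
  k <- panel$k
  if (window < k) abort("window must be at least k")
  kmers <- all_kmers(toupper(sequence), k)
  empty <- tibble(start = integer(0), end = integer(0),
                  strand = character(0), density = numeric(0))
  n <- length(kmers)
  if (n < window) return(empty)
  hit_f <- kmers %in% panel$kmers_fwd
  hit_r <- kmers %in% panel$kmers_rc
  hit <- hit_f | hit_r
  cs <- cumsum(c(0L, hit))
  nwin <- n - window + 1
  counts <- cs[(window + 1):(n + 1)] - cs[1:nwin]
  above <- counts >= density_threshold * window
  if (!any(above)) return(empty)
  r <- rle(above)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1
  runs <- tibble(
    ks = starts[r$values],            # first window index of the run
    ke = stops[r$values] + window - 1 # last k-mer start covered
  )
  # merge runs separated by less than one window
  merged <- list()
  cur <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$ks[i] - cur$ke <= window) {
        cur$ke <- runs$ke[i]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- runs[i, ]
      }
    }
  }
  merged[[length(merged) + 1]] <- cur
  runs <- dplyr::bind_rows(merged)
  purrr::pmap_dfr(runs, function(ks, ke) {
    idx <- ks:ke
    f_votes <- sum(hit_f[idx] & !hit_r[idx])
    r_votes <- sum(hit_r[idx] & !hit_f[idx])
    tibble(
      start = ks - 1L,                # 0-based
      end = ke + k - 1L,              # half-open
      strand = if (r_votes > f_votes) "-" else "+",
      density = sum(hit[idx]) / length(idx)
    )
  })
}

# IUPAC motif matching on a plain-base slice
motif_positions <- function(slice, motif) match_primer(slice, motif)

#' Anchor terminal motifs within a candidate and extract gene hits
#'
#' Orients the candidate to the sense strand, locates start/end motif
#' occurrences, and pairs them greedily left to right; when several end
#' motifs give an admissible span, the one whose length is closest to the
#' panel's median gene length wins. Coordinates are mapped back to the
#' genomic (plus) strand.
#'
#' @param candidate One row of [scan_candidates()] output (list or one-row
#'   data frame with `start`, `end`, `strand`).
#' @param sequence The unit's full sequence.
#' @param panel Reference panel.
#' @param min_len,max_len Admissible gene length range in bp.
#' @param margin Extra bases taken on both sides of the candidate before
#'   motif search (default 60).
#' @return Tibble of gene hits (possibly zero rows): `start`, `end` (0-based
#'   half-open), `strand`, `sequence` (sense orientation), `length_bp`.
#' @export
anchor_and_extract <- function(candidate, sequence, panel,
                               min_len = 1200, max_len = 1900, margin = 60) {
  empty <- tibble(start = integer(0), end = integer(0), strand = character(0),
                  sequence = character(0), length_bp = integer(0))
  slice_start0 <- max(0L, candidate$start - margin)
  slice_end0 <- min(nchar(sequence), candidate$end + margin)
  slice <- substr(sequence, slice_start0 + 1, slice_end0)
  L <- nchar(slice)
  sense <- if (candidate$strand == "-") revcomp_plain(slice) else slice
  sp <- motif_positions(sense, panel$start_motif)
  ep <- motif_positions(sense, panel$end_motif)
  if (length(sp) == 0 || length(ep) == 0) return(empty)
  ep_end <- ep + nchar(panel$end_motif) - 1L
  hits <- list()
  cursor <- 1L
  for (s in sp) {
    if (s < cursor) next
    len <- ep_end - s + 1L
    ok <- which(len >= min_len & len <= max_len & ep > s)
    if (length(ok) == 0) next
    best <- ok[which.min(abs(len[ok] - panel$median_len))]
    e_end <- ep_end[best]
    hits[[length(hits) + 1]] <- c(s, e_end)
    cursor <- e_end + 1L
  }
  if (length(hits) == 0) return(empty)
  purrr::map_dfr(hits, function(h) {
    s <- h[1]; e <- h[2]
    gene_seq <- substr(sense, s, e)
    if (candidate$strand == "+") {
      g_start0 <- slice_start0 + s - 1L
      g_end0 <- slice_start0 + e
    } else {
      g_start0 <- slice_start0 + (L - e)
      g_end0 <- slice_start0 + (L - s + 1L)
    }
    tibble(
      start = as.integer(g_start0), end = as.integer(g_end0),
      strand = candidate$strand, sequence = gene_seq,
      length_bp = nchar(gene_seq)
    )
  })
}

#' Detect and extract 16S rRNA genes from analysis units
#'
#' Composition of [scan_candidates()] and [anchor_and_extract()] over every
#' unit: k-mer-density candidate detection followed by conserved-motif
#' anchoring. Hits are sorted by start; overlapping hits keep the one from
#' the denser candidate.
#'
#' @param units Tibble from [split_units()] (needs `unit_id`, `sequence`).
#' @param panel Reference panel.
#' @inheritParams scan_candidates
#' @inheritParams anchor_and_extract
#' @return Tibble of gene hits: `unit_id`, `gene_index`, `start`, `end`
#'   (0-based half-open), `strand`, `sequence` (sense 5'->3'), `length_bp`.
#' @export
extract_genes <- function(units, panel, window = 100, density_threshold = 0.30,
                          min_len = 1200, max_len = 1900) {
  purrr::map_dfr(seq_len(nrow(units)), function(i) {
    seq_i <- units$sequence[i]
    cands <- scan_candidates(seq_i, panel, window, density_threshold)
    if (nrow(cands) == 0) return(NULL)
    hits <- purrr::map_dfr(seq_len(nrow(cands)), function(j) {
      h <- anchor_and_extract(cands[j, ], seq_i, panel, min_len, max_len)
      if (nrow(h) > 0) h$density <- cands$density[j]
      h
    })
    if (nrow(hits) == 0) return(NULL)
    hits <- dplyr::arrange(hits, .data$start)
    keep <- rep(TRUE, nrow(hits))
    last_end <- -1L
    last_idx <- 0L
    for (j in seq_len(nrow(hits))) {
      if (hits$start[j] < last_end) {
        # overlap: keep the hit from the denser candidate
        if (hits$density[j] > hits$density[last_idx]) {
          keep[last_idx] <- FALSE
          last_end <- hits$end[j]; last_idx <- j
        } else {
          keep[j] <- FALSE
        }
      } else {
        last_end <- hits$end[j]; last_idx <- j
      }
    }
    hits <- hits[keep, ]
    dplyr::mutate(
      dplyr::select(hits, -"density"),
      unit_id = units$unit_id[i],
      gene_index = dplyr::row_number(),
      .before = 1
    )
  })
}

#' Read pre-extracted 16S genes (finder bypass)
#'
#' Accepts a FASTA whose record ids are `<unit_id>|gene<i>`; sequences are
#' taken as already sense-oriented. Downstream metrics run identically on
#' this table and on [extract_genes()] output.
#'
#' @param path FASTA path.
#' @param delim Separator between unit id and gene label (default `"|"`).
#' @return Tibble with `unit_id`, `gene_index`, `sequence`, `length_bp`.
#' @export
read_genes_fasta <- function(path, delim = "|") {
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  parts <- stringr::str_split_fixed(ids, stringr::fixed(delim), 2)
  seqs <- unname(toupper(as.character(dss)))
  tibble(
    unit_id = parts[, 1],
    gene_index = as.integer(sub("^gene", "", parts[, 2])),
    sequence = seqs,
    length_bp = nchar(seqs)
  )
}
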