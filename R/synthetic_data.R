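rotate_base <- function(base) {
  bases <- c("A", "C", "G", "T")
  bases[(match(base, bases)) %% 4 + 1]
}

#' Define a synthetic community
#'
#' A community specification fixes, per species: taxonomy, number of
#' strains, 16S copies per analysis unit (chromosome), number of gene
#' variants, per-base divergence applied outside protected windows, number
#' of chromosomes per genome, the fraction of gene copies inserted on the
#' minus strand, whether the genome carries an extra decoy chromosome with
#' a disqualifying ambiguity run, and optionally a primer pair whose
#' binding site is corrupted so the species goes undetected by it.
#' `ma_links` force byte-identical amplified windows between two species
#' for a named pair. Primer binding sites and the conserved gene termini
#' are never mutated.
#'
#' @param species Tibble with columns `species`, `superkingdom`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `n_strains`, `copies`,
#'   `n_variants`, `divergence`, `n_chromosomes`, `minus_strand_fraction`,
#'   `ambiguity_decoy` (logical), `mutate_pair` (pair id or NA).
#' @param ma_links Tibble with `species_a`, `species_b`, `pair_id` (may be
#'   NULL).
#' @param primer_pairs Primer table whose binding sites are planted exactly
#'   (default: bundled catalogue).
#' @return Object of class `community_spec`.
#' @export
community_spec <- function(species, ma_links = NULL,
                           primer_pairs = read_primer_pairs()) {
  species <- as_tibble(species)
  defaults <- list(
    n_strains = 1L, copies = 4L, n_variants = 1L, divergence = 0.02,
    n_chromosomes = 1L, minus_strand_fraction = 0,
    ambiguity_decoy = FALSE, mutate_pair = NA_character_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(species)) species[[nm]] <- defaults[[nm]]
  }
  if (any(species$copies < 0)) abort("copies must be >= 0")
  if (any(species$divergence < 0 | species$divergence > 0.1)) {
    abort("divergence must lie in [0, 0.1]")
  }
  if (any(species$n_variants > pmax(species$copies, 1))) {
    abort("n_variants cannot exceed copies")
  }
  if (!is.null(ma_links)) {
    ma_links <- as_tibble(ma_links)
    bad <- setdiff(c(ma_links$species_a, ma_links$species_b), species$species)
    if (length(bad) > 0) abort(sprintf("ma_links reference unknown species: %s",
                                       paste(bad, collapse = ", ")))
    if (!all(ma_links$pair_id %in% primer_pairs$pair_id)) {
      abort("ma_links reference unknown primer pair")
    }
  }
  structure(
    list(species = species, ma_links = ma_links, primer_pairs = primer_pairs),
    class = "community_spec"
  )
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf("<community_spec> %d species, %d MA links, %d primer pairs\n",
              nrow(x$species),
              if (is.null(x$ma_links)) 0L else nrow(x$ma_links),
              nrow(x$primer_pairs)))
  invisible(x)
}

#' Bundled community emulating observed copy-number structure
#'
#' Twenty species (14 bacterial, 6 archaeal) spanning copy numbers 1-11 and
#' variant counts 1-9 across several phyla; includes two-strain species, a
#' two-chromosome and a five-chromosome genome, minus-strand gene copies,
#' one genome with a decoy chromosome carrying an 11-nt ambiguity run
#' (excluded by sanitization), one species whose reverse-primer site for
#' OP_F009-OP_R029 is corrupted (undetected by that pair), and three
#' planted cross-species matching-amplicon links.
#'
#' @return A [community_spec()] object, the package's default test fixture.
#' @export
table1_like_spec <- function() {
  sp <- tibble::tribble(
    ~species,                  ~superkingdom, ~phylum,          ~copies, ~n_variants, ~n_strains, ~n_chromosomes, ~minus_strand_fraction, ~ambiguity_decoy, ~mutate_pair,
    "Bacillus maximus",        "Bacteria", "Firmicutes",     11L, 9L, 2L, 1L, 0.4, FALSE, NA,
    "Streptococcus primus",    "Bacteria", "Firmicutes",      5L, 4L, 2L, 1L, 0.4, FALSE, NA,
    "Streptococcus secundus",  "Bacteria", "Firmicutes",      4L, 1L, 1L, 1L, 0.0, FALSE, NA,
    "Lactobacillus acerbus",   "Bacteria", "Firmicutes",      6L, 2L, 1L, 1L, 0.4, FALSE, NA,
    "Lactobacillus mitis",     "Bacteria", "Firmicutes",      3L, 2L, 1L, 1L, 0.0, FALSE, NA,
    "Escherichia ficta",       "Bacteria", "Proteobacteria",  8L, 8L, 1L, 2L, 0.4, FALSE, NA,
    "Neisseria parva",         "Bacteria", "Proteobacteria",  2L, 1L, 1L, 1L, 0.0, FALSE, NA,
    "Actinomyces fictus",      "Bacteria", "Actinobacteria",  5L, 4L, 1L, 1L, 0.4, FALSE, NA,
    "Rothia simplex",          "Bacteria", "Actinobacteria",  1L, 1L, 1L, 1L, 0.0, FALSE, NA,
    "Prevotella umbra",        "Bacteria", "Bacteroidetes",   7L, 5L, 1L, 1L, 0.4, FALSE, NA,
    "Fusobacterium junctum",   "Bacteria", "Fusobacteria",    5L, 5L, 1L, 1L, 0.0, FALSE, NA,
    "Treponema gracile",       "Bacteria", "Spirochaetes",    2L, 1L, 1L, 1L, 0.0, FALSE, NA,
    "Mycoplasma tenue",        "Bacteria", "Tenericutes",     1L, 1L, 1L, 1L, 0.0, TRUE,  NA,
    "Haemophilus lapsus",      "Bacteria", "Proteobacteria",  3L, 2L, 1L, 1L, 0.0, FALSE, "OP_F009-OP_R029",
    "Methanobrevibacter altus","Archaea",  "Euryarchaeota",   4L, 3L, 2L, 1L, 0.4, FALSE, NA,
    "Methanosarcina socia",    "Archaea",  "Euryarchaeota",   3L, 2L, 1L, 1L, 0.0, FALSE, NA,
    "Methanosarcina proxima",  "Archaea",  "Euryarchaeota",   2L, 1L, 1L, 1L, 0.0, FALSE, NA,
    "Haloarcula sola",         "Archaea",  "Euryarchaeota",   1L, 1L, 1L, 1L, 0.0, FALSE, NA,
    "Sulfolobus quintuplex",   "Archaea",  "Crenarchaeota",   5L, 2L, 1L, 5L, 0.4, FALSE, NA,
    "Thermococcus unicus",     "Archaea",  "Crenarchaeota",   1L, 1L, 1L, 1L, 0.0, FALSE, NA
  )
  genus <- vapply(strsplit(sp$species, " "), `[[`, character(1), 1)
  sp <- dplyr::mutate(
    sp,
    genus = genus,
    family = paste0(genus, "aceae"),
    order = paste0(genus, "ales"),
    class = paste0(sp$phylum, "ia"),
    divergence = 0.02
  )
  links <- tibble::tribble(
    ~species_a, ~species_b, ~pair_id,
    "Streptococcus primus", "Streptococcus secundus", "OP_F066-OP_R073",
    "Lactobacillus acerbus", "Lactobacillus mitis",   "KP_F048-OP_R030",
    "Methanosarcina socia",  "Methanosarcina proxima","OP_F114-OP_R121"
  )
  community_spec(sp, links)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# corrupt a planted primer site so exact degenerate matching must fail:
# set up to three site positions to bases outside the primer's expansion set
corrupt_site <- function(chars, site_seq_iupac, first) {
  schars <- strsplit(site_seq_iupac, "", fixed = TRUE)[[1]]
  done <- 0L
  for (j in seq_along(schars)) {
    set <- IUPAC_SETS[[schars[j]]]
    out <- setdiff(c("A", "C", "G", "T"), set)
    if (length(out) > 0) {
      chars[first + j - 1L] <- out[1]
      done <- done + 1L
      if (done >= 3L) break
    }
  }
  if (done == 0L) abort("cannot corrupt a fully degenerate site")
  chars
}

#' Generate a synthetic genome community with truth tables
#'
#' Builds every species' gene variants from the synthetic 16S template
#' (divergence and variant substitutions never touch primer sites or the
#' conserved termini; each species additionally carries a unique barcode
#' substitution in every sizeable unprotected segment, so amplified windows
#' differ between species unless an MA link forces them identical), plants
#' the requested number of copies on each chromosome (minus-strand copies
#' as reverse complements) separated by random background, and derives
#' machine-readable truth tables by direct construction: expected amplicons
#' are substring extractions at the known planted coordinates and MA flags
#' come from pairwise string comparison — no pipeline code is involved.
#'
#' @param spec A [community_spec()].
#' @param seed Integer seed; the whole community is a deterministic
#'   function of (spec, seed).
#' @return Object of class `synthetic_community`: `genomes`, `taxonomy`,
#'   `genes` (per-gene truth: unit, coordinates, strand, sense sequence),
#'   `truth` (list: `units`, `species_amplicons`, `amplicon_counts`,
#'   `ma_flags`, `evaluation`), `template`, `spec`, `seed`.
#' @export
generate_community <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "community_spec"))
  pp <- spec$primer_pairs
  template <- synthetic_16s_template(pp)
  tchars <- strsplit(template, "", fixed = TRUE)[[1]]
  mask <- protected_mask(template_protected_windows(pp))
  free_idx <- which(!mask)
  # maximal free segments able to hold one barcode position per species
  seg <- rle(mask)
  seg_end <- cumsum(seg$lengths)
  seg_start <- seg_end - seg$lengths + 1L
  big_free <- which(!seg$values & seg$lengths >= nrow(spec$species) + 2L)
  sp <- spec$species

  with_seed(seed, {
    # --- species base genes -------------------------------------------------
    bases <- list()
    for (i in seq_len(nrow(sp))) {
      chars <- tchars
      div <- sp$divergence[i]
      if (div > 0) {
        hit <- free_idx[stats::runif(length(free_idx)) < div]
        chars[hit] <- vapply(chars[hit], rotate_base, character(1))
        extra <- stats::runif(length(hit))  # second rotation for ~1/3 of hits
        chars[hit[extra < 1 / 3]] <- vapply(chars[hit[extra < 1 / 3]],
                                            rotate_base, character(1))
      }
      # unique per-species barcode in every large unprotected segment
      for (b in big_free) {
        pos <- seg_start[b] + i - 1L
        chars[pos] <- rotate_base(tchars[pos])
      }
      if (!is.na(sp$mutate_pair[i])) {
        row <- pp[pp$pair_id == sp$mutate_pair[i], ]
        chars <- corrupt_site(chars, iupac_revcomp(row$rev_seq),
                              row$template_r_first)
      }
      bases[[sp$species[i]]] <- chars
    }
    # --- MA links: copy the full amplified window A -> B --------------------
    if (!is.null(spec$ma_links)) {
      for (l in seq_len(nrow(spec$ma_links))) {
        row <- pp[pp$pair_id == spec$ma_links$pair_id[l], ]
        w <- row$template_f_first:row$template_r_last
        bases[[spec$ma_links$species_b[l]]][w] <-
          bases[[spec$ma_links$species_a[l]]][w]
      }
    }
    # --- variants: nested extra substitutions at distinct free positions ----
    variants <- list()
    for (i in seq_len(nrow(sp))) {
      nv <- sp$n_variants[i]
      vs <- list(bases[[sp$species[i]]])
      if (nv > 1) {
        vpos <- sample(free_idx, nv - 1)
        for (j in 2:nv) {
          chars <- vs[[j - 1]]
          chars[vpos[j - 1]] <- rotate_base(chars[vpos[j - 1]])
          vs[[j]] <- chars
        }
      }
      variants[[sp$species[i]]] <- vapply(vs, paste, character(1), collapse = "")
    }
    # --- assemble genomes ---------------------------------------------------
    genome_rows <- list()
    gene_rows <- list()
    unit_rows <- list()
    tax_rows <- list()
    for (i in seq_len(nrow(sp))) {
      nv <- sp$n_variants[i]
      m <- sp$copies[i]
      vset <- variants[[sp$species[i]]]
      variant_ids <- if (m == 0) integer(0) else rep(seq_len(nv), c(m - nv + 1L, rep(1L, nv - 1L)))
      for (s in seq_len(sp$n_strains[i])) {
        gid <- sprintf("sp%02d_s%d", i, s)
        strain_name <- if (sp$n_strains[i] == 1) sp$species[i] else
          paste0(sp$species[i], " str", s)
        tax_rows[[length(tax_rows) + 1]] <- tibble(
          genome_id = gid,
          superkingdom = sp$superkingdom[i], phylum = sp$phylum[i],
          class = sp$class[i], order = sp$order[i], family = sp$family[i],
          genus = sp$genus[i], species = sp$species[i], strain = strain_name
        )
        n_chrom <- sp$n_chromosomes[i]
        for (cc in seq_len(n_chrom)) {
          strands <- ifelse(stats::runif(m) < sp$minus_strand_fraction[i], "-", "+")
          pieces <- character(0)
          pos <- 0L
          starts <- integer(m)
          lead <- random_dna(800)
          if (i == 1 && s == 1 && cc == 1) {
            # replaceable single-code ambiguities in the background
            substr(lead, 101, 101) <- "R"
            substr(lead, 201, 201) <- "Y"
            substr(lead, 301, 301) <- "W"
          }
          pieces <- c(pieces, lead); pos <- pos + nchar(lead)
          for (g in seq_len(m)) {
            gseq <- vset[variant_ids[g]]
            placed <- if (strands[g] == "-") revcomp_plain(gseq) else gseq
            starts[g] <- pos
            pieces <- c(pieces, placed); pos <- pos + nchar(placed)
            gap <- random_dna(if (g < m) 400 else 600)
            pieces <- c(pieces, gap); pos <- pos + nchar(gap)
          }
          chrom_seq <- paste(pieces, collapse = "")
          unit_id <- paste0(gid, "_", cc)
          genome_rows[[length(genome_rows) + 1]] <- tibble(
            genome_id = gid, chrom_id = paste0("chr", cc), sequence = chrom_seq
          )
          unit_rows[[length(unit_rows) + 1]] <- tibble(
            unit_id = unit_id, genome_id = gid, species = sp$species[i],
            superkingdom = sp$superkingdom[i], excluded = FALSE,
            n_genes = m,
            n_variants = if (m == 0) 0L else length(unique(vset[variant_ids])),
            n_plus_strand = sum(strands == "+"),
            n_minus_strand = sum(strands == "-"),
            length_bp = nchar(chrom_seq)
          )
          if (m > 0) {
            gene_rows[[length(gene_rows) + 1]] <- tibble(
              unit_id = unit_id,
              gene_index = seq_len(m),
              start = starts,
              end = starts + nchar(vset[variant_ids]),
              strand = strands,
              sequence = vset[variant_ids]
            )
          }
        }
        if (sp$ambiguity_decoy[i] && s == 1) {
          decoy <- random_dna(1200)
          substr(decoy, 601, 611) <- strrep("N", 11)
          genome_rows[[length(genome_rows) + 1]] <- tibble(
            genome_id = gid, chrom_id = paste0("chr", n_chrom + 1L),
            sequence = decoy
          )
          unit_rows[[length(unit_rows) + 1]] <- tibble(
            unit_id = paste0(gid, "_", n_chrom + 1L), genome_id = gid,
            species = sp$species[i], superkingdom = sp$superkingdom[i],
            excluded = TRUE, n_genes = 0L, n_variants = 0L,
            n_plus_strand = 0L, n_minus_strand = 0L, length_bp = nchar(decoy)
          )
        }
      }
    }
    genomes <- dplyr::bind_rows(genome_rows)
    taxonomy <- dplyr::bind_rows(tax_rows)
    genes <- dplyr::bind_rows(gene_rows)
    units_truth <- dplyr::bind_rows(unit_rows)

    truth <- build_truth(sp, variants, units_truth, pp, spec$ma_links)

    structure(
      list(
        genomes = genomes, taxonomy = taxonomy, genes = genes,
        truth = truth, template = template, spec = spec, seed = seed
      ),
      class = "synthetic_community"
    )
  })
}

# Truth-table construction: expected amplicons are substring extractions at
# the planted template coordinates (substitution-only mutation keeps every
# coordinate fixed); detection, MA flags and the coverage metrics follow by
# direct loops over these strings. Independent of the matching machinery.
build_truth <- function(sp, variants, units_truth, pp, ma_links) {
  domains <- superkingdom_domain(sp$superkingdom)
  active_units <- units_truth[!units_truth$excluded, ]

  # per-species, per-pair: detected? and the set/multiset of amplicon strings
  # carried by each unit (the unit variant multiset is identical across units)
  species_amps <- list()
  for (i in seq_len(nrow(sp))) {
    s <- sp$species[i]
    nv <- sp$n_variants[i]
    m <- sp$copies[i]
    if (m == 0) next
    variant_counts <- c(m - nv + 1L, rep(1L, nv - 1L))
    for (p in seq_len(nrow(pp))) {
      pid <- pp$pair_id[p]
      detected <- m > 0 && (is.na(sp$mutate_pair[i]) || sp$mutate_pair[i] != pid)
      if (!detected) next
      windows <- substr(variants[[s]], pp$template_f_first[p], pp$template_r_last[p])
      species_amps[[length(species_amps) + 1]] <- tibble(
        species = s, domain = domains[i], pair_id = pid,
        variant_index = seq_len(nv),
        count_per_unit = variant_counts,
        amplicon = windows
      )
    }
  }
  species_amps <- dplyr::bind_rows(species_amps)

  unit_counts <- species_amps |>
    dplyr::group_by(.data$species, .data$pair_id) |>
    dplyr::summarise(
      n_amplicons = sum(.data$count_per_unit),
      n_amplicon_variants = dplyr::n_distinct(.data$amplicon),
      .groups = "drop"
    ) |>
    dplyr::inner_join(
      dplyr::select(active_units, "unit_id", "species"),
      by = "species", relationship = "many-to-many"
    ) |>
    dplyr::select("pair_id", "unit_id", "species",
                  "n_amplicons", "n_amplicon_variants")

  # MA flags by pairwise string-set intersection within each domain
  ma_flag_rows <- list()
  for (pid in unique(species_amps$pair_id)) {
    sub <- species_amps[species_amps$pair_id == pid, ]
    for (dom in unique(sub$domain)) {
      dsub <- sub[sub$domain == dom, ]
      spl <- split(dsub$amplicon, dsub$species)
      nm <- names(spl)
      if (length(nm) < 2) next
      for (a in seq_along(nm)) {
        for (b in seq_along(nm)) {
          if (a >= b) next
          if (length(intersect(spl[[a]], spl[[b]])) > 0) {
            ma_flag_rows[[length(ma_flag_rows) + 1]] <- tibble(
              pair_id = pid, domain = dom, species = c(nm[a], nm[b])
            )
          }
        }
      }
    }
  }
  ma_flags <- if (length(ma_flag_rows) > 0) {
    dplyr::distinct(dplyr::bind_rows(ma_flag_rows))
  } else {
    tibble(pair_id = character(0), domain = character(0), species = character(0))
  }
  # keep flags only for the evaluation set(s) the pair's scope declares
  scope_map <- dplyr::bind_rows(purrr::map2(pp$pair_id, pp$domain_scope, function(pid, sc) {
    tibble(pair_id = pid,
           domain = if (sc == "both") c("bacteria", "archaea") else sc)
  }))
  ma_flags <- dplyr::semi_join(ma_flags, scope_map, by = c("pair_id", "domain"))

  # per-pair per-domain evaluation under the documented OF interpretation
  dom_totals <- active_units |>
    dplyr::mutate(domain = superkingdom_domain(.data$superkingdom)) |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(n_units = dplyr::n(),
                     n_species = dplyr::n_distinct(.data$species),
                     .groups = "drop")
  units_per_species <- active_units |>
    dplyr::count(.data$species, name = "n_units_sp")

  eval_rows <- list()
  for (p in seq_len(nrow(pp))) {
    pid <- pp$pair_id[p]
    scope <- pp$domain_scope[p]
    doms <- if (scope == "both") c("bacteria", "archaea") else scope
    doms <- doms[doms %in% dom_totals$domain]
    per_dom <- list()
    for (dom in doms) {
      tot <- dom_totals[dom_totals$domain == dom, ]
      sub <- species_amps[species_amps$pair_id == pid & species_amps$domain == dom, ]
      det_sp <- unique(sub$species)
      det_units <- sum(units_per_species$n_units_sp[
        units_per_species$species %in% det_sp])
      mas <- ma_flags$species[ma_flags$pair_id == pid & ma_flags$domain == dom]
      # OF: copies + foreign matching amplicons per foreign unit
      ofs <- vapply(det_sp, function(s) {
        own <- sub[sub$species == s, ]
        copies <- sum(own$count_per_unit)
        foreign_total <- 0
        foreign_units <- 0
        for (t in setdiff(det_sp, s)) {
          oth <- sub[sub$species == t, ]
          per_unit <- sum(oth$count_per_unit[oth$amplicon %in% own$amplicon])
          if (per_unit > 0) {
            nu <- units_per_species$n_units_sp[units_per_species$species == t]
            foreign_total <- foreign_total + per_unit * nu
            foreign_units <- foreign_units + nu
          }
        }
        foreign <- if (foreign_units > 0) foreign_total / foreign_units else 0
        c(of = copies + foreign, of_ma = (copies + foreign) / copies)
      }, numeric(2))
      per_dom[[dom]] <- tibble(
        pair_id = pid, domain = dom,
        n_genomes_detected = det_units,
        n_species_detected = length(det_sp),
        n_species_ma = length(unique(mas)),
        sc_nma_count = length(det_sp) - length(unique(mas)),
        sc_nma_pct = sc_nma(length(det_sp), length(unique(mas)), tot$n_species),
        of_mean = if (length(det_sp) == 0) NA_real_ else
          round_half_up(mean(ofs["of", ]), 2),
        of_ma_mean = if (length(det_sp) == 0) NA_real_ else
          round_half_up(mean(ofs["of_ma", ]), 2),
        n_total_units = tot$n_units,
        n_total_species = tot$n_species
      )
    }
    res <- dplyr::bind_rows(per_dom)
    if (scope == "both" && nrow(res) == 2) {
      res <- dplyr::bind_rows(res, tibble(
        pair_id = pid, domain = "overall",
        n_genomes_detected = sum(res$n_genomes_detected),
        n_species_detected = sum(res$n_species_detected),
        n_species_ma = sum(res$n_species_ma),
        sc_nma_count = sum(res$sc_nma_count),
        sc_nma_pct = sc_nma(sum(res$n_species_detected), sum(res$n_species_ma),
                            sum(res$n_total_species)),
        of_mean = NA_real_, of_ma_mean = NA_real_,
        n_total_units = sum(res$n_total_units),
        n_total_species = sum(res$n_total_species)
      ))
    }
    eval_rows[[length(eval_rows) + 1]] <- res
  }

  list(
    units = units_truth,
    species_amplicons = species_amps,
    amplicon_counts = unit_counts,
    ma_flags = ma_flags,
    evaluation = dplyr::bind_rows(eval_rows)
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf(
    "<synthetic_community> %d genomes / %d chromosomes, %d species, seed %d\n",
    dplyr::n_distinct(x$genomes$genome_id), nrow(x$genomes),
    dplyr::n_distinct(x$taxonomy$species), x$seed
  ))
  invisible(x)
}

#' Write a synthetic community to disk
#'
#' Emits `genomes.fasta` (record ids `<genome_id>|<chrom_id>`),
#' `taxonomy.tsv`, `genes_truth.fasta` (record ids `<unit_id>|gene<i>`,
#' sense orientation — the finder-bypass input) and the truth tables as
#' TSVs.
#'
#' @param community A [generate_community()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(community$genomes$sequence)
  names(g) <- paste0(community$genomes$genome_id, "|", community$genomes$chrom_id)
  Biostrings::writeXStringSet(g, file.path(dir, "genomes.fasta"))
  readr::write_tsv(community$taxonomy, file.path(dir, "taxonomy.tsv"))
  if (nrow(community$genes) > 0) {
    gt <- Biostrings::DNAStringSet(community$genes$sequence)
    names(gt) <- paste0(community$genes$unit_id, "|gene", community$genes$gene_index)
    Biostrings::writeXStringSet(gt, file.path(dir, "genes_truth.fasta"))
  }
  readr::write_tsv(community$truth$units, file.path(dir, "truth_units.tsv"))
  readr::write_tsv(community$truth$amplicon_counts,
                   file.path(dir, "truth_amplicon_counts.tsv"))
  readr::write_tsv(community$truth$ma_flags, file.path(dir, "truth_ma_flags.tsv"))
  readr::write_tsv(community$truth$evaluation, file.path(dir, "truth_evaluation.tsv"))
  invisible(dir)
}
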