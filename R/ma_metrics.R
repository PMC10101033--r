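#' Find matching-amplicon (MA) groups
#'
#' Matching amplicons are amplicons with byte-identical sequence produced by
#' two or more *different species* with the same primer pair; identical
#' copies within one species (intragenomic redundancy, or shared across
#' strains of the same species) do not form a group.
#'
#' @param amplicons Amplicon tibble from [amplify()] including a `species`
#'   column.
#' @return Tibble with one row per group: `pair_id`, `sequence`,
#'   `n_species`, and a `members` list-column of
#'   (`species`, `unit_id`, `gene_index`).
#' @export
find_ma_groups <- function(amplicons) {
  if (!"species" %in% names(amplicons)) {
    abort("amplicons need a 'species' column (pass units = to amplify())")
  }
  amplicons |>
    dplyr::group_by(.data$pair_id, .data$sequence) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species),
      members = list(dplyr::pick(dplyr::all_of(c("species", "unit_id", "gene_index")))),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_species >= 2)
}

#' Species flagged as having matching amplicons
#'
#' @param ma_groups Output of [find_ma_groups()].
#' @return Tibble of distinct (`pair_id`, `species`) combinations.
#' @export
ma_species <- function(ma_groups) {
  if (nrow(ma_groups) == 0) {
    return(tibble(pair_id = character(0), species = character(0)))
  }
  ma_groups |>
    dplyr::select("pair_id", "members") |>
    tidyr::unnest("members") |>
    dplyr::distinct(.data$pair_id, .data$species)
}

#' Species coverage with no matching amplicons (SC-NMA)
#'
#' `SC-NMA (%) = (species detected - species with MAs) / total species x 100`,
#' reported to two decimals (half-up).
#'
#' @param n_detected Species detected by the primer pair.
#' @param n_ma_species Detected species having at least one MA.
#' @param n_total Total species evaluated.
#' @return Percentage rounded to 2 decimals.
#' @examples
#' sc_nma(180, 6, 186) # 93.55
#' @export
sc_nma <- function(n_detected, n_ma_species, n_total) {
  if (any(n_total <= 0)) abort("n_total must be positive")
  if (any(n_ma_species < 0 | n_detected < n_ma_species | n_total < n_detected)) {
    abort("need 0 <= n_ma_species <= n_detected <= n_total")
  }
  round_half_up((n_detected - n_ma_species) / n_total * 100, 2)
}

#' Overall two-domain SC-NMA
#'
#' Combines bacterial and archaeal counts for a primer pair usable on both
#' domains: `[(det_B - ma_B) + (det_A - ma_A)] / (total_B + total_A) x 100`.
#'
#' @param det_b,ma_b,tot_b Bacterial detected / MA / total species counts.
#' @param det_a,ma_a,tot_a Archaeal counterparts.
#' @return Percentage rounded to 2 decimals.
#' @examples
#' sc_nma_overall(180, 6, 186, 129, 6, 135) # 92.52
#' @export
sc_nma_overall <- function(det_b, ma_b, tot_b, det_a, ma_a, tot_a) {
  sc_nma(det_b + det_a, ma_b + ma_a, tot_b + tot_a)
}

#' Per-species overestimation factors (OF and OF-MA)
#'
#' For each species detected by a primer pair, `copies` is its mean number
#' of amplicons per detected genome unit and `foreign` is the number of
#' byte-identical amplicons found in other species' units, averaged over
#' the foreign units carrying at least one such amplicon (zero when the
#' species has no MAs). Then `OF = copies + foreign` combines intragenomic
#' redundancy with cross-species matching amplicons, and
#' `OF-MA = OF / copies` isolates the MA contribution: a species with
#' OF-MA exactly 1.00 has no amplicons matching any other species.
#'
#' @param amplicons Amplicons of a single primer pair (with `species` and
#'   `unit_id`); species with zero amplicons are simply absent.
#' @return Tibble: `species`, `copies`, `foreign`, `of`, `of_ma`.
#' @export
overestimation_factors <- function(amplicons) {
  if (nrow(amplicons) == 0) {
    return(tibble(species = character(0), copies = numeric(0),
                  foreign = numeric(0), of = numeric(0), of_ma = numeric(0)))
  }
  if (dplyr::n_distinct(amplicons$pair_id) > 1) {
    abort("overestimation_factors() expects amplicons of a single primer pair")
  }
  species_list <- unique(amplicons$species)
  purrr::map_dfr(species_list, function(s) {
    own <- amplicons[amplicons$species == s, ]
    copies <- nrow(own) / dplyr::n_distinct(own$unit_id)
    other <- amplicons[amplicons$species != s & amplicons$sequence %in% own$sequence, ]
    foreign <- if (nrow(other) == 0) 0 else nrow(other) / dplyr::n_distinct(other$unit_id)
    of <- copies + foreign
    tibble(species = s, copies = copies, foreign = foreign,
           of = of, of_ma = of / copies)
  })
}

superkingdom_domain <- function(x) {
  d <- tolower(x)
  dplyr::case_when(
    d %in% c("bacteria", "bacterium") ~ "bacteria",
    d %in% c("archaea", "archaeon") ~ "archaea",
    TRUE ~ d
  )
}

#' Evaluate one primer pair on one evaluation set
#'
#' @param pair_id Primer pair identifier (labels the output).
#' @param amplicons Amplicons of that pair restricted to the evaluation set.
#' @param n_units_total,n_species_total Denominators for the genome and
#'   species percentages (the full evaluated set, not just detections).
#' @return One-row tibble with detected-genome/species counts and
#'   percentages, MA species count and percentage (denominator: detected
#'   species), SC-NMA count and percentage, and mean OF / OF-MA.
#' @export
evaluate_pair <- function(pair_id, amplicons, n_units_total, n_species_total) {
  det_units <- dplyr::n_distinct(amplicons$unit_id)
  det_species <- dplyr::n_distinct(amplicons$species)
  mas <- ma_species(find_ma_groups(amplicons))
  n_ma <- length(unique(mas$species))
  ofs <- overestimation_factors(amplicons)
  tibble(
    pair_id = pair_id,
    n_genomes_detected = det_units,
    pct_genomes_detected = round_half_up(det_units / n_units_total * 100, 2),
    n_species_detected = det_species,
    pct_species_detected = round_half_up(det_species / n_species_total * 100, 2),
    n_species_ma = n_ma,
    pct_species_ma = if (det_species == 0) 0 else round_half_up(n_ma / det_species * 100, 2),
    sc_nma_count = det_species - n_ma,
    sc_nma_pct = sc_nma(det_species, n_ma, n_species_total),
    of_mean = if (nrow(ofs) == 0) NA_real_ else round_half_up(mean(ofs$of), 2),
    of_ma_mean = if (nrow(ofs) == 0) NA_real_ else round_half_up(mean(ofs$of_ma), 2),
    mean_amplicon_length = if (nrow(amplicons) == 0) NA_real_ else mean(amplicons$length_bp),
    n_total_units = n_units_total,
    n_total_species = n_species_total
  )
}

#' Evaluate every primer pair per domain
#'
#' Each pair is evaluated against the evaluation set(s) its `domain_scope`
#' declares: bacteria-only pairs against the bacterial units, archaea-only
#' against the archaeal units, and both-domain pairs against each domain
#' separately plus a combined `overall` row whose SC-NMA uses the pooled
#' two-domain formula ([sc_nma_overall()]). Matching amplicons are assessed
#' within each domain's evaluation set. An amplicon length category
#' ([classify_length_category()]) is assigned from the pair's mean amplicon
#' length over all its amplicons.
#'
#' @param amplicons Full amplicon table from [amplify()] (with species).
#' @param units Unit table from [split_units()].
#' @param pairs Primer table.
#' @return A `primer_evaluation` tibble, one row per pair per evaluation
#'   set (`domain` column), with the per-species MA flags in
#'   `attr(, "ma_flags")`.
#' @export
evaluate_primer_pairs <- function(amplicons, units, pairs) {
  units <- dplyr::mutate(units, domain = superkingdom_domain(.data$superkingdom))
  totals <- units |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      n_units = dplyr::n(),
      n_species = dplyr::n_distinct(.data$species),
      .groups = "drop"
    )
  get_total <- function(dom, what) {
    row <- totals[totals$domain == dom, ]
    if (nrow(row) == 0) c(n_units = 0L, n_species = 0L)[[what]] else row[[what]]
  }
  amplicons <- dplyr::left_join(
    amplicons,
    dplyr::select(units, "unit_id", "domain"),
    by = "unit_id"
  )
  flags <- list()
  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    scope <- pairs$domain_scope[i]
    doms <- if (scope == "both") c("bacteria", "archaea") else scope
    pid <- pairs$pair_id[i]
    doms <- doms[doms %in% totals$domain]  # skip evaluation sets with no units
    pair_amps <- amplicons[amplicons$pair_id == pid, ]
    res <- purrr::map_dfr(doms, function(dom) {
      sub <- pair_amps[pair_amps$domain == dom, ]
      ev <- evaluate_pair(pid, sub, get_total(dom, "n_units"), get_total(dom, "n_species"))
      mas <- ma_species(find_ma_groups(sub))
      if (nrow(mas) > 0) {
        flags[[length(flags) + 1]] <<- dplyr::mutate(mas, domain = dom)
      }
      dplyr::mutate(ev, domain = dom, .after = "pair_id")
    })
    if (scope == "both" && nrow(res) == 2) {
      comb <- tibble(
        pair_id = pid, domain = "overall",
        n_genomes_detected = sum(res$n_genomes_detected),
        pct_genomes_detected = round_half_up(
          sum(res$n_genomes_detected) / sum(res$n_total_units) * 100, 2),
        n_species_detected = sum(res$n_species_detected),
        pct_species_detected = round_half_up(
          sum(res$n_species_detected) / sum(res$n_total_species) * 100, 2),
        n_species_ma = sum(res$n_species_ma),
        pct_species_ma = if (sum(res$n_species_detected) == 0) 0 else
          round_half_up(sum(res$n_species_ma) / sum(res$n_species_detected) * 100, 2),
        sc_nma_count = sum(res$sc_nma_count),
        sc_nma_pct = sc_nma(sum(res$n_species_detected), sum(res$n_species_ma),
                            sum(res$n_total_species)),
        of_mean = NA_real_, of_ma_mean = NA_real_,
        mean_amplicon_length = if (nrow(pair_amps) == 0) NA_real_ else
          mean(pair_amps$length_bp),
        n_total_units = sum(res$n_total_units),
        n_total_species = sum(res$n_total_species)
      )
      res <- dplyr::bind_rows(res, comb)
    }
    res
  })
  rows <- dplyr::mutate(
    rows,
    length_category = classify_length_category(.data$mean_amplicon_length),
    .after = "domain"
  )
  out <- structure(rows, class = c("primer_evaluation", class(rows)))
  attr(out, "ma_flags") <- if (length(flags) > 0) {
    dplyr::bind_rows(flags)
  } else {
    tibble(pair_id = character(0), species = character(0), domain = character(0))
  }
  out
}

#' Tally species with matching amplicons across primer pairs
#'
#' @param ma_flags Tibble of (`pair_id`, `species`) MA flags, e.g.
#'   `attr(evaluate_primer_pairs(...), "ma_flags")`.
#' @param threshold Minimum number of primer pairs (default 10).
#' @return Tibble `species`, `n_pairs_with_ma`, `flagged` (TRUE when the
#'   species has MAs in at least `threshold` pairs), with the full
#'   species-by-pair logical flag matrix in `attr(, "flag_matrix")`.
#' @export
cross_primer_ma_tally <- function(ma_flags, threshold = 10) {
  if (nrow(ma_flags) == 0) {
    out <- tibble(species = character(0), n_pairs_with_ma = integer(0),
                  flagged = logical(0))
    attr(out, "flag_matrix") <- tibble(species = character(0))
    return(out)
  }
  mat <- ma_flags |>
    dplyr::distinct(.data$species, .data$pair_id) |>
    dplyr::mutate(flag = TRUE) |>
    tidyr::pivot_wider(names_from = "pair_id", values_from = "flag",
                       values_fill = FALSE)
  out <- tibble(
    species = mat$species,
    n_pairs_with_ma = as.integer(rowSums(as.matrix(mat[, -1, drop = FALSE])))
  ) |>
    dplyr::mutate(flagged = .data$n_pairs_with_ma >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$n_pairs_with_ma), .data$species)
  attr(out, "flag_matrix") <- mat
  out
}
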