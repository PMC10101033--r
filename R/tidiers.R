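#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a primer evaluation
#'
#' @param x A `primer_evaluation` from [evaluate_primer_pairs()].
#' @param ... Unused.
#' @return Plain tibble, one row per pair per evaluation set.
#' @export
tidy.primer_evaluation <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "ma_flags") <- NULL
  class(out) <- setdiff(class(out), "primer_evaluation")
  out
}

#' One-row summary of a primer evaluation
#'
#' @param x A `primer_evaluation`.
#' @param ... Unused.
#' @return Tibble with pair counts and the best pair (highest SC-NMA,
#'   ties broken by lowest mean OF-MA) per evaluation set.
#' @export
glance.primer_evaluation <- function(x, ...) {
  tbl <- tidy(x)
  tbl |>
    dplyr::group_by(.data$domain) |>
    dplyr::arrange(dplyr::desc(.data$sc_nma_pct), .data$of_ma_mean,
                   .by_group = TRUE) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      best_pair = dplyr::first(.data$pair_id),
      best_sc_nma = dplyr::first(.data$sc_nma_pct),
      best_of_ma = dplyr::first(.data$of_ma_mean),
      .groups = "drop"
    )
}

#' Plot SC-NMA by primer pair
#'
#' Bar chart of SC-NMA per pair, faceted by evaluation set and coloured by
#' amplicon length category, with the detected-species coverage overlaid as
#' points (the gap between point and bar is the MA penalty).
#'
#' @param object A `primer_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.primer_evaluation <- function(object, ...) {
  tbl <- tidy(object)
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = stats::reorder(.data$pair_id, .data$sc_nma_pct),
    y = .data$sc_nma_pct,
    fill = .data$length_category
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_point(ggplot2::aes(y = .data$pct_species_detected),
                        shape = 21, fill = "white") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$domain)) +
    ggplot2::labs(
      x = NULL, y = "SC-NMA (%)", fill = "Length category",
      title = "Species coverage with no matching amplicons",
      subtitle = "points: conventional species coverage (%)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-species copy-number spectrum
#'
#' @param stats Per-unit table from [summarize_genomes()].
#' @param value `"genes"` or `"variants"`.
#' @return A ggplot object (histogram of species-mean copy numbers).
#' @export
plot_copy_number <- function(stats, value = c("genes", "variants")) {
  value <- match.arg(value)
  col <- if (value == "genes") "n_genes" else "n_variants"
  sp <- stats |>
    dplyr::group_by(.data$superkingdom, .data$species) |>
    dplyr::summarise(mean = mean(.data[[col]]), .groups = "drop")
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$mean)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = 0.5,
                            fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$superkingdom), scales = "free_y") +
    ggplot2::labs(
      x = sprintf("Mean 16S %s per genome", value),
      y = "Species"
    ) +
    ggplot2::theme_minimal()
}
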