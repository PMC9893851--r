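RESIDUE_CLASS_COLOURS <- c(
  positive = "#1f6fd6", negative = "#d62728", aromatic = "#e6b800",
  polar = "#2ca02c", nonpolar = "#000000"
)

#' Plot pool-screen or individual-peptide calls
#'
#' Bar plot of the mock-vs-immunized effect per stimulus with significance
#' marked, mirroring an ELISpot quantification panel.
#'
#' @param calls `epi_screen_calls` tibble from [screen_test()].
#' @return A ggplot object.
#' @export
plot_screen_calls <- function(calls) {
  stopifnot(inherits(calls, "epi_screen_calls"))
  df <- tidy(calls)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$stimulus, levels = unique(.data$stimulus)),
    y = .data$effect, fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$effect - .data$se,
                                        ymax = .data$effect + .data$se),
                           width = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey60")) +
    ggplot2::labs(x = "stimulus", y = "immunized - mock (spots/well)",
                  fill = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a sequence-logo frequency matrix
#'
#' Letters are drawn per position with height proportional to their
#' frequency and coloured by residue chemistry class (positive blue,
#' negative red, aromatic yellow, polar green, non-polar black).
#'
#' @param logo A `logo_matrix` from [position_frequency_matrix()].
#' @return A ggplot object.
#' @export
plot_logo <- function(logo) {
  stopifnot(inherits(logo, "logo_matrix"))
  df <- logo |>
    group_by(.data$position) |>
    arrange(.data$frequency, .by_group = TRUE) |>
    mutate(ymax = cumsum(.data$frequency),
           ymin = .data$ymax - .data$frequency,
           ymid = (.data$ymin + .data$ymax) / 2) |>
    ungroup()
  ggplot2::ggplot(df) +
    ggplot2::geom_text(
      ggplot2::aes(x = .data$position, y = .data$ymid, label = .data$residue,
                   size = .data$frequency, colour = .data$class),
      fontface = "bold", show.legend = c(size = FALSE, colour = TRUE)
    ) +
    ggplot2::scale_size_continuous(range = c(1.5, 8)) +
    ggplot2::scale_colour_manual(values = RESIDUE_CLASS_COLOURS) +
    ggplot2::scale_x_continuous(breaks = unique(df$position)) +
    ggplot2::labs(x = "position", y = "frequency", colour = "chemistry") +
    ggplot2::theme_minimal()
}

#' Plot per-allele peptide-length distributions
#'
#' @param dist Tibble from [length_distribution()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = factor(.data$length),
                                     y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~allele) +
    ggplot2::labs(x = "peptide length (aa)", y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' Plot proteome coverage by identified epitopes
#'
#' @param coverage Tibble from [proteome_coverage()].
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage) {
  ggplot2::ggplot(coverage, ggplot2::aes(
    x = factor(.data$protein, levels = unique(.data$protein)),
    y = .data$fraction
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~allele) +
    ggplot2::labs(x = "viral protein", y = "fraction of residues covered") +
    ggplot2::theme_minimal()
}

#' Plot the ICS-ELISpot pairing
#'
#' @param paired Tibble with `elispot_mean` and `ics_mean` columns (one row
#'   per epitope).
#' @return A ggplot object with the least-squares line.
#' @export
plot_ics_correlation <- function(paired) {
  ggplot2::ggplot(paired, ggplot2::aes(x = .data$elispot_mean,
                                       y = .data$ics_mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2182b") +
    ggplot2::labs(x = "IFN-γ ELISpot (spots/well)",
                  y = "% IFN-γ+ CD8+ T cells") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.epi_screen_calls <- function(object, ...) plot_screen_calls(object)

#' @export
autoplot.logo_matrix <- function(object, ...) plot_logo(object)
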