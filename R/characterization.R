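#' Previously described MHC-I epitopes for the VSV-GP proteome
#'
#' The literature-described C57BL/6 epitopes within the VSV-GP proteome used
#' for novelty annotation: the H2-Kb VSV-N epitope RGYVYQGL (N 52-59), the
#' H2-Kb LCMV-GP epitopes AVYNFATC (GP 34-41) and LNHNFCNL (GP 118-125), and
#' the H2-Db LCMV-GP epitope KAVYNFATC (GP 33-41, overlapping AVYNFATC but
#' presented by the other allele).
#'
#' @return Tibble with columns `allele`, `sequence`, `protein`, `start`,
#'   `end`.
#' @export
known_epitopes <- function() {
  tibble(
    allele = c("H2-Kb", "H2-Kb", "H2-Kb", "H2-Db"),
    sequence = c("RGYVYQGL", "AVYNFATC", "LNHNFCNL", "KAVYNFATC"),
    protein = c("N", "GP", "GP", "GP"),
    start = c(52L, 34L, 118L, 33L),
    end = c(59L, 41L, 125L, 41L)
  )
}

#' Annotate epitope hits for novelty against known epitopes
#'
#' A hit is "known" only when its allele AND sequence both match a
#' previously described epitope: the same sequence presented by a different
#' allele is a novel finding.
#'
#' @param hits Tibble with columns `allele` and `sequence`.
#' @param known Known-epitope tibble (default [known_epitopes()]).
#' @return `hits` with a logical `known` column appended.
#' @export
annotate_novelty <- function(hits, known = known_epitopes()) {
  stopifnot(is.data.frame(hits), all(c("allele", "sequence") %in% names(hits)))
  key <- paste(known$allele, known$sequence)
  mutate(hits, known = paste(.data$allele, .data$sequence) %in% key)
}

#' Position frequency matrix for a set of epitope sequences
#'
#' Left-aligned counting (every peptide starts at position one of the logo):
#' position p's sample size is the number of peptides of length >= p, and
#' frequency(p, residue) = count / positional sample size, so frequencies at
#' every occupied position sum to one even with mixed peptide lengths.
#'
#' @param sequences Character vector of peptide sequences (>= 1).
#' @return A tibble of class `logo_matrix` with columns `position`,
#'   `residue`, `count`, `n`, `frequency` and `class` (the 5-class WebLogo
#'   chemistry of the residue, see [residue_class()]); only observed
#'   (position, residue) pairs are listed.
#' @examples
#' position_frequency_matrix(c("RGYVYQGL", "LNHNFCNL", "AVYNFATC"))
#' @export
position_frequency_matrix <- function(sequences) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  stopifnot(is.character(sequences))
  if (length(sequences) == 0) abort("Need at least one sequence for a logo matrix.")
  check_aa(sequences, what = "peptide")
  chars <- strsplit(sequences, "", fixed = TRUE)
  out <- purrr::map_dfr(chars, function(ch) {
    tibble(position = seq_along(ch), residue = ch)
  }) |>
    count(.data$position, .data$residue, name = "count") |>
    group_by(.data$position) |>
    mutate(n = sum(.data$count), frequency = .data$count / .data$n) |>
    ungroup() |>
    mutate(class = residue_class(.data$residue)) |>
    arrange(.data$position, desc(.data$frequency), .data$residue)
  class(out) <- c("logo_matrix", class(out))
  out
}

#' Five-class chemistry of an amino-acid residue
#'
#' The WebLogo-style colour classes: positively charged (K, R, H),
#' negatively charged (D, E), aromatic (F, Y, W), polar (S, T, N, Q, C, G)
#' and non-polar (A, V, L, I, M, P).
#'
#' @param residue Character vector of single-letter residues.
#' @param classes Named list mapping class label -> residue set (override to
#'   reassign C/G, for instance).
#' @return Character vector of class labels.
#' @examples
#' residue_class(c("F", "D", "L"))
#' @export
residue_class <- function(residue,
                          classes = list(
                            positive = c("K", "R", "H"),
                            negative = c("D", "E"),
                            aromatic = c("F", "Y", "W"),
                            polar = c("S", "T", "N", "Q", "C", "G"),
                            nonpolar = c("A", "V", "L", "I", "M", "P")
                          )) {
  stopifnot(is.character(residue))
  map <- unlist(lapply(names(classes), function(cl) {
    setNames(rep(cl, length(classes[[cl]])), classes[[cl]])
  }))
  bad <- setdiff(unique(residue), names(map))
  if (length(bad) > 0) abort(sprintf("Invalid residue(s): %s", toString(bad)))
  unname(map[residue])
}

#' Relative peptide-length distribution per allele
#'
#' @param hits Tibble with columns `allele` and `length` (or `sequence`).
#' @param lengths Lengths to report (default 8:11); absent lengths get
#'   frequency 0.
#' @return Tibble with columns `allele`, `length`, `count`, `total`,
#'   `frequency`; frequencies sum to 1 within each allele.
#' @export
length_distribution <- function(hits, lengths = 8:11) {
  stopifnot(is.data.frame(hits), "allele" %in% names(hits))
  if (!"length" %in% names(hits)) {
    stopifnot("sequence" %in% names(hits))
    hits$length <- nchar(hits$sequence)
  }
  if (nrow(hits) == 0) abort("Need at least one hit per allele.")
  hits |>
    count(.data$allele, length = factor(.data$length, levels = lengths),
          name = "count", .drop = FALSE) |>
    group_by(.data$allele) |>
    mutate(total = sum(.data$count), frequency = .data$count / .data$total) |>
    ungroup() |>
    mutate(length = as.integer(as.character(.data$length)))
}

#' Proteome coverage by identified epitopes
#'
#' For each (allele, protein): the number of residues covered by the union
#' of the epitope intervals, divided by the protein length. Because epitopes
#' can overlap, a literal "summed" variant (interval lengths added with
#' double counting) is reported alongside; only the union fraction is
#' bounded by 1.
#'
#' @param hits Tibble with columns `allele`, `protein`, `start`, `end`.
#' @param proteome Proteome tibble (see [as_proteome()]).
#' @return Tibble with one row per allele x protein: `covered_residues`
#'   (union), `summed_residues`, `protein_length`, `fraction`
#'   (union/length), `summed_fraction`.
#' @export
proteome_coverage <- function(hits, proteome) {
  stopifnot(is.data.frame(hits), is.data.frame(proteome),
            all(c("allele", "protein", "start", "end") %in% names(hits)))
  plen <- setNames(proteome$length, proteome$protein)
  bad <- hits |>
    filter(!.data$protein %in% names(plen) |
             .data$start < 1 | .data$end > plen[.data$protein])
  if (nrow(bad) > 0) {
    abort(sprintf("Hit coordinates outside protein bounds: %s",
                  toString(paste0(bad$protein, ":", bad$start, "-", bad$end))))
  }
  grid <- tidyr::expand_grid(
    allele = unique(hits$allele),
    protein = proteome$protein
  )
  cov <- hits |>
    group_by(.data$allele, .data$protein) |>
    summarise(
      covered_residues = length(unique(unlist(
        purrr::map2(.data$start, .data$end, seq)
      ))),
      summed_residues = sum(.data$end - .data$start + 1L),
      .groups = "drop"
    )
  grid |>
    left_join(cov, by = c("allele", "protein")) |>
    mutate(
      covered_residues = tidyr::replace_na(.data$covered_residues, 0L),
      summed_residues = tidyr::replace_na(.data$summed_residues, 0L),
      protein_length = unname(plen[.data$protein]),
      fraction = .data$covered_residues / .data$protein_length,
      summed_fraction = .data$summed_residues / .data$protein_length
    )
}
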