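#' Dissimilarity of peptides to a host proteome
#'
#' Screens candidate peptides against the host (self) proteome so that
#' self-identical peptides — against which T cells are centrally tolerized —
#' can be excluded, and near-self peptides deprioritized. The score is a
#' transparent best-window identity complement: for each peptide, every
#' same-length ungapped window of every host protein is compared and the
#' score is `1 - max identity fraction`. A peptide occurring verbatim in the
#' host proteome scores exactly 0; a peptide sharing no residue with any
#' window scores 1.
#'
#' @param peptides Character vector of peptide sequences (length >= 8 each),
#'   or a candidate tibble with a `sequence` column.
#' @param host A proteome tibble (see [as_proteome()]) for the host species.
#' @return Numeric vector in \[0, 1\], one score per peptide (per row for a
#'   tibble input). Duplicated sequences are scored once and recycled.
#' @examples
#' host <- as_proteome(c(h1 = "MAAAAKLLWWSRV"))
#' dissimilarity_score(c("AAAAKLLW", "AAAAKLLY"), host)
#' @export
dissimilarity_score <- function(peptides, host) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  stopifnot(is.character(peptides))
  if (!is.data.frame(host) || nrow(host) == 0) {
    abort("Host proteome is empty; dissimilarity screening needs host sequences.")
  }
  if (length(peptides) == 0) return(numeric(0))
  if (any(nchar(peptides) < 8)) abort("Peptides must be at least 8 residues long.")
  check_aa(peptides, what = "peptide")

  uniq <- unique(peptides)
  by_len <- split(uniq, nchar(uniq))
  scores <- setNames(numeric(length(uniq)), uniq)
  for (len_chr in names(by_len)) {
    k <- as.integer(len_chr)
    pep <- by_len[[len_chr]]
    # all host windows of length k as a (windows x k) character matrix
    win <- unlist(lapply(host$sequence, function(s) {
      L <- nchar(s)
      if (L < k) return(character(0))
      substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    }), use.names = FALSE)
    if (length(win) == 0) {
      scores[pep] <- 1
      next
    }
    W <- matrix(unlist(strsplit(win, "", fixed = TRUE), use.names = FALSE),
                nrow = length(win), byrow = TRUE)
    P <- matrix(unlist(strsplit(pep, "", fixed = TRUE), use.names = FALSE),
                nrow = length(pep), byrow = TRUE)
    for (i in seq_along(pep)) {
      matches <- 0L
      for (j in seq_len(k)) matches <- matches + (W[, j] == P[i, j])
      scores[pep[i]] <- 1 - max(matches) / k
    }
  }
  unname(scores[peptides])
}

#' Fraction of hydrophobic residues in a peptide
#'
#' Annotation only: hydrophobicity is reported alongside the ranking but is
#' never used as a ranking key. The default hydrophobic set is the
#' conventional Kyte-Doolittle-positive residues.
#'
#' @param peptides Character vector of peptide sequences.
#' @param hydrophobic Character vector of residues counted as hydrophobic.
#' @return Numeric vector in \[0, 1\].
#' @examples
#' hydrophobic_fraction(c("LLLL", "LLSS", "SSSS"))
#' @export
hydrophobic_fraction <- function(peptides,
                                 hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C")) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  stopifnot(is.character(peptides))
  if (length(peptides) == 0) return(numeric(0))
  check_aa(peptides, what = "peptide")
  vapply(strsplit(peptides, "", fixed = TRUE),
         function(ch) mean(ch %in% hydrophobic), numeric(1))
}

#' Rank consensus records by binding tier, stability and dissimilarity
#'
#' Orders each allele's candidates by strict lexicographic priority:
#' consensus tier key (descending — e.g. `3-3-3` beats `3-3-2`), then
#' predicted-stability percentile rank (ascending — lower rank means a more
#' stable peptide-MHC complex), then dissimilarity to the host proteome
#' (descending), with `peptide_id` as the final deterministic tie-break.
#' Candidates identical to a host-proteome window (dissimilarity 0) are
#' excluded before ranking, so quotas are filled from eligible peptides only.
#'
#' @param consensus Consensus tibble from [build_consensus()], joined with
#'   candidate metadata (`protein`, `gene_order_index`, `start`, `end`,
#'   `length`, `sequence`) from [enumerate_peptides()].
#' @param dissimilarities Either a numeric vector aligned with `consensus`
#'   rows or `NULL` if `consensus` already carries a `dissimilarity` column.
#' @return The input rows with dissimilarity-0 candidates removed, a
#'   `hydrophobic_fraction` annotation, and an integer `rank_position`
#'   (1 = best) assigned within each allele.
#' @export
rank_candidates <- function(consensus, dissimilarities = NULL) {
  stopifnot(is.data.frame(consensus))
  if (!is.null(dissimilarities)) {
    stopifnot(length(dissimilarities) == nrow(consensus))
    consensus$dissimilarity <- dissimilarities
  }
  need <- c("peptide_id", "allele", "k1", "k2", "k3", "stability_rank",
            "dissimilarity")
  if (!all(need %in% names(consensus))) {
    abort(sprintf("rank_candidates() needs columns: %s",
                  toString(setdiff(need, names(consensus)))))
  }
  if (any(is.na(consensus$dissimilarity))) {
    abort("Every candidate needs a dissimilarity score before ranking.")
  }
  out <- consensus |>
    filter(.data$dissimilarity > 0) |>
    arrange(
      .data$allele,
      desc(.data$k1), desc(.data$k2), desc(.data$k3),
      .data$stability_rank,
      desc(.data$dissimilarity),
      .data$peptide_id
    ) |>
    group_by(.data$allele) |>
    mutate(rank_position = row_number()) |>
    ungroup()
  if ("sequence" %in% names(out)) {
    out$hydrophobic_fraction <- hydrophobic_fraction(out$sequence)
  }
  out
}

#' Default per-protein selection quota
#'
#' Decreasing candidate quotas follow the 3'-to-5' expression gradient of
#' the viral genome: the most-expressed protein (N) contributes the most
#' candidates, the polymerase (L) the fewest. Totals 50 per allele.
#'
#' @return Named integer vector `c(N = 15, P = 15, M = 10, GP = 5, L = 5)`.
#' @export
default_quota <- function() {
  c(N = 15L, P = 15L, M = 10L, GP = 5L, L = 5L)
}

#' Select the top-ranked candidates per protein quota
#'
#' Takes, for each protein, its best-ranked candidates up to the quota
#' (selection is per protein, not by interleaved global rank), then orders
#' the selected set by gene order and genome position and assigns the
#' block-numbered `candidate_id`: with the default quota the N block is
#' N1-N15, P is P16-P30, M is M31-M40, GP is GP41-GP45 and L is L46-L50,
#' within each block in order of position in the protein.
#'
#' @param ranked Ranked tibble from [rank_candidates()] for one or more
#'   alleles; must carry `protein`, `gene_order_index` and `start`.
#' @param quota Named integer vector protein -> count; see [default_quota()].
#' @return Tibble of selected candidates with `candidate_id` and
#'   `within_protein_rank`, ordered by allele, gene order, then start.
#' @export
select_by_quota <- function(ranked, quota = default_quota()) {
  stopifnot(is.data.frame(ranked), !is.null(names(quota)), all(quota >= 0))
  need <- c("peptide_id", "allele", "protein", "gene_order_index", "start",
            "rank_position")
  if (!all(need %in% names(ranked))) {
    abort(sprintf("select_by_quota() needs columns: %s",
                  toString(setdiff(need, names(ranked)))))
  }
  sel <- purrr::map_dfr(unique(ranked$allele), function(al) {
    sub <- filter(ranked, .data$allele == al)
    avail <- table(factor(sub$protein, levels = names(quota)))
    short <- quota[quota > avail[names(quota)]]
    if (length(short) > 0) {
      p <- names(short)[1]
      abort(sprintf(
        "Allele %s: protein %s has only %d eligible candidate(s) for a quota of %d (shortfalls: %s).",
        al, p, avail[[p]], quota[[p]],
        paste(sprintf("%s=%d/%d", names(short), avail[names(short)], short),
              collapse = ", ")
      ))
    }
    sub |>
      filter(.data$protein %in% names(quota)) |>
      group_by(.data$protein) |>
      arrange(.data$rank_position, .by_group = TRUE) |>
      mutate(within_protein_rank = row_number()) |>
      filter(.data$within_protein_rank <= quota[as.character(first(.data$protein))]) |>
      ungroup()
  })
  sel <- sel |>
    arrange(.data$allele, .data$gene_order_index, .data$start, .data$peptide_id) |>
    group_by(.data$allele) |>
    mutate(candidate_id = paste0(.data$protein, row_number())) |>
    ungroup() |>
    relocate("candidate_id")
  sel
}
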