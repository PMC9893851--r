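#' Read a proteome FASTA in a configured gene order
#'
#' Reads an amino-acid FASTA file and returns one row per protein, ordered by
#' the supplied gene order rather than by file order. For non-segmented
#' negative-strand RNA viruses the gene order encodes the 3'-to-5'
#' transcription gradient (for VSV-GP: N, P, M, GP, L), which downstream
#' quota selection and pool design rely on.
#'
#' FASTA record names are matched to `gene_order` by their first whitespace
#' -delimited token. Sequences are uppercased and trailing stop characters
#' (`*`) are stripped; any remaining non-standard residue letter is an error.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param gene_order Character vector of protein names, in genome order.
#'   Every name must match exactly one FASTA record.
#' @return A tibble with columns `protein`, `sequence`, `gene_order_index`
#'   and `length`, one row per protein in gene order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P", "MSLSKV", ">N", "MDKSWW"), fa)
#' read_proteome(fa, gene_order = c("N", "P"))
#' @export
read_proteome <- function(path, gene_order) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: '%s'", path))
  }
  stopifnot(is.character(gene_order), length(gene_order) >= 1)
  aa <- Biostrings::readAAStringSet(path)
  nm <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate FASTA record name(s): %s", toString(dup)))
  }
  missing <- setdiff(gene_order, nm)
  if (length(missing) > 0) {
    abort(sprintf(
      "Configured gene-order protein(s) missing from FASTA: %s",
      toString(missing)
    ))
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  names(seqs) <- nm
  seqs <- seqs[gene_order]
  if (any(nchar(seqs) == 0)) {
    abort(sprintf(
      "Empty sequence for record '%s'", gene_order[which(nchar(seqs) == 0)[1]]
    ))
  }
  for (i in seq_along(seqs)) check_aa(seqs[[i]], what = paste0("record ", gene_order[i]))
  as_proteome(tibble(protein = gene_order, sequence = unname(seqs)))
}

#' Build a proteome table from named sequences
#'
#' Lightweight constructor used by the simulator and tests; applies the same
#' validation as [read_proteome()].
#'
#' @param x A tibble with columns `protein` and `sequence` (rows already in
#'   gene order), or a named character vector of sequences.
#' @return A validated proteome tibble (columns `protein`, `sequence`,
#'   `gene_order_index`, `length`).
#' @export
as_proteome <- function(x) {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble(protein = names(x), sequence = unname(x))
  }
  stopifnot(is.data.frame(x), all(c("protein", "sequence") %in% names(x)))
  if (anyDuplicated(x$protein)) abort("Duplicate protein names in proteome.")
  if (any(nchar(x$sequence) == 0)) abort("Proteome sequences must be non-empty.")
  seqs <- toupper(x$sequence)
  for (i in seq_len(nrow(x))) check_aa(seqs[i], what = paste0("record ", x$protein[i]))
  tibble(
    protein = x$protein,
    sequence = seqs,
    gene_order_index = seq_len(nrow(x)),
    length = nchar(seqs)
  )
}

#' Enumerate candidate peptides of given lengths from a proteome
#'
#' Slides windows of each requested length over every protein and emits one
#' candidate per (protein, start, length), crossed with the requested MHC-I
#' alleles. For a protein of length L a window length k contributes
#' `max(L - k + 1, 0)` peptides, so lengths 8-11 on a protein with L >= 11
#' give `4L - 34` candidates.
#'
#' Coordinates are 1-based inclusive, matching the convention used for
#' published epitope positions (e.g. VSV-N 52-59). Each peptide carries a
#' stable `peptide_id` of the form `<protein>_<start>_<length>`; the
#' block-numbered `candidate_id` (N1, GP42, ...) is assigned only after quota
#' selection by [select_by_quota()].
#'
#' @param proteome A proteome tibble from [read_proteome()] or [as_proteome()].
#' @param lengths Integer vector of peptide lengths (default `8:11`).
#' @param alleles Character vector of MHC-I allele labels
#'   (default `c("H2-Db", "H2-Kb")`).
#' @return A tibble with columns `peptide_id`, `allele`, `protein`,
#'   `gene_order_index`, `start`, `end`, `length`, `sequence`, ordered by
#'   allele, gene order, start, then length.
#' @examples
#' prot <- as_proteome(c(N = "MDKSWWKLIHA"))
#' enumerate_peptides(prot, lengths = 8:11, alleles = "H2-Kb")
#' @export
enumerate_peptides <- function(proteome, lengths = 8:11,
                               alleles = c("H2-Db", "H2-Kb")) {
  stopifnot(is.data.frame(proteome), length(alleles) >= 1)
  lengths <- sort(unique(as.integer(lengths)))
  if (length(lengths) == 0) {
    return(tibble(
      peptide_id = character(), allele = character(), protein = character(),
      gene_order_index = integer(), start = integer(), end = integer(),
      length = integer(), sequence = character()
    ))
  }
  if (min(lengths) < 1) abort("Peptide lengths must be >= 1.")
  per_protein <- purrr::pmap(
    list(proteome$protein, proteome$sequence, proteome$gene_order_index),
    function(protein, sequence, idx) {
      L <- nchar(sequence)
      grid <- purrr::map_dfr(lengths, function(k) {
        if (k > L) return(NULL)  # too long for this protein: contributes nothing
        tibble(start = seq_len(L - k + 1L), length = k)
      })
      if (nrow(grid) == 0) return(NULL)
      grid |>
        mutate(
          protein = protein,
          gene_order_index = idx,
          end = .data$start + .data$length - 1L,
          sequence = substring(sequence, .data$start, .data$end),
          peptide_id = sprintf("%s_%d_%d", protein, .data$start, .data$length)
        ) |>
        arrange(.data$start, .data$length)
    }
  )
  base <- bind_rows(per_protein)
  out <- tidyr::expand_grid(allele = alleles, base) |>
    arrange(.data$allele, .data$gene_order_index, .data$start, .data$length) |>
    select(
      "peptide_id", "allele", "protein", "gene_order_index",
      "start", "end", "length", "sequence"
    )
  out
}
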