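#' Classify predicted binder strength from a percentile rank
#'
#' Percentile ranks express a predictor's binding score for a peptide as its
#' rank among random background peptides for the same allele; lower means
#' stronger predicted binding. Ranks below 0.5% are strong binders, 0.5-2%
#' weak, 2-3% marginal, and anything at or above 3% a non-binder. Boundaries
#' are half-open with the boundary value assigned to the weaker tier, so each
#' rank belongs to exactly one tier.
#'
#' @param percentile_rank Numeric vector of percentile ranks in \[0, 100\].
#' @param thresholds Increasing numeric vector of the three tier cutoffs,
#'   default `c(0.5, 2, 3)` (%).
#' @return Character vector with values `"strong"`, `"weak"`, `"marginal"`,
#'   `"non_binder"`.
#' @seealso [binder_ordinal()] for the strong=3 ... non_binder=0 encoding.
#' @examples
#' categorize_binder(c(0.3, 0.5, 2, 2.9, 50))
#' @export
categorize_binder <- function(percentile_rank, thresholds = c(0.5, 2, 3)) {
  stopifnot(is.numeric(percentile_rank), length(thresholds) == 3,
            all(diff(thresholds) > 0))
  if (any(is.na(percentile_rank)) ||
      any(percentile_rank < 0 | percentile_rank > 100)) {
    abort("Percentile ranks must lie in [0, 100] and be non-missing.")
  }
  out <- rep("non_binder", length(percentile_rank))
  out[percentile_rank < thresholds[3]] <- "marginal"
  out[percentile_rank < thresholds[2]] <- "weak"
  out[percentile_rank < thresholds[1]] <- "strong"
  out
}

#' Ordinal encoding of binder categories
#'
#' @param category Character vector of binder category labels.
#' @return Integer vector: strong = 3, weak = 2, marginal = 1, non_binder = 0.
#' @export
binder_ordinal <- function(category) {
  map <- c(strong = 3L, weak = 2L, marginal = 1L, non_binder = 0L)
  bad <- setdiff(unique(category), names(map))
  if (length(bad) > 0) abort(sprintf("Unknown binder category: %s", toString(bad)))
  unname(map[category])
}

PREDICTION_TOOLS <- c("binding_A", "binding_B", "stability")

#' Import one predictor's rank table
#'
#' Reads a TSV/CSV of percentile ranks for one prediction tool and returns a
#' long-format record table. The three predictor slots are abstract
#' (`binding_A`, `binding_B`, `stability`) so synthetic tables and tables
#' exported from external prediction servers are interchangeable.
#'
#' Rows whose `peptide_id` is not in `expected` are dropped with a warning;
#' expected candidates missing from the table are reported as coverage gaps
#' (attribute `"gaps"` plus a warning) and later treated as non-binders by
#' [build_consensus()].
#'
#' @param path Path to a delimited file with columns `peptide_id`, `allele`,
#'   `percentile_rank` (names configurable via `col_map`).
#' @param tool One of `"binding_A"`, `"binding_B"`, `"stability"`.
#' @param expected Optional tibble of expected candidates (columns
#'   `peptide_id`, `allele`), typically from [enumerate_peptides()].
#' @param col_map Named character vector mapping the standard column names to
#'   the file's column names.
#' @return Tibble with columns `peptide_id`, `allele`, `tool`,
#'   `percentile_rank`; attribute `"gaps"` holds expected rows not covered.
#' @export
import_prediction_table <- function(path, tool, expected = NULL,
                                    col_map = c(peptide_id = "peptide_id",
                                                allele = "allele",
                                                percentile_rank = "percentile_rank")) {
  tool <- match.arg(tool, PREDICTION_TOOLS)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  need <- unname(col_map)
  if (!all(need %in% names(raw))) {
    abort(sprintf("Prediction table '%s' lacks column(s): %s",
                  path, toString(setdiff(need, names(raw)))))
  }
  tab <- tibble(
    peptide_id = raw[[col_map[["peptide_id"]]]],
    allele = raw[[col_map[["allele"]]]],
    rank_chr = raw[[col_map[["percentile_rank"]]]]
  )
  rank <- suppressWarnings(as.numeric(tab$rank_chr))
  if (any(is.na(rank))) {
    abort(sprintf("Unparseable percentile rank in row %d of '%s' (value '%s').",
                  which(is.na(rank))[1], path, tab$rank_chr[which(is.na(rank))[1]]))
  }
  tab <- tab |> mutate(percentile_rank = rank, tool = tool) |>
    select("peptide_id", "allele", "tool", "percentile_rank")
  if (any(tab$percentile_rank < 0 | tab$percentile_rank > 100)) {
    abort("Percentile ranks must lie in [0, 100].")
  }
  if (anyDuplicated(tab[c("peptide_id", "allele", "tool")])) {
    abort(sprintf("Duplicate (peptide_id, allele) rows in '%s'.", path))
  }
  gaps <- tibble(peptide_id = character(), allele = character())
  if (!is.null(expected)) {
    exp_keys <- distinct(expected[, c("peptide_id", "allele")])
    unknown <- anti_join(tab, exp_keys, by = c("peptide_id", "allele"))
    if (nrow(unknown) > 0) {
      warn(sprintf("%d row(s) in '%s' reference unknown candidates; dropped.",
                   nrow(unknown), path))
      tab <- inner_join(tab, exp_keys, by = c("peptide_id", "allele"))
    }
    gaps <- anti_join(exp_keys, tab, by = c("peptide_id", "allele"))
    if (nrow(gaps) > 0) {
      warn(sprintf("Tool '%s': %d expected candidate(s) missing from '%s' (coverage gap).",
                   tool, nrow(gaps), path))
    }
  }
  attr(tab, "gaps") <- gaps
  tab
}

#' Build the per-candidate cross-tool consensus record
#'
#' Collapses long-format prediction records (one row per peptide, allele and
#' tool) into one consensus row per (peptide, allele). Each tool's percentile
#' rank is categorized with [categorize_binder()]; the consensus key is the
#' three category ordinals sorted in decreasing order (so it depends only on
#' the multiset of categories, not on tool order). The stability tool's
#' percentile rank is carried along as `stability_rank`.
#'
#' A candidate missing a tool slot is scored `non_binder` for that slot; the
#' gap is counted in the `n_missing_tools` column rather than dropping the
#' candidate, so coverage gaps stay visible in the ranking.
#'
#' @param predictions Tibble with columns `peptide_id`, `allele`, `tool`,
#'   `percentile_rank` (tools among `binding_A`, `binding_B`, `stability`).
#' @param thresholds Tier cutoffs passed to [categorize_binder()].
#' @return Tibble with one row per (peptide_id, allele): category columns
#'   `cat_binding_A`, `cat_binding_B`, `cat_stability`, the sorted ordinal
#'   key columns `k1 >= k2 >= k3`, its display form `consensus_key` (e.g.
#'   `"3-3-2"`), `stability_rank` and `n_missing_tools`.
#' @export
build_consensus <- function(predictions, thresholds = c(0.5, 2, 3)) {
  stopifnot(is.data.frame(predictions),
            all(c("peptide_id", "allele", "tool", "percentile_rank") %in%
                  names(predictions)))
  bad <- setdiff(unique(predictions$tool), PREDICTION_TOOLS)
  if (length(bad) > 0) abort(sprintf("Unknown tool slot(s): %s", toString(bad)))
  if (anyDuplicated(predictions[c("peptide_id", "allele", "tool")])) {
    abort("Duplicate (peptide_id, allele, tool) prediction records.")
  }
  wide <- predictions |>
    mutate(category = categorize_binder(.data$percentile_rank, thresholds)) |>
    select("peptide_id", "allele", "tool", "percentile_rank", "category") |>
    tidyr::pivot_wider(
      names_from = "tool",
      values_from = c("percentile_rank", "category")
    )
  # ensure all three slots exist even if a whole tool table is absent
  for (t in PREDICTION_TOOLS) {
    pc <- paste0("percentile_rank_", t)
    cc <- paste0("category_", t)
    if (!pc %in% names(wide)) wide[[pc]] <- NA_real_
    if (!cc %in% names(wide)) wide[[cc]] <- NA_character_
  }
  n_missing <- rowSums(is.na(wide[paste0("category_", PREDICTION_TOOLS)]))
  if (any(n_missing > 0)) {
    inform(sprintf(
      "%d candidate(s) missing one or more tool records; missing slots scored non_binder.",
      sum(n_missing > 0)
    ))
  }
  cats <- lapply(PREDICTION_TOOLS, function(t) {
    x <- wide[[paste0("category_", t)]]
    x[is.na(x)] <- "non_binder"
    x
  })
  ords <- vapply(cats, binder_ordinal, integer(nrow(wide)))
  if (nrow(wide) == 1) ords <- matrix(ords, nrow = 1)
  key <- t(apply(ords, 1, sort, decreasing = TRUE))
  tibble(
    peptide_id = wide$peptide_id,
    allele = wide$allele,
    cat_binding_A = cats[[1]],
    cat_binding_B = cats[[2]],
    cat_stability = cats[[3]],
    k1 = key[, 1], k2 = key[, 2], k3 = key[, 3],
    consensus_key = paste(key[, 1], key[, 2], key[, 3], sep = "-"),
    stability_rank = wide$percentile_rank_stability,
    n_missing_tools = as.integer(n_missing)
  )
}
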