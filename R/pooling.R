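#' Design a horizontal/vertical peptide pool matrix
#'
#' Arranges one allele's selected peptides on an r x c grid, filling cells
#' row-major in the supplied order (gene order, not overall rank). Each
#' peptide then belongs to exactly two pools: the horizontal pool of its row
#' and the vertical pool of its column, so a responding peptide sits at the
#' intersection of two positive pools. Pools are labelled 1..r for rows and
#' r+1..r+c for columns (14 pools for the default 7 x 7 grid).
#'
#' When there are more peptides than grid cells (50 on a 7 x 7 grid), the
#' overflow peptides are co-placed deterministically starting from the first
#' cell, so with 50 peptides exactly one cell holds two peptides. Capacity is
#' two peptides per cell.
#'
#' @param selected Tibble of one allele's selected candidates in the order
#'   they should fill the grid (from [select_by_quota()]); needs a
#'   `candidate_id` column and at most one allele.
#' @param n_horizontal,n_vertical Grid dimensions (default 7 and 7).
#' @return A tibble of class `pool_matrix` with columns `candidate_id`,
#'   `cell_row`, `cell_col`, `pool_h`, `pool_v` and attributes
#'   `n_horizontal`, `n_vertical`, `allele`, `pool_labels`.
#' @examples
#' sel <- tibble::tibble(candidate_id = paste0("N", 1:9))
#' design_pool_matrix(sel, n_horizontal = 3, n_vertical = 3)
#' @export
design_pool_matrix <- function(selected, n_horizontal = 7, n_vertical = 7) {
  stopifnot(is.data.frame(selected), "candidate_id" %in% names(selected))
  if (n_horizontal < 2 || n_vertical < 2) {
    abort("Pool grid needs at least 2 horizontal and 2 vertical pools.")
  }
  if ("allele" %in% names(selected) && length(unique(selected$allele)) > 1) {
    abort("design_pool_matrix() expects a single allele's selection.")
  }
  if (anyDuplicated(selected$candidate_id)) abort("Duplicate candidate_id.")
  n <- nrow(selected)
  if (n == 0) abort("No peptides to pool.")
  cells <- n_horizontal * n_vertical
  if (n > 2 * cells) {
    abort(sprintf("%d peptides exceed the %d x %d grid capacity of %d (two per cell).",
                  n, n_horizontal, n_vertical, 2 * cells))
  }
  idx <- seq_len(n)
  cell <- ifelse(idx <= cells, idx, idx - cells)  # overflow restarts at cell 1
  row <- ((cell - 1L) %/% n_vertical) + 1L
  col <- ((cell - 1L) %% n_vertical) + 1L
  out <- tibble(
    candidate_id = selected$candidate_id,
    cell_row = as.integer(row),
    cell_col = as.integer(col),
    pool_h = as.integer(row),
    pool_v = as.integer(n_horizontal + col)
  )
  attr(out, "n_horizontal") <- as.integer(n_horizontal)
  attr(out, "n_vertical") <- as.integer(n_vertical)
  attr(out, "allele") <- if ("allele" %in% names(selected) && n > 0)
    selected$allele[1] else NA_character_
  attr(out, "pool_labels") <- seq_len(n_horizontal + n_vertical)
  class(out) <- c("pool_matrix", class(out))
  out
}

#' List the peptides in each pool
#'
#' @param matrix A `pool_matrix` from [design_pool_matrix()].
#' @return Long tibble with columns `pool`, `orientation`
#'   (`"horizontal"`/`"vertical"`) and `candidate_id`; each peptide appears
#'   exactly twice (once per orientation).
#' @export
pool_contents <- function(matrix) {
  stopifnot(inherits(matrix, "pool_matrix"))
  bind_rows(
    tibble(pool = matrix$pool_h, orientation = "horizontal",
           candidate_id = matrix$candidate_id),
    tibble(pool = matrix$pool_v, orientation = "vertical",
           candidate_id = matrix$candidate_id)
  ) |>
    arrange(.data$pool, .data$candidate_id)
}

#' Deconvolve significant pools to individual candidate peptides
#'
#' Crossing out the non-significant pools leaves the peptides whose
#' horizontal AND vertical pools were both called significant; these are the
#' candidates carried forward to individual testing.
#'
#' @param matrix A `pool_matrix` from [design_pool_matrix()].
#' @param significant_pools Integer vector of significant pool labels
#'   (subset of the matrix's labels).
#' @return Tibble of surviving rows of `matrix` (possibly empty), with
#'   attribute `significant_pools`.
#' @export
deconvolve_pools <- function(matrix, significant_pools) {
  stopifnot(inherits(matrix, "pool_matrix"))
  significant_pools <- unique(as.integer(significant_pools))
  unknown <- setdiff(significant_pools, attr(matrix, "pool_labels"))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown pool label(s): %s", toString(unknown)))
  }
  out <- matrix |>
    filter(.data$pool_h %in% significant_pools &
             .data$pool_v %in% significant_pools) |>
    as_tibble()
  attr(out, "significant_pools") <- significant_pools
  out
}
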