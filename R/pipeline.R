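#' Published per-allele epitope hit identifiers
#'
#' The candidate labels of the validated VSV-GP T-cell epitopes in C57BL/6J
#' mice, per presenting allele: five H2-Db epitopes and fifteen H2-Kb
#' epitopes (twenty in total). Used as the default planted ground truth for
#' plant-and-recover experiments; the label scheme (N1-N15, P16-P30,
#' M31-M40, GP41-GP45, L46-L50) matches the gene-order block numbering
#' assigned by [select_by_quota()].
#'
#' @return Named list of character vectors, one per allele.
#' @export
reference_hit_ids <- function() {
  list(
    "H2-Db" = c("N15", "P18", "P21", "GP42", "L50"),
    "H2-Kb" = c("N3", "N4", "N5", "N7", "N9",
                "P17", "P19", "P21", "P23", "P26",
                "M38", "GP42", "GP45", "L47", "L50")
  )
}

#' Run the end-to-end epitope identification pipeline on synthetic data
#'
#' Executes every stage in order: candidate enumeration, synthetic predictor
#' tables (with ample planted binders), cross-tool consensus, host-proteome
#' dissimilarity, ranking, gene-order quota selection, pool-matrix design,
#' simulated pool-screen ELISpot with two-way-ANOVA/Sidak calls, matrix
#' deconvolution, simulated individual-peptide ELISpot (with the respective
#' vertical pools in the tested family), hit calling, novelty annotation,
#' simulated ICS validation with the same test machinery, and the
#' ICS-ELISpot Pearson correlation.
#'
#' Group sizes follow the study design they emulate: pool screens use 4 mock
#' vs 6 immunized animals, individual peptide tests 5 vs 4, and ICS 6 vs 6,
#' each with 2 technical replicates. All randomness derives from `seed`
#' (identical seed, identical run).
#'
#' @param proteome Viral proteome tibble (default [simulate_proteome()]
#'   drawn under `seed`).
#' @param host Host proteome tibble for dissimilarity screening (default
#'   [simulate_host_proteome()] drawn under `seed`).
#' @param planted_responders Named list allele -> candidate_id vector of
#'   true responders (default [reference_hit_ids()]).
#' @param alleles MHC-I alleles screened (default H2-Db and H2-Kb).
#' @param quota Per-protein selection quota (default [default_quota()]).
#' @param n_horizontal,n_vertical Pool grid (default 7 x 7 = 14 pools).
#' @param thresholds Binder-tier percentile-rank cutoffs.
#' @param alpha Family-wise significance level (default 0.05).
#' @param config [sim_config()] of synthetic-data parameters.
#' @param seed Integer seed for the whole run.
#' @param dissimilarity Optional precomputed named vector
#'   (sequence -> score) to reuse across runs that share a proteome.
#' @param out_dir Optional directory; when given, every stage table is
#'   written as TSV.
#' @return A list of class `epi_screen_run` with elements `selected`,
#'   `ranked`, `matrices`, `pool_calls`, `significant_pools`, `deconvolved`,
#'   `individual_calls`, `hits`, `ics`, `summary` and the inputs used.
#' @examples
#' \donttest{
#' run <- run_screen(seed = 1)
#' run$summary
#' }
#' @export
run_screen <- function(proteome = NULL, host = NULL,
                       planted_responders = reference_hit_ids(),
                       alleles = c("H2-Db", "H2-Kb"),
                       quota = default_quota(),
                       n_horizontal = 7, n_vertical = 7,
                       thresholds = c(0.5, 2, 3), alpha = 0.05,
                       config = sim_config(), seed = 1,
                       dissimilarity = NULL, out_dir = NULL) {
  with_seed(seed, {
    if (is.null(proteome)) proteome <- simulate_proteome()
    if (is.null(host)) host <- simulate_host_proteome()

    # --- enumeration -------------------------------------------------------
    candidates <- enumerate_peptides(proteome, lengths = 8:11, alleles = alleles)

    # --- synthetic predictions with ample planted binders ------------------
    planted_binders <- candidates |>
      group_by(.data$allele, .data$protein) |>
      dplyr::slice_sample(n = 30) |>
      ungroup() |>
      select("peptide_id", "allele")
    predictions <- simulate_predictions(candidates, planted = planted_binders,
                                        config = config)

    # --- consensus, dissimilarity, ranking, selection ----------------------
    consensus <- build_consensus(predictions, thresholds = thresholds) |>
      left_join(
        candidates |>
          select("peptide_id", "allele", "protein", "gene_order_index",
                 "start", "end", "length", "sequence"),
        by = c("peptide_id", "allele")
      )
    if (is.null(dissimilarity)) {
      useq <- unique(consensus$sequence)
      dissimilarity <- setNames(dissimilarity_score(useq, host), useq)
    }
    consensus$dissimilarity <- unname(dissimilarity[consensus$sequence])
    ranked <- rank_candidates(consensus)
    selected <- select_by_quota(ranked, quota = quota)

    # --- per-allele screening ---------------------------------------------
    matrices <- list(); pool_calls <- list(); significant_pools <- list()
    deconvolved <- list(); individual_calls <- list(); hit_list <- list()
    ics_tables <- list(); ics_calls <- list()

    for (al in alleles) {
      sel <- filter(selected, .data$allele == al)
      truth <- intersect(planted_responders[[al]] %||% character(),
                         sel$candidate_id)
      mat <- design_pool_matrix(sel, n_horizontal, n_vertical)
      matrices[[al]] <- mat

      # pool screen: a pool responds iff it contains a planted responder
      contents <- pool_contents(mat)
      responder_pools <- contents |>
        filter(.data$candidate_id %in% truth) |>
        pull(.data$pool) |> unique()
      pool_counts <- simulate_elispot(
        as.character(attr(mat, "pool_labels")),
        responders = as.character(responder_pools),
        config = config, n_mock = 4, n_immunized = 6
      )
      pc <- screen_test(average_replicates(pool_counts), alpha = alpha)
      pool_calls[[al]] <- pc
      sig <- as.integer(pc$stimulus[pc$significant])
      significant_pools[[al]] <- sig

      # deconvolution and individual testing (with the vertical pools in
      # the same tested family)
      dec <- deconvolve_pools(mat, sig)
      deconvolved[[al]] <- dec
      if (nrow(dec) == 0) {
        individual_calls[[al]] <- NULL
        hit_list[[al]] <- tibble()
        next
      }
      vpools <- sort(unique(dec$pool_v))
      ind_stimuli <- c(dec$candidate_id, as.character(vpools))
      vresp <- contents |>
        filter(.data$pool %in% vpools, .data$candidate_id %in% truth) |>
        pull(.data$pool) |> unique()
      ind_counts <- simulate_elispot(
        ind_stimuli, responders = c(truth, as.character(vresp)),
        config = config, n_mock = 5, n_immunized = 4
      )
      ic <- screen_test(average_replicates(ind_counts), alpha = alpha)
      individual_calls[[al]] <- ic
      hits <- call_hits(ic, sel) |> annotate_novelty()
      hit_list[[al]] <- hits

      # ICS validation on the identified epitopes (6 vs 6 animals)
      if (nrow(hits) > 0) {
        ics_latent <- simulate_elispot(
          hits$candidate_id, responders = intersect(hits$candidate_id, truth),
          config = config, n_mock = 6, n_immunized = 6, controls = FALSE
        )
        ics_means <- average_replicates(ics_latent)
        ics_tab <- simulate_ics(ics_means, config = config)
        ics_tables[[al]] <- ics_tab
        ics_calls[[al]] <- screen_test(ics_tab,
                                       response = "pct_ifng_pos_cd8",
                                       alpha = alpha)
      }
    }

    hits_all <- bind_rows(hit_list, .id = NULL)

    # --- ICS-ELISpot correlation across all identified epitopes ------------
    correlation <- NULL
    if (length(ics_tables) > 0) {
      paired <- purrr::map_dfr(names(ics_tables), function(al) {
        el <- individual_calls[[al]]
        h <- hit_list[[al]]
        ics_mean <- ics_tables[[al]] |>
          filter(.data$group == "immunized") |>
          group_by(.data$stimulus) |>
          summarise(ics_mean = mean(.data$pct_ifng_pos_cd8), .groups = "drop")
        el |>
          filter(.data$stimulus %in% h$candidate_id) |>
          mutate(
            # immunized-group mean spots = mock mean + effect; recover from
            # the fitted model's cell means
            elispot_mean = vapply(.data$stimulus, function(s) {
              mm <- attr(el, "model")$model
              mean(mm$y[mm$stimulus == s & mm$group == "immunized"])
            }, numeric(1))
          ) |>
          inner_join(ics_mean, by = "stimulus") |>
          select("stimulus", "elispot_mean", "ics_mean")
      })
      if (nrow(paired) >= 3 &&
          stats::sd(paired$elispot_mean) > 0 && stats::sd(paired$ics_mean) > 0) {
        correlation <- correlate_ics_elispot(paired)
      }
    }

    summary <- purrr::map_dfr(alleles, function(al) {
      h <- hit_list[[al]]
      tibble(
        allele = al,
        n_candidates = sum(candidates$allele == al),
        n_selected = sum(selected$allele == al),
        n_pools = n_horizontal + n_vertical,
        n_significant_pools = length(significant_pools[[al]]),
        n_deconvolved = nrow(deconvolved[[al]]),
        n_hits = nrow(h),
        n_known = if (nrow(h) > 0) sum(h$known) else 0L,
        n_novel = if (nrow(h) > 0) sum(!h$known) else 0L,
        n_ics_significant = if (!is.null(ics_calls[[al]]))
          sum(ics_calls[[al]]$significant) else 0L
      )
    })

    run <- structure(list(
      proteome = proteome, host = host, quota = quota, alpha = alpha,
      seed = seed, planted_responders = planted_responders,
      ranked = ranked, selected = selected, matrices = matrices,
      pool_calls = pool_calls, significant_pools = significant_pools,
      deconvolved = deconvolved, individual_calls = individual_calls,
      hits = hits_all, ics_tables = ics_tables, ics_calls = ics_calls,
      correlation = correlation, summary = summary
    ), class = "epi_screen_run")

    if (!is.null(out_dir)) write_run(run, out_dir)
    run
  })
}

#' @export
print.epi_screen_run <- function(x, ...) {
  cat("Epitope screening run (seed ", x$seed, ")\n\n", sep = "")
  print(x$summary)
  if (!is.null(x$correlation)) {
    cat(sprintf("\nICS-ELISpot Pearson r = %.3f (p = %.3g, n = %d)\n",
                x$correlation$r, x$correlation$p_value, x$correlation$n))
  }
  invisible(x)
}

# Write every stage table of a run as TSV under out_dir.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$ranked, file.path(out_dir, "ranked_candidates.tsv"))
  readr::write_tsv(run$selected, file.path(out_dir, "selected_candidates.tsv"))
  for (al in names(run$matrices)) {
    slug <- gsub("[^A-Za-z0-9]", "", al)
    readr::write_tsv(as_tibble(run$matrices[[al]]),
                     file.path(out_dir, paste0("matrix_", slug, ".tsv")))
    sheet <- pool_contents(run$matrices[[al]]) |>
      group_by(.data$pool, .data$orientation) |>
      summarise(candidate_ids = paste(.data$candidate_id, collapse = ","),
                .groups = "drop")
    readr::write_tsv(sheet, file.path(out_dir, paste0("pools_", slug, ".tsv")))
    readr::write_tsv(as_tibble(run$pool_calls[[al]]),
                     file.path(out_dir, paste0("pool_calls_", slug, ".tsv")))
    if (!is.null(run$individual_calls[[al]])) {
      readr::write_tsv(as_tibble(run$individual_calls[[al]]),
                       file.path(out_dir, paste0("peptide_calls_", slug, ".tsv")))
    }
  }
  readr::write_tsv(run$hits, file.path(out_dir, "hits.tsv"))
  readr::write_tsv(run$summary, file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}
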