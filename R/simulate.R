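# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Approximate background amino-acid frequencies (vertebrate proteome scale);
# used so synthetic proteins have a realistic composition.
AA_BACKGROUND_FREQ <- c(
  A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033, Q = 0.037,
  E = 0.058, G = 0.074, H = 0.029, I = 0.038, L = 0.076, K = 0.072,
  M = 0.018, F = 0.040, P = 0.050, S = 0.081, T = 0.062, W = 0.013,
  Y = 0.033, V = 0.068
)

random_protein <- function(n) {
  paste(sample(names(AA_BACKGROUND_FREQ), n, replace = TRUE,
               prob = AA_BACKGROUND_FREQ), collapse = "")
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data module with its default:
#' group sizes for individual-peptide assays (5 mock / 4 immunized; pool
#' screens override these to 4 / 6 and ICS to 6 / 6 in [run_screen()]),
#' 2 technical replicates, negative-binomial spot counts with background
#' mean 5 and responder mean 60 spots/well at dispersion (size) 8, planted
#' -binder percentile ranks Uniform(0, 0.5) against a Uniform(0, 100)
#' background, and ICS frequencies linear in the ELISpot mean (0.02 %/spot)
#' with Gaussian noise (sd 0.1 percentage points), truncated at zero.
#'
#' @param ... Overrides for any default field.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_mock = 5L, n_immunized = 4L, n_replicates = 2L,
    background_mean = 5, responder_mean = 60, dispersion = 8,
    pc_mean = 500, cells_per_well = 250000L,
    binder_rank_max = 0.5, background_rank_max = 100,
    ics_slope = 0.02, ics_noise_sd = 0.1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) abort(sprintf("Unknown sim_config field(s): %s",
                                         toString(unknown)))
  cfg[names(over)] <- over
  stopifnot(cfg$n_mock >= 1, cfg$n_immunized >= 1, cfg$n_replicates >= 1,
            cfg$background_mean >= 0, cfg$responder_mean >= 0,
            cfg$dispersion > 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a scaled-down chimeric viral proteome
#'
#' Generates five random proteins named N, P, M, GP and L in genome order,
#' with decreasing expression implied by the order (the quotas downstream
#' encode the gradient). The four literature-described C57BL/6 epitopes are
#' planted at their published coordinates (RGYVYQGL at N 52-59, KAVYNFATC at
#' GP 33-41 — which contains AVYNFATC at 34-41 — and LNHNFCNL at GP
#' 118-125) when the protein is long enough, so novelty annotation is
#' exercised on realistic content. All other residues are random draws from
#' background amino-acid frequencies; this proteome is synthetic, not the
#' real viral sequence.
#'
#' @param lengths Named integer vector of protein lengths in gene order.
#' @param seed Integer seed (determinism contract: same seed, same proteome).
#' @param plant_known Plant the known epitope sequences (default TRUE).
#' @return A proteome tibble (see [as_proteome()]).
#' @export
simulate_proteome <- function(lengths = c(N = 130L, P = 130L, M = 100L,
                                          GP = 140L, L = 90L),
                              seed = NULL, plant_known = TRUE) {
  stopifnot(!is.null(names(lengths)), all(lengths >= 11))
  with_seed(seed, {
    seqs <- vapply(lengths, random_protein, character(1))
    if (plant_known) {
      for (i in seq_len(nrow(known_epitopes()))) {
        ke <- known_epitopes()[i, ]
        if (ke$protein %in% names(seqs) &&
            nchar(seqs[[ke$protein]]) >= ke$end) {
          s <- seqs[[ke$protein]]
          substr(s, ke$start, ke$end) <- ke$sequence
          seqs[[ke$protein]] <- s
        }
      }
    }
    as_proteome(seqs)
  })
}

#' Simulate a toy host (self) proteome
#'
#' A small random proteome standing in for the host proteome in
#' dissimilarity screening; real self-proteome screening uses the same code
#' path on a full FASTA via [read_proteome()].
#'
#' @param n_proteins Number of host proteins (default 3).
#' @param length Length of each host protein (default 150).
#' @param seed Integer seed.
#' @return A proteome tibble.
#' @export
simulate_host_proteome <- function(n_proteins = 3, length = 150, seed = NULL) {
  with_seed(seed, {
    seqs <- setNames(
      vapply(rep(length, n_proteins), random_protein, character(1)),
      paste0("host", seq_len(n_proteins))
    )
    as_proteome(seqs)
  })
}

#' Simulate per-tool percentile-rank prediction tables
#'
#' Planted binders draw their percentile rank independently per tool from
#' Uniform(0, `binder_rank_max`) — below the strong-binder cutoff by
#' construction — and every other peptide from Uniform(0,
#' `background_rank_max`). One record per peptide, allele and tool slot.
#'
#' @param candidates Candidate tibble from [enumerate_peptides()].
#' @param planted Character vector of planted-binder `peptide_id`s (may be
#'   empty), or a tibble with `peptide_id` (and optionally `allele`)
#'   columns for per-allele planting.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Long prediction tibble (`peptide_id`, `allele`, `tool`,
#'   `percentile_rank`) covering all three tool slots.
#' @export
simulate_predictions <- function(candidates, planted = character(),
                                 config = sim_config(), seed = NULL) {
  stopifnot(is.data.frame(candidates),
            all(c("peptide_id", "allele") %in% names(candidates)))
  if (is.data.frame(planted)) {
    if (!"allele" %in% names(planted)) planted$allele <- NA_character_
    planted_key <- ifelse(is.na(planted$allele), planted$peptide_id,
                          paste(planted$peptide_id, planted$allele))
    known_ids <- planted$peptide_id
  } else {
    planted_key <- planted
    known_ids <- planted
  }
  missing <- setdiff(known_ids, candidates$peptide_id)
  if (length(missing) > 0) {
    abort(sprintf("Planted binder(s) not in the candidate universe: %s",
                  toString(utils::head(missing, 5))))
  }
  keys <- candidates[, c("peptide_id", "allele")]
  is_planted <- keys$peptide_id %in% planted_key |
    paste(keys$peptide_id, keys$allele) %in% planted_key
  n <- nrow(keys)
  with_seed(seed, {
    purrr::map_dfr(PREDICTION_TOOLS, function(tool) {
      rank <- runif(n, 0, config$background_rank_max)
      rank[is_planted] <- runif(sum(is_planted), 0, config$binder_rank_max)
      tibble(peptide_id = keys$peptide_id, allele = keys$allele,
             tool = tool, percentile_rank = rank)
    })
  })
}

#' Simulate an ELISpot spot-count table
#'
#' Draws negative-binomial replicate spot counts for every animal x stimulus
#' x replicate well. Wells of immunized animals on responder stimuli draw
#' from the responder mean; all other peptide/pool wells, all mock wells and
#' the NC well draw from the background mean; the PC (mitogen) well draws
#' from a high fixed mean in both groups. A pool stimulus is a responder
#' stimulus iff it contains at least one planted responder peptide.
#'
#' @param stimuli Tibble with columns `stimulus` and logical `is_responder`
#'   (controls are added automatically), or a character vector of stimulus
#'   labels plus `responders`.
#' @param responders Character vector of responder stimulus labels (used
#'   when `stimuli` is a character vector).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param n_mock,n_immunized Group sizes; default from `config`.
#' @param controls Add NC/PC wells (default TRUE).
#' @return Replicate-level tibble: `animal_id`, `group`, `stimulus`,
#'   `replicate`, `spot_count`, `cells_per_well`.
#' @export
simulate_elispot <- function(stimuli, responders = character(),
                             config = sim_config(), seed = NULL,
                             n_mock = config$n_mock,
                             n_immunized = config$n_immunized,
                             controls = TRUE) {
  if (!is.data.frame(stimuli)) {
    stimuli <- tibble(stimulus = as.character(stimuli),
                      is_responder = as.character(stimuli) %in% responders)
  }
  stopifnot(all(c("stimulus", "is_responder") %in% names(stimuli)))
  if (controls) {
    stimuli <- bind_rows(stimuli,
                         tibble(stimulus = c("NC", "PC"),
                                is_responder = FALSE))
  }
  animals <- bind_rows(
    tibble(animal_id = sprintf("mock_%02d", seq_len(n_mock)), group = "mock"),
    tibble(animal_id = sprintf("imm_%02d", seq_len(n_immunized)),
           group = "immunized")
  )
  wells <- tidyr::expand_grid(animals, stimuli,
                              replicate = seq_len(config$n_replicates)) |>
    mutate(mu = dplyr::case_when(
      .data$stimulus == "PC" ~ config$pc_mean,
      .data$group == "immunized" & .data$is_responder ~ config$responder_mean,
      TRUE ~ config$background_mean
    ))
  with_seed(seed, {
    wells |>
      mutate(spot_count = rnbinom(n(), size = config$dispersion, mu = .data$mu),
             cells_per_well = config$cells_per_well) |>
      select("animal_id", "group", "stimulus", "replicate", "spot_count",
             "cells_per_well")
  })
}

#' Simulate an ICS table linked to ELISpot responses
#'
#' Per animal and stimulus, the percentage of IFN-gamma-positive CD8+ cells
#' is a truncated linear function of that animal's mean ELISpot count:
#' `max(0, ics_slope * mean_count + N(0, ics_noise_sd))`.
#'
#' @param elispot_means Tibble from [average_replicates()] (columns
#'   `animal_id`, `group`, `stimulus`, `mean_count`), restricted to the
#'   stimuli assayed by ICS.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Tibble: `animal_id`, `group`, `stimulus`, `pct_ifng_pos_cd8`.
#' @export
simulate_ics <- function(elispot_means, config = sim_config(), seed = NULL) {
  stopifnot(is.data.frame(elispot_means),
            all(c("animal_id", "group", "stimulus", "mean_count") %in%
                  names(elispot_means)))
  with_seed(seed, {
    elispot_means |>
      mutate(pct_ifng_pos_cd8 = pmax(
        0, config$ics_slope * .data$mean_count +
          rnorm(n(), 0, config$ics_noise_sd)
      )) |>
      select("animal_id", "group", "stimulus", "pct_ifng_pos_cd8")
  })
}
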