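#' Average technical replicates of an ELISpot table
#'
#' Collapses a replicate-level spot-count table to one row per animal and
#' stimulus (the arithmetic mean of the replicate counts). All downstream
#' testing operates on these animal-level means.
#'
#' @param counts Tibble with columns `animal_id`, `group`, `stimulus`,
#'   `spot_count` (and optionally `replicate`).
#' @return Tibble with one row per (animal_id, group, stimulus) and a
#'   `mean_count` column.
#' @export
average_replicates <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("animal_id", "group", "stimulus", "spot_count") %in% names(counts)))
  if (any(counts$spot_count < 0)) abort("Spot counts must be non-negative.")
  counts |>
    group_by(.data$animal_id, .data$group, .data$stimulus) |>
    summarise(mean_count = mean(.data$spot_count),
              n_replicates = n(), .groups = "drop")
}

#' Sidak multiple-comparison adjustment
#'
#' Adjusted p = 1 - (1 - p)^m for m comparisons, clipped to \[0, 1\].
#' Monotone in both arguments and never smaller than the raw p-value.
#'
#' @param raw_p Numeric vector of raw p-values in \[0, 1\].
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p-values.
#' @examples
#' sidak_adjust(0.01, 7)  # 1 - 0.99^7
#' @export
sidak_adjust <- function(raw_p, m) {
  if (length(m) != 1 || is.na(m) || m < 1) abort("m must be a single number >= 1.")
  if (any(is.na(raw_p)) || any(raw_p < 0 | raw_p > 1)) {
    abort("Raw p-values must lie in [0, 1].")
  }
  pmin(1, pmax(0, 1 - (1 - raw_p)^m))
}

#' Per-stimulus mock-vs-immunized contrasts from a two-way ANOVA
#'
#' Fits a two-factor linear model (group x stimulus, with interaction) on
#' animal-level replicate means and tests, for every stimulus in the family,
#' the immunized-minus-mock difference in cell means using the model's
#' pooled error term: `SE = sqrt(MSE * (1/n_imm + 1/n_mock))` with the
#' residual degrees of freedom of the full model. Raw two-sided p-values are
#' Sidak-adjusted with m = the number of stimuli in the family. This mirrors
#' the "two-way ANOVA with Sidak's multiple comparisons" convention of
#' standard graphing software.
#'
#' Control wells (by default `NC` and `PC`) are excluded from the tested
#' family; when both are present, a plate-validity check requires the PC
#' (mitogen) mean to exceed the NC mean. Stimuli observed in only one group
#' are excluded with a warning.
#'
#' @param averaged Tibble from [average_replicates()] (columns `animal_id`,
#'   `group`, `stimulus`, and the response), or an ICS table with the
#'   response named via `response`.
#' @param response Name of the response column (default `"mean_count"`).
#' @param groups Length-2 character vector `c(reference, treatment)`;
#'   effects are treatment minus reference (default mock, immunized).
#' @param exclude Stimulus labels excluded from the family (default NC/PC).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble of class `epi_screen_calls` with one row per stimulus:
#'   `stimulus`, `effect` (treatment - reference), `se`, `df`, `statistic`,
#'   `raw_p`, `adjusted_p`, `significant`; attributes `m`, `alpha`, `model`.
#' @export
screen_test <- function(averaged, response = "mean_count",
                        groups = c("mock", "immunized"),
                        exclude = c("NC", "PC"), alpha = 0.05) {
  stopifnot(is.data.frame(averaged), length(groups) == 2)
  need <- c("animal_id", "group", "stimulus", response)
  if (!all(need %in% names(averaged))) {
    abort(sprintf("screen_test() needs columns: %s",
                  toString(setdiff(need, names(averaged)))))
  }
  bad_groups <- setdiff(unique(averaged$group), c(groups, NA))
  if (length(bad_groups) > 0) {
    abort(sprintf("Unknown group label(s): %s", toString(bad_groups)))
  }

  if (all(c("NC", "PC") %in% averaged$stimulus) && all(c("NC", "PC") %in% exclude)) {
    pc <- mean(averaged[[response]][averaged$stimulus == "PC"])
    nc <- mean(averaged[[response]][averaged$stimulus == "NC"])
    if (!pc > nc) {
      warn(sprintf("Plate-validity check failed: PC mean (%.1f) does not exceed NC mean (%.1f).",
                   pc, nc))
    }
  }

  dat <- averaged |>
    filter(!.data$stimulus %in% exclude) |>
    mutate(
      group = factor(.data$group, levels = groups),
      y = .data[[response]]
    )
  # keep only stimuli observed in both groups
  both <- dat |>
    distinct(.data$stimulus, .data$group) |>
    count(.data$stimulus) |>
    filter(.data$n == 2) |>
    pull(.data$stimulus)
  dropped <- setdiff(unique(dat$stimulus), both)
  if (length(dropped) > 0) {
    warn(sprintf("Stimulus(-i) with one group only excluded: %s", toString(dropped)))
    dat <- filter(dat, .data$stimulus %in% both)
  }
  stimuli <- unique(dat$stimulus)
  if (length(stimuli) == 0) abort("No testable stimuli (need both groups present).")
  per_cell <- dat |> count(.data$stimulus, .data$group)
  if (any(per_cell$n < 2)) {
    abort("Need at least 2 animals per group for every stimulus.")
  }
  dat$stimulus <- factor(dat$stimulus, levels = stimuli)

  fit <- lm(y ~ group * stimulus, data = dat)
  mse <- sum(fit$residuals^2) / fit$df.residual
  if (mse <= .Machine$double.eps) {
    abort("Degenerate input: zero residual variance everywhere; the pooled-error contrast is undefined.")
  }

  m <- length(stimuli)
  calls <- purrr::map_dfr(stimuli, function(s) {
    sub <- dat[dat$stimulus == s, ]
    y_trt <- sub$y[sub$group == groups[2]]
    y_ref <- sub$y[sub$group == groups[1]]
    eff <- mean(y_trt) - mean(y_ref)
    se <- sqrt(mse * (1 / length(y_trt) + 1 / length(y_ref)))
    tval <- eff / se
    tibble(
      stimulus = as.character(s),
      effect = eff, se = se, df = fit$df.residual, statistic = tval,
      raw_p = 2 * pt(-abs(tval), df = fit$df.residual)
    )
  }) |>
    mutate(
      adjusted_p = sidak_adjust(.data$raw_p, m),
      significant = .data$adjusted_p < alpha
    )
  attr(calls, "m") <- m
  attr(calls, "alpha") <- alpha
  attr(calls, "groups") <- groups
  attr(calls, "model") <- fit
  class(calls) <- c("epi_screen_calls", class(calls))
  calls
}

#' Call epitope hits from individual-peptide significance calls
#'
#' A candidate peptide is an epitope hit when its individual ELISpot
#' mock-vs-immunized contrast is significant after Sidak adjustment. Hits
#' are returned with their peptide metadata, sorted by genome position.
#'
#' @param calls `epi_screen_calls` tibble whose `stimulus` values are
#'   candidate IDs (vertical-pool stimuli in the same family are ignored
#'   here; they are tested for context, not called as epitopes).
#' @param metadata Candidate metadata tibble with columns `candidate_id`,
#'   `allele`, `protein`, `gene_order_index`, `start`, `end`, `length`,
#'   `sequence`.
#' @return Tibble of hits (one row per significant candidate) carrying the
#'   call columns plus metadata, ordered by gene order then start.
#' @export
call_hits <- function(calls, metadata) {
  stopifnot(is.data.frame(calls), is.data.frame(metadata),
            "candidate_id" %in% names(metadata))
  hits <- calls |>
    filter(.data$significant, .data$stimulus %in% metadata$candidate_id) |>
    rename(candidate_id = "stimulus") |>
    inner_join(metadata, by = "candidate_id") |>
    arrange(.data$gene_order_index, .data$start)
  as_tibble(hits)
}

#' Pearson correlation between paired ICS and ELISpot summaries
#'
#' @param paired Tibble with one row per stimulus and columns
#'   `elispot_mean` (spots/well) and `ics_mean` (% IFN-gamma+ CD8+ cells).
#' @return One-row tibble: `r`, `statistic`, `df`, `p_value`, `n`,
#'   `conf_low`, `conf_high`.
#' @export
correlate_ics_elispot <- function(paired) {
  stopifnot(is.data.frame(paired),
            all(c("elispot_mean", "ics_mean") %in% names(paired)))
  if (nrow(paired) < 3) abort("Need at least 3 paired stimuli for a correlation.")
  if (stats::sd(paired$elispot_mean) == 0 || stats::sd(paired$ics_mean) == 0) {
    abort("Zero variance in one of the paired variables; correlation undefined.")
  }
  ct <- cor.test(paired$elispot_mean, paired$ics_mean, method = "pearson")
  ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
  tibble(
    r = unname(ct$estimate), statistic = unname(ct$statistic),
    df = unname(ct$parameter), p_value = ct$p.value, n = nrow(paired),
    conf_low = ci[1], conf_high = ci[2]
  )
}
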