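#' Tidy per-stimulus significance calls
#'
#' @param x An `epi_screen_calls` object from [screen_test()].
#' @param ... Unused.
#' @return A plain tibble with one row per stimulus: `stimulus`, `effect`,
#'   `se`, `df`, `statistic`, `raw_p`, `adjusted_p`, `significant`.
#' @export
tidy.epi_screen_calls <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a screening test
#'
#' @param x An `epi_screen_calls` object from [screen_test()].
#' @param ... Unused.
#' @return One-row tibble: number of stimuli in the Sidak family (`m`),
#'   `alpha`, `n_significant`, the underlying two-way ANOVA's residual
#'   `df` and `sigma` (root mean squared error), and `r_squared`.
#' @export
glance.epi_screen_calls <- function(x, ...) {
  fit <- attr(x, "model")
  s <- summary(fit)
  tibble(
    m = attr(x, "m"),
    alpha = attr(x, "alpha"),
    n_significant = sum(x$significant),
    df_residual = fit$df.residual,
    sigma = s$sigma,
    r_squared = s$r.squared
  )
}

#' Tidy a pool matrix
#'
#' @param x A `pool_matrix` from [design_pool_matrix()].
#' @param ... Unused.
#' @return Long tibble of pool memberships, as [pool_contents()].
#' @export
tidy.pool_matrix <- function(x, ...) {
  pool_contents(x)
}

#' Tidy an end-to-end screening run
#'
#' @param x An `epi_screen_run` from [run_screen()].
#' @param ... Unused.
#' @return The per-allele summary tibble of the run.
#' @export
tidy.epi_screen_run <- function(x, ...) {
  x$summary
}
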