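# Shared fixture builders; everything is generated in code.

# A deterministic toy protein sequence of length n (cycles the alphabet so
# that every window is unique for n <= a few hundred).
toy_sequence <- function(n, offset = 0) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  # mixed-radix walk: unique 2-mers for a long stretch
  i <- (seq_len(n) - 1 + offset)
  paste(aa[(i * 7 + (i %/% 20)) %% 20 + 1], collapse = "")
}

# A five-protein toy viral proteome in gene order, long enough for default
# quotas when enumerated at lengths 8-11.
toy_viral_proteome <- function(seed = 42) {
  simulate_proteome(
    lengths = c(N = 60L, P = 60L, M = 50L, GP = 40L, L = 40L),
    seed = seed, plant_known = FALSE
  )
}

# Brute-force substring enumeration oracle (independent of the package's
# vectorized path).
oracle_substrings <- function(sequence, lengths) {
  out <- list()
  for (k in lengths) {
    L <- nchar(sequence)
    if (k > L) next
    for (s in seq_len(L - k + 1)) {
      out[[length(out) + 1]] <- list(start = s, length = k,
                                     sequence = substr(sequence, s, s + k - 1))
    }
  }
  out
}

# Brute-force dissimilarity oracle: loop over every window, residue by residue.
oracle_dissimilarity <- function(peptide, host_seqs) {
  k <- nchar(peptide)
  best <- 0
  pch <- strsplit(peptide, "")[[1]]
  for (s in host_seqs) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      wch <- strsplit(substr(s, i, i + k - 1), "")[[1]]
      best <- max(best, sum(wch == pch) / k)
    }
  }
  1 - best
}

# Write a small prediction table to a temp file and return the path.
write_prediction_file <- function(df, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  if (ext == ".csv") readr::write_csv(df, path) else readr::write_tsv(df, path)
  path
}

# A balanced averaged-count table for screen_test: one value per animal and
# stimulus, constant `base` everywhere plus per-stimulus immunized shifts.
toy_averaged <- function(stimuli, n_mock = 4, n_imm = 6, base = 5,
                         shift = setNames(numeric(0), character(0)),
                         noise_sd = 1, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(
    animal_id = c(sprintf("m%02d", seq_len(n_mock)),
                  sprintf("i%02d", seq_len(n_imm))),
    stimulus = stimuli, stringsAsFactors = FALSE
  )
  grid$group <- ifelse(grepl("^m", grid$animal_id), "mock", "immunized")
  grid$mean_count <- base + rnorm(nrow(grid), 0, noise_sd) +
    ifelse(grid$group == "immunized" & grid$stimulus %in% names(shift),
           shift[grid$stimulus], 0)
  tibble::as_tibble(grid)
}
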