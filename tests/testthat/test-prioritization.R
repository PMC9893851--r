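test_that("dissimilarity is 0 for verbatim self-matches and 1 for no identity", {
  host <- as_proteome(c(h1 = "MAAAAKLLWWSRVDDD"))
  expect_equal(dissimilarity_score("AAAAKLLW", host), 0)     # exact substring
  expect_equal(dissimilarity_score("CCCCCCCC", host), 1)     # no shared residue
})

test_that("dissimilarity equals the complement of the best-window identity", {
  host <- as_proteome(c(h1 = "MAAAAKLLWWSRVDDD"))
  # best window matches 6 of 8 residues -> 0.25
  expect_equal(dissimilarity_score("AAAAKLYY", host), 0.25)
  # brute-force oracle over random peptides and a random host
  set.seed(7)
  host2 <- simulate_host_proteome(n_proteins = 2, length = 40, seed = 11)
  peps <- vapply(1:12, function(i) {
    paste(sample(c("A","R","N","D","C","Q","E","G","H","I"),
                 sample(8:11, 1), replace = TRUE), collapse = "")
  }, character(1))
  expect_equal(dissimilarity_score(peps, host2),
               vapply(peps, oracle_dissimilarity, numeric(1),
                      host_seqs = host2$sequence),
               ignore_attr = TRUE)
})

test_that("dissimilarity rejects degenerate input", {
  host <- as_proteome(c(h1 = "MAAAAKLLWWSRVDDD"))
  expect_error(dissimilarity_score("SHORT", host), "at least 8")
  expect_error(dissimilarity_score("AAAAKLLW", host[0, ]), "empty")
  # windows shorter than the peptide contribute nothing -> score 1
  tiny <- as_proteome(c(h1 = "MAAAAKLL"))
  expect_equal(dissimilarity_score("AAAAKLLWW", tiny), 1)
})

test_that("hydrophobic fraction counts the configured residue set", {
  expect_equal(hydrophobic_fraction(c("LLLL", "SSSS", "LLSS")), c(1, 0, 0.5))
  expect_equal(hydrophobic_fraction("LSLS", hydrophobic = "S"), 0.5)
  expect_error(hydrophobic_fraction("LBLX"), "Invalid residue")
})

test_that("ranking is lexicographic: tier key, then stability, then dissimilarity", {
  base <- tibble::tibble(
    peptide_id = c("a", "b", "c", "d", "e"),
    allele = "H2-Db",
    k1 = c(3, 3, 3, 3, 2), k2 = c(3, 3, 3, 3, 2), k3 = c(3, 2, 2, 2, 2),
    stability_rank = c(5.0, 0.4, 1.5, 1.5, 0.1),
    dissimilarity = c(0.2, 0.2, 0.2, 0.9, 0.9)
  )
  ranked <- rank_candidates(base)
  # 3-3-3 beats 3-3-2 even with far worse stability; among equal keys lower
  # stability wins; among equal stability higher dissimilarity wins
  expect_equal(ranked$peptide_id[order(ranked$rank_position)],
               c("a", "b", "d", "c", "e"))
})

test_that("fully tied candidates are ordered by peptide_id and ranking is total", {
  tied <- tibble::tibble(
    peptide_id = c("z", "m", "a"), allele = "H2-Kb",
    k1 = 3, k2 = 3, k3 = 3, stability_rank = 0.3, dissimilarity = 0.5
  )
  ranked <- rank_candidates(tied)
  expect_equal(ranked$peptide_id, c("a", "m", "z"))
  expect_equal(ranked$rank_position, 1:3)
})

test_that("self-identical peptides are excluded before ranking", {
  df <- tibble::tibble(
    peptide_id = c("self", "other"), allele = "H2-Db",
    k1 = 3, k2 = 3, k3 = 3, stability_rank = 0.1,
    dissimilarity = c(0, 0.4)
  )
  ranked <- rank_candidates(df)
  expect_equal(ranked$peptide_id, "other")
  expect_equal(ranked$rank_position, 1L)
})

test_that("worsening a stability rank never improves a candidate's position", {
  set.seed(3)
  df <- tibble::tibble(
    peptide_id = sprintf("p%02d", 1:30), allele = "H2-Db",
    k1 = sample(0:3, 30, TRUE), k2 = 0L, k3 = 0L,
    stability_rank = runif(30, 0, 10), dissimilarity = runif(30, 0.1, 1)
  )
  df$k2 <- pmin(df$k1, sample(0:3, 30, TRUE))
  df$k3 <- pmin(df$k2, sample(0:3, 30, TRUE))
  before <- rank_candidates(df)
  for (i in c(4, 11, 23)) {
    pert <- df
    pert$stability_rank[i] <- pert$stability_rank[i] + 5  # strictly worse
    after <- rank_candidates(pert)
    id <- df$peptide_id[i]
    expect_gte(after$rank_position[after$peptide_id == id],
               before$rank_position[before$peptide_id == id])
  }
})

test_that("quota selection takes per-protein prefixes and assigns block ids", {
  prot <- toy_viral_proteome()
  cand <- enumerate_peptides(prot)
  preds <- simulate_predictions(cand, config = sim_config(), seed = 5)
  consensus <- build_consensus(preds) |>
    dplyr::left_join(cand, by = c("peptide_id", "allele"))
  consensus$dissimilarity <- runif(nrow(consensus), 0.2, 1)
  ranked <- rank_candidates(consensus)
  sel <- select_by_quota(ranked)

  for (al in unique(sel$allele)) {
    sub <- sel[sel$allele == al, ]
    expect_equal(nrow(sub), 50)
    expect_equal(as.vector(table(factor(sub$protein, names(default_quota())))),
                 unname(default_quota()), ignore_attr = TRUE)
    # block numbering in gene order: N1..N15, P16..P30, M31..M40, GP41..GP45,
    # L46..L50
    expect_equal(sub$candidate_id,
                 paste0(rep(c("N", "P", "M", "GP", "L"), default_quota()), 1:50))
    # per-protein selections are prefix-closed in rank (no skipping)
    for (p in unique(sub$protein)) {
      taken <- sort(ranked$rank_position[ranked$allele == al &
                                           ranked$peptide_id %in%
                                           sub$peptide_id[sub$protein == p]])
      avail <- sort(ranked$rank_position[ranked$allele == al &
                                           ranked$protein == p])
      expect_equal(taken, avail[seq_along(taken)])
    }
    expect_true(all(sub$dissimilarity > 0))
  }
  expect_equal(nrow(sel), 100)  # both alleles
})

test_that("quota shortfall names the protein and available count", {
  ranked <- tibble::tibble(
    peptide_id = sprintf("GP_%d_8", 1:4), allele = "H2-Db", protein = "GP",
    gene_order_index = 4L, start = 1:4, k1 = 3, k2 = 3, k3 = 3,
    stability_rank = runif(4), dissimilarity = 0.5, rank_position = 1:4
  )
  expect_error(select_by_quota(ranked, quota = c(GP = 5L)), "GP has only 4")
  single <- select_by_quota(ranked[1, ], quota = c(GP = 1L))
  expect_equal(single$candidate_id, "GP1")
})
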