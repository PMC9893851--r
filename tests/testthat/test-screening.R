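test_that("technical replicates are averaged per animal and stimulus", {
  tab <- tibble::tibble(
    animal_id = c("a", "a", "b", "c", "c", "c"),
    group = c("mock", "mock", "mock", "immunized", "immunized", "immunized"),
    stimulus = "1",
    replicate = c(1, 2, 1, 1, 2, 3),
    spot_count = c(10, 20, 7, 0, 0, 3)
  )
  avg <- average_replicates(tab)
  expect_equal(avg$mean_count[avg$animal_id == "a"], 15)
  expect_equal(avg$mean_count[avg$animal_id == "b"], 7)
  expect_equal(avg$mean_count[avg$animal_id == "c"], 1)
  expect_error(average_replicates(dplyr::mutate(tab, spot_count = -1)),
               "non-negative")
})

test_that("Sidak adjustment matches its closed form and is monotone", {
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  expect_equal(sidak_adjust(1, 3), 1)
  expect_equal(sidak_adjust(0.01, 7), 1 - 0.99^7, tolerance = 1e-12)
  p <- seq(0, 1, by = 0.01)
  expect_true(all(sidak_adjust(p, 14) >= p))                # never below raw
  expect_true(all(diff(sidak_adjust(p, 14)) >= 0))          # monotone in p
  by_m <- vapply(1:20, function(m) sidak_adjust(0.02, m), numeric(1))
  expect_true(all(diff(by_m) >= 0))                         # monotone in m
  expect_error(sidak_adjust(0.5, 0), "m must")
  expect_error(sidak_adjust(1.2, 3), "\\[0, 1\\]")
})

test_that("identical groups yield no significant stimuli", {
  avg <- toy_averaged(as.character(1:6), noise_sd = 1, seed = 2)
  calls <- screen_test(avg)
  expect_equal(sum(calls$significant), 0)
  expect_equal(attr(calls, "m"), 6)
  expect_true(all(calls$adjusted_p >= calls$raw_p))
})

test_that("a planted large effect is detected and verified by a permutation oracle", {
  avg <- toy_averaged(as.character(1:6), n_mock = 5, n_imm = 4,
                      shift = c("3" = 100), noise_sd = 1, seed = 4)
  calls <- screen_test(avg)
  expect_true(calls$significant[calls$stimulus == "3"])
  expect_equal(sum(calls$significant), 1)
  expect_equal(calls$effect[calls$stimulus == "3"], 100, tolerance = 0.05)

  # permutation oracle on the same data: permute group labels within the
  # planted stimulus; the observed mean difference should be extreme
  sub <- avg[avg$stimulus == "3", ]
  obs <- mean(sub$mean_count[sub$group == "immunized"]) -
    mean(sub$mean_count[sub$group == "mock"])
  set.seed(99)
  perm <- replicate(500, {
    g <- sample(sub$group)
    mean(sub$mean_count[g == "immunized"]) - mean(sub$mean_count[g == "mock"])
  })
  p_perm <- (1 + sum(abs(perm) >= abs(obs))) / 501
  expect_lt(p_perm, 0.05)
  expect_lt(calls$raw_p[calls$stimulus == "3"], 0.05)
})

test_that("pooled-error contrasts agree with emmeans pairwise comparisons", {
  skip_if_not_installed("emmeans")
  avg <- toy_averaged(as.character(1:5), shift = c("2" = 8, "5" = 3),
                      noise_sd = 2, seed = 11)
  calls <- screen_test(avg)
  fit <- attr(calls, "model")
  emm <- emmeans::emmeans(fit, ~ group | stimulus)
  ctr <- as.data.frame(emmeans::contrast(emm, method = "revpairwise"))
  ctr <- ctr[order(match(ctr$stimulus, calls$stimulus)), ]
  expect_equal(calls$effect, ctr$estimate, tolerance = 1e-10)
  expect_equal(calls$se, ctr$SE, tolerance = 1e-10)
  expect_equal(calls$raw_p, ctr$p.value, tolerance = 1e-10)
})

test_that("screen_test is invariant to stimulus ordering and animal relabeling", {
  avg <- toy_averaged(as.character(1:4), shift = c("2" = 50), seed = 6)
  base <- tidy(screen_test(avg))

  shuf <- avg[sample(nrow(avg)), ]
  reord <- tidy(screen_test(shuf))
  reord <- reord[match(base$stimulus, reord$stimulus), ]
  expect_equal(base$raw_p, reord$raw_p, tolerance = 1e-12)

  relab <- dplyr::mutate(avg, animal_id = paste0("zz_", animal_id))
  relab_calls <- tidy(screen_test(relab))
  expect_equal(base$raw_p, relab_calls$raw_p, tolerance = 1e-12)
})

test_that("controls are excluded from the family and plate validity is checked", {
  avg <- toy_averaged(c("1", "2", "NC"), shift = c("1" = 60), seed = 8)
  pc_block <- toy_averaged("PC", base = 400, seed = 9)
  calls <- screen_test(dplyr::bind_rows(avg, pc_block))
  expect_setequal(calls$stimulus, c("1", "2"))
  expect_equal(attr(calls, "m"), 2)
  # failing PC (below NC) triggers the validity warning
  bad_pc <- dplyr::mutate(pc_block, mean_count = 0)
  expect_warning(screen_test(dplyr::bind_rows(avg, bad_pc)), "Plate-validity")
})

test_that("degenerate and one-group inputs are rejected or excluded", {
  flat <- toy_averaged(as.character(1:3), noise_sd = 0, seed = 1)
  expect_error(screen_test(flat), "Degenerate")

  avg <- toy_averaged(as.character(1:3), seed = 2)
  lonely <- toy_averaged("solo", seed = 3)
  lonely <- lonely[lonely$group == "immunized", ]
  expect_warning(calls <- screen_test(dplyr::bind_rows(avg, lonely)),
                 "one group only")
  expect_false("solo" %in% calls$stimulus)
})

test_that("hits are the significant candidates, sorted by genome position", {
  meta <- tibble::tibble(
    candidate_id = c("N1", "P16", "L46"), allele = "H2-Db",
    protein = c("N", "P", "L"), gene_order_index = c(1L, 2L, 5L),
    start = c(10L, 3L, 7L), end = c(17L, 10L, 14L), length = 8L,
    sequence = c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD")
  )
  avg <- toy_averaged(c("N1", "P16", "L46", "15"),
                      shift = c("L46" = 80, "N1" = 90), seed = 10)
  calls <- screen_test(avg)
  hits <- call_hits(calls, meta)
  expect_equal(hits$candidate_id, c("N1", "L46"))  # genome order, pool "15" ignored
  expect_true(all(hits$significant))

  none <- call_hits(screen_test(toy_averaged(c("N1", "P16"), seed = 3)), meta)
  expect_equal(nrow(none), 0)
})

test_that("ICS-ELISpot correlation recovers exact and simulated linear links", {
  exact <- tibble::tibble(elispot_mean = c(5, 50, 120, 300),
                          ics_mean = 0.02 * c(5, 50, 120, 300))
  expect_equal(correlate_ics_elispot(exact)$r, 1)
  neg <- dplyr::mutate(exact, ics_mean = -ics_mean)
  expect_equal(correlate_ics_elispot(neg)$r, -1)

  # simulated link: slope 0.02 %/spot, Gaussian noise, n = 16 stimuli
  set.seed(21)
  spots <- runif(16, 5, 300)
  noise_sd <- 0.4
  rho_true <- 0.02 * sd(spots) / sqrt((0.02 * sd(spots))^2 + noise_sd^2)
  rs <- replicate(200, {
    ics <- 0.02 * spots + rnorm(16, 0, noise_sd)
    correlate_ics_elispot(tibble::tibble(elispot_mean = spots,
                                         ics_mean = ics))$r
  })
  expect_equal(mean(rs), rho_true, tolerance = 3 * sd(rs) / sqrt(200) + 0.02)

  expect_error(correlate_ics_elispot(exact[1:2, ]), "at least 3")
  flat <- tibble::tibble(elispot_mean = c(1, 1, 1), ics_mean = c(1, 2, 3))
  expect_error(correlate_ics_elispot(flat), "Zero variance")
})

test_that("tidy and glance summarise screening calls", {
  avg <- toy_averaged(as.character(1:4), shift = c("2" = 50), seed = 6)
  calls <- screen_test(avg)
  td <- tidy(calls)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "epi_screen_calls"))
  gl <- glance(calls)
  expect_equal(gl$m, 4)
  expect_equal(gl$n_significant, sum(calls$significant))
  expect_gt(gl$sigma, 0)
})
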