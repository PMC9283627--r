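test_that("planted interaction counts follow the configured fractions exactly", {
  cfg <- screen_config(n_donors = 50, n_recipients = 60,
                       planted_fraction_aggravating = 0.05,
                       planted_fraction_alleviating = 0.05,
                       rewired_fraction = 0.3, seed = 1)
  sim <- simulate_screen(cfg)
  pl <- sim$truth$planted

  agg_pairs <- dplyr::distinct(dplyr::filter(pl, sign == "aggravating"),
                               donor, recipient)
  all_pairs <- dplyr::distinct(dplyr::filter(pl, sign == "alleviating"),
                               donor, recipient)
  expect_equal(nrow(agg_pairs), round(0.05 * 50 * 60))  # 150
  expect_equal(nrow(all_pairs), 150)

  # rewired pairs: round(0.3 * 150) per sign, split between the conditions
  rw <- sim$truth$rewired
  expect_equal(sum(rw$sign == "aggravating"), round(0.3 * 150))
  expect_equal(sum(rw$sign == "alleviating"), round(0.3 * 150))
  expect_true(all(pair_key(rw$donor, rw$recipient) %in%
                    pair_key(pl$donor, pl$recipient)))

  # per-condition bookkeeping: a sign's pairs in a condition are all pairs
  # minus those rewired into the other condition only
  for (sgn in c("aggravating", "alleviating")) {
    for (cond in c("RM", "MM")) {
      other <- setdiff(c("RM", "MM"), cond)
      got <- sum(pl$sign == sgn & pl$condition == cond)
      expected <- 150 - sum(rw$sign == sgn & rw$condition == other)
      expect_equal(got, expected)
    }
  }

  # no duplicate (pair, condition) entries
  expect_equal(nrow(pl), nrow(dplyr::distinct(pl, donor, recipient, condition)))
})

test_that("zero planted fractions produce an empty truth", {
  cfg <- screen_config(n_donors = 10, n_recipients = 12, n_replicates = 4,
                       planted_fraction_aggravating = 0,
                       planted_fraction_alleviating = 0, seed = 3)
  sim <- simulate_screen(cfg)
  expect_equal(nrow(sim$truth$planted), 0)
  expect_equal(nrow(sim$truth$rewired), 0)
})

test_that("identical config and seed reproduce the screen bit for bit", {
  cfg <- screen_config(n_donors = 8, n_recipients = 10, n_replicates = 4,
                       seed = 11)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$screens$RM, b$screens$RM)
  expect_identical(a$screens$MM, b$screens$MM)
  expect_identical(a$truth, b$truth)
})

test_that("colony means match the multiplicative expectation without artifacts", {
  cfg <- screen_config(n_donors = 20, n_recipients = 24, n_replicates = 8,
                       planted_fraction_aggravating = 0,
                       planted_fraction_alleviating = 0,
                       row_effect_sd = 0, col_effect_sd = 0, edge_effect = 0,
                       missing_fraction = 0, noise_sd = 5, seed = 5)
  sim <- simulate_screen(cfg)
  W <- setNames(sim$truth$fitness$W, sim$truth$fitness$gene_id)
  means <- sim$screens$RM %>%
    dplyr::group_by(donor, recipient) %>%
    dplyr::summarise(m = mean(size), .groups = "drop") %>%
    dplyr::mutate(expected = cfg$baseline_colony_size * W[donor] * W[recipient])
  tol <- 3 * cfg$noise_sd / sqrt(cfg$n_replicates)
  expect_gte(mean(abs(means$m - means$expected) <= tol), 0.99)
})

test_that("screen sizes are finite, non-negative and fully laid out", {
  cfg <- screen_config(n_donors = 6, n_recipients = 30, n_replicates = 4,
                       missing_fraction = 0.05, seed = 7)
  sim <- simulate_screen(cfg)
  for (scr in sim$screens) {
    expect_true(all(is.na(scr$size) | scr$size >= 0))
    expect_true(all(scr$row >= 1 & scr$row <= cfg$plate_rows))
    expect_true(all(scr$col >= 1 & scr$col <= cfg$plate_cols))
    # plate positions unique within a plate
    expect_false(any(duplicated(scr[, c("plate", "row", "col")])))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(screen_config(n_donors = 0), class = "giscreen_config_error")
  expect_error(screen_config(n_replicates = 1), class = "giscreen_config_error")
  expect_error(screen_config(planted_fraction_aggravating = 0.3,
                             planted_fraction_alleviating = 0.2),
               class = "giscreen_config_error")
  expect_error(screen_config(noise_sd = -1), class = "giscreen_config_error")
})

test_that("annotation quotas are exact and memberships non-empty", {
  cfg <- screen_config(n_donors = 150, n_recipients = 154, seed = 2)
  genes <- simulate_annotations(cfg, orphan_fraction = 72 / 304,
                                global_fraction = 14 / 304)
  expect_equal(nrow(genes), 304)
  expect_equal(sum(genes$is_orphan), 72)
  expect_equal(sum(genes$regulator_scope == "global"), 14)
  expect_true(all(lengths(genes$major_bioprocesses) >= 1))
  expect_true(all(genes$locus_position >= 0 &
                    genes$locus_position < cfg$genome_length))
  expect_false(any(duplicated(genes$gene_id)))

  none <- simulate_annotations(cfg, orphan_fraction = 0)
  expect_equal(sum(none$is_orphan), 0)

  # deterministic under the config seed
  expect_identical(genes, simulate_annotations(cfg, orphan_fraction = 72 / 304,
                                               global_fraction = 14 / 304))
})

test_that("phylogenetic profiles honour presence probability extremes", {
  genes <- sprintf("g%02d", 1:10)
  all_on <- simulate_phylo_profiles(genes, presence_prob = 1, seed = 1)
  expect_equal(ncol(all_on), 18)  # gene_id + 17 phyla
  expect_true(co_conserved(all_on, "g01", "g02"))
  expect_true(all(as.matrix(all_on[, -1]) == 1))

  all_off <- simulate_phylo_profiles(genes, presence_prob = 0,
                                     coconservation_boost = 0, seed = 1)
  expect_false(co_conserved(all_off, "g01", "g02"))

  boosted <- simulate_phylo_profiles(
    genes, presence_prob = 0.3, coconservation_boost = 1,
    coconserved_pairs = tibble::tibble(gene_a = "g03", gene_b = "g07"),
    seed = 4)
  expect_true(co_conserved(boosted, "g03", "g07"))
})

test_that("alignment hits separate planted paralogs from decoys", {
  genes <- sprintf("g%02d", 1:20)
  hits <- simulate_alignment_hits(genes, n_paralog_pairs = 12, seed = 6)
  expect_equal(sum(hits$planted), 12)
  kept <- paralog_filter(hits)
  planted_keys <- pair_key(pmin(hits$query_id, hits$subject_id),
                           pmax(hits$query_id, hits$subject_id))[hits$planted]
  expect_setequal(pair_key(kept$gene_a, kept$gene_b), planted_keys)

  none <- simulate_alignment_hits(genes, n_paralog_pairs = 0, n_decoys = 10,
                                  seed = 6)
  expect_equal(nrow(paralog_filter(none)), 0)
})
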