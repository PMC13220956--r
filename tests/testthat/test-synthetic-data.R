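test_that("all generators are bit-identical under the same seed and differ across seeds", {
  cfg <- bulk_panel_config(n_genes = 200L, n_true_up = 10L, n_true_down = 10L,
                           seed = 42L)
  expect_identical(simulate_bulk_panel(cfg), simulate_bulk_panel(cfg))
  cfg2 <- bulk_panel_config(n_genes = 200L, n_true_up = 10L, n_true_down = 10L,
                            seed = 43L)
  expect_false(identical(simulate_bulk_panel(cfg)$datasets[[1]]$matrix,
                         simulate_bulk_panel(cfg2)$datasets[[1]]$matrix))

  panel <- synthetic_marker_panel(n_up = 10, n_down = 10, n_sasp = 8, n_ecm = 6)
  sc_cfg <- single_cell_config(n_cells = 300L, n_genes = 200L, seed = 5L)
  expect_identical(simulate_single_cell(sc_cfg, panel),
                   simulate_single_cell(sc_cfg, panel))
  expect_identical(simulate_region_matrix(4L, panel, seed = 9L),
                   simulate_region_matrix(4L, panel, seed = 9L))
  expect_identical(simulate_paired_omics(50L, 20L, seed = 3L),
                   simulate_paired_omics(50L, 20L, seed = 3L))
})

test_that("invalid configurations raise errors naming the violated field", {
  expect_error(bulk_panel_config(n_genes = 10L, n_true_up = 8L, n_true_down = 8L),
               "n_true_up")
  expect_error(bulk_panel_config(effect_consistency = 9L), "effect_consistency")
  expect_error(bulk_panel_config(noise_sd = 0), "noise_sd")
  expect_error(bulk_panel_config(n_replicates_per_group = 1L),
               "n_replicates_per_group")
  expect_error(single_cell_config(frac_senescent = 0.7, frac_escaped = 0.5),
               "frac_senescent")
  expect_error(single_cell_config(dropout_rate = 1), "dropout_rate")
  expect_error(simulate_region_matrix(n_regions = 1L), "n_regions")
  expect_error(simulate_paired_omics(rho_by_set = c(a = 1)), "rho")
  panel0 <- synthetic_marker_panel(n_sasp = 1)
  panel0$sasp <- character(0)
  expect_error(simulate_single_cell(single_cell_config(n_cells = 10L,
                                                       n_genes = 700L),
                                    panel0), "sasp")
})

test_that("a null bulk panel produces only noise-level group differences", {
  cfg <- bulk_panel_config(n_datasets = 2L, n_genes = 1500L, n_true_up = 0L,
                           n_true_down = 0L, effect_log2fc = 0,
                           effect_consistency = 2L,
                           n_replicates_per_group = 4L, seed = 77L)
  sim <- simulate_bulk_panel(cfg)
  de <- call_degs(fit_moderated(sim$datasets[[2]]$matrix,
                                sim$datasets[[2]]$groups))
  # with adjusted p < .05 and |lfc| > 0.5 almost nothing passes under the null
  expect_lt(sum(de$direction != "none"), 0.01 * 1500)
})

test_that("planted bulk effects land at the configured size in carrier datasets", {
  cfg <- bulk_panel_config(n_genes = 500L, n_true_up = 30L, n_true_down = 30L,
                           effect_log2fc = 2, effect_consistency = 4L,
                           n_replicates_per_group = 4L, noise_sd = 0.5,
                           seed = 11L)
  sim <- simulate_bulk_panel(cfg)
  ordinary <- setdiff(names(sim$truth$carrier_datasets),
                      c(sim$truth$core_up_genes, sim$truth$core_down_genes))
  expect_true(all(lengths(sim$truth$carrier_datasets[ordinary]) == 4L))
  expect_true(all(lengths(sim$truth$carrier_datasets[sim$truth$core_up_genes]) == 6L))
  diffs <- vapply(sim$truth$true_up_genes, function(g) {
    mean(vapply(sim$truth$carrier_datasets[[g]], function(d) {
      mat <- sim$datasets[[d]]$matrix
      grp <- sim$datasets[[d]]$groups
      mean(mat[g, grp == "senescent"]) - mean(mat[g, grp == "proliferating"])
    }, numeric(1)))
  }, numeric(1))
  # ordinary markers carry the configured effect; the core subset carries 1.5x
  ord_up <- intersect(sim$truth$true_up_genes, ordinary)
  expect_gt(mean(diffs[ord_up]), 1.8)
  expect_lt(mean(diffs[ord_up]), 2.2)
  expect_gt(mean(diffs[sim$truth$core_up_genes]), 2.7)
  expect_lt(mean(diffs[sim$truth$core_up_genes]), 3.3)
  # non-carrier datasets carry no effect beyond noise (ordinary marker; core
  # markers have no non-carrier dataset)
  g1 <- ord_up[1]
  non_carrier <- setdiff(1:6, sim$truth$carrier_datasets[[g1]])[1]
  mat <- sim$datasets[[non_carrier]]$matrix
  grp <- sim$datasets[[non_carrier]]$groups
  expect_lt(abs(mean(mat[g1, grp == "senescent"]) -
                  mean(mat[g1, grp == "proliferating"])), 1.5)
})

test_that("simulated counts are non-negative integers with the contracted subpopulation sizes", {
  panel <- synthetic_marker_panel(n_up = 10, n_down = 10, n_sasp = 8, n_ecm = 6)
  cfg <- single_cell_config(n_cells = 5000L, n_genes = 400L,
                            frac_senescent = 0.025, frac_escaped = 0.01,
                            seed = 21L)
  sim <- simulate_single_cell(cfg, panel)
  expect_true(is.integer(sim$counts))
  expect_true(all(sim$counts >= 0))
  expect_length(sim$truth$senescent_cell_ids, round(0.025 * 5000))
  expect_length(sim$truth$escaped_cell_ids, round(0.01 * 5000))
  expect_length(intersect(sim$truth$senescent_cell_ids,
                          sim$truth$escaped_cell_ids), 0L)

  cfg0 <- single_cell_config(n_cells = 400L, n_genes = 400L,
                             frac_senescent = 0, frac_escaped = 0, seed = 2L)
  sim0 <- simulate_single_cell(cfg0, panel)
  expect_length(sim0$truth$senescent_cell_ids, 0L)
})

test_that("every planted senescent cell passes an independent re-filter of all four criteria", {
  panel <- synthetic_marker_panel(n_up = 10, n_down = 10, n_sasp = 8, n_ecm = 6)
  thr <- caller_thresholds()
  for (s in c(1L, 9L)) {
    cfg <- single_cell_config(n_cells = 1000L, n_genes = 400L,
                              frac_senescent = 0.03, frac_escaped = 0.02,
                              seed = s)
    sim <- simulate_single_cell(cfg, panel, thr)
    oracle <- brute_force_caller(sim$counts, panel, thr)
    planted <- rownames(sim$counts) %in% sim$truth$senescent_cell_ids
    expect_true(all(oracle[planted]))
    # criterion 2 in isolation: hard zeros on every down marker
    expect_true(all(sim$counts[planted, panel$common_down] == 0))
    # escaped cells satisfy their own contract
    esc <- rownames(sim$counts) %in% sim$truth$escaped_cell_ids
    expect_true(all(sim$counts[esc, "CDKN1A"] > 0))
    expect_true(all(sim$counts[esc, "MKI67"] > 0))
    expect_true(all(sim$counts[esc, "PCNA"] > 0))
    expect_true(all(rowSums(sim$counts[esc, panel$mcm, drop = FALSE] > 0) >= 1))
    # and are never senescent calls (they retain down-marker expression)
    expect_true(!any(oracle[esc]))
  }
})

test_that("the planted region is constructed with elevated up and suppressed down markers", {
  panel <- synthetic_marker_panel(n_up = 20, n_down = 20, n_sasp = 5, n_ecm = 5)
  sim <- simulate_region_matrix(n_regions = 6L, panel = panel, seed = 31L)
  fpkm <- sim$fpkm
  tr <- sim$truth$true_region
  others <- setdiff(rownames(fpkm), tr)
  up_mean_ratio <- mean(fpkm[tr, panel$consensus_up] /
                          colMeans(fpkm[others, panel$consensus_up]))
  down_mean_ratio <- mean(fpkm[tr, panel$consensus_down] /
                            colMeans(fpkm[others, panel$consensus_down]))
  expect_gt(up_mean_ratio, 2)
  expect_lt(down_mean_ratio, 0.5)
})

test_that("paired omics hit their target rank correlations", {
  # zero-correlation target: mean estimated Spearman within +/-0.05 at n=99
  sim0 <- simulate_paired_omics(n_genes = 300L, n_samples = 99L,
                                rho_by_set = c(null = 0), seed = 51L)
  rho0 <- spearman_per_gene(sim0$mrna, sim0$protein)
  expect_lt(abs(mean(rho0$rho)), 0.05)

  # near-perfect target: nearly all genes significant at P < .05
  sim99 <- simulate_paired_omics(n_genes = 200L, n_samples = 99L,
                                 rho_by_set = c(tight = 0.99), seed = 52L)
  rho99 <- spearman_per_gene(sim99$mrna, sim99$protein)
  expect_gte(fraction_significant(rho99$p), 0.95)

  # moderate target: empirical mean near the configured value
  sim6 <- simulate_paired_omics(n_genes = 400L, n_samples = 99L,
                                rho_by_set = c(mid = 0.6), seed = 53L)
  rho6 <- spearman_per_gene(sim6$mrna, sim6$protein)
  expect_lt(abs(mean(rho6$rho) - 0.6), 0.05)

  # degenerate but legal: 3 samples generate fine; testing needs min_pairs=3
  sim3 <- simulate_paired_omics(n_genes = 20L, n_samples = 3L, seed = 54L)
  expect_equal(dim(sim3$mrna), c(20L, 3L))
  rho3 <- spearman_per_gene(sim3$mrna, sim3$protein, min_pairs = 3L)
  expect_equal(nrow(rho3), 20L)
  expect_true(all(rho3$rho >= -1 & rho3$rho <= 1))
})
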