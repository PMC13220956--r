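test_that("the combined call equals the intersection of four brute-force filters on a toy matrix", {
  panel <- toy_panel()
  m <- toy_cell_matrix(n_cells = 20L, seed = 11L)
  thr <- caller_thresholds(up_sum_min = 8, down_tolerance = 2,
                           top_quantile = 0.25)
  calls <- score_cells(m, panel, thr)
  expect_equal(calls$senescent, brute_force_caller(m, panel, thr))
  # and with a different threshold set
  thr2 <- caller_thresholds(up_sum_min = 5, down_tolerance = 0,
                            top_quantile = 0.5, min_cdki_expressed = 2L)
  calls2 <- score_cells(m, panel, thr2)
  expect_equal(calls2$senescent, brute_force_caller(m, panel, thr2))
})

test_that("any down-marker expression above the tolerance vetoes the call", {
  panel <- toy_panel()
  m <- toy_cell_matrix(seed = 2L)
  # make cell 1 pass everything except criterion 2
  m[1, c("UP1", "UP2")] <- 1000
  m[1, c("SA1", "SA2", "EC1", "EC2")] <- 1000
  m[1, "CDKN1A"] <- 5
  m[1, "DN1"] <- 1
  thr <- caller_thresholds(up_sum_min = 100, down_tolerance = 0)
  calls <- score_cells(m, panel, thr)
  expect_gt(calls$c1_up_sum[1], 100)
  expect_true(calls$c3_sasp_top[1] && calls$c4_ecm_top[1] && calls$c5_cdki[1])
  expect_false(calls$c2_down_absent[1])
  expect_false(calls$senescent[1])
})

test_that("exactly ceiling(q*n) cells pass each top-quantile criterion absent ties", {
  panel <- toy_panel()
  withr::with_seed(41, {
    m <- toy_cell_matrix(n_cells = 40L, seed = 41L)
    # continuous totals -> no ties
    m[, c("SA1", "SA2", "EC1", "EC2")] <-
      matrix(runif(40 * 4, 0, 100), nrow = 40)
  })
  for (q in c(0.1, 0.15, 0.33)) {
    calls <- score_cells(m, panel, caller_thresholds(top_quantile = q))
    expect_equal(sum(calls$c3_sasp_top), ceiling(q * 40))
    expect_equal(sum(calls$c4_ecm_top), ceiling(q * 40))
  }
  # ties all pass (inclusive rule): identical totals put every cell in the top
  m[, c("SA1", "SA2")] <- 3
  calls <- score_cells(m, panel, caller_thresholds(top_quantile = 0.15))
  expect_true(all(calls$c3_sasp_top))
})

test_that("raising the up-sum threshold never increases the senescent count", {
  panel <- toy_panel()
  m <- toy_cell_matrix(n_cells = 50L, seed = 13L)
  counts <- vapply(c(1, 5, 10, 20, 50), function(cut)
    sum(score_cells(m, panel, caller_thresholds(up_sum_min = cut,
                                                down_tolerance = 50,
                                                top_quantile = 0.5))$senescent),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("missing panel genes are tolerated but a fully absent set is an error", {
  panel <- toy_panel()
  m <- toy_cell_matrix(seed = 3L)
  m2 <- m[, setdiff(colnames(m), "SA1")]
  expect_message(calls <- score_cells(m2, panel, caller_thresholds(up_sum_min = 1)),
                 "absent")
  expect_s3_class(calls, "senescence_calls")
  m3 <- m[, setdiff(colnames(m), c("SA1", "SA2"))]
  expect_error(score_cells(m3, panel), "sasp")
  expect_error(score_cells(m[0, , drop = FALSE], panel), "empty")
})

test_that("cluster composition fractions sum to one and recover a planted mix", {
  calls <- tibble::tibble(
    cell = paste0("c", 1:6), cluster = c("A", "A", "B", "C", "C", "C"),
    senescent = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  comp <- summarize_clusters(calls)
  expect_equal(comp$cluster, "A")
  expect_equal(comp$fraction, 1)

  # multinomial 30/30/40 at n = 1000 senescent cells
  withr::with_seed(8, {
    cl <- sample(c("Endo", "ImmAstro", "RadialGlia"), 1000, replace = TRUE,
                 prob = c(0.3, 0.3, 0.4))
  })
  calls2 <- tibble::tibble(cell = paste0("c", 1:1000), cluster = cl,
                           senescent = TRUE)
  comp2 <- summarize_clusters(calls2)
  expect_equal(sum(comp2$fraction), 1)
  got <- setNames(comp2$fraction, comp2$cluster)
  expect_lt(abs(got[["Endo"]] - 0.3), 0.03)
  expect_lt(abs(got[["RadialGlia"]] - 0.4), 0.03)

  empty <- tibble::tibble(cell = "c1", cluster = "A", senescent = FALSE)
  expect_warning(comp3 <- summarize_clusters(empty), "no senescent")
  expect_equal(nrow(comp3), 0L)
})

test_that("escape fractions match a manual count on a hand-built matrix", {
  genes <- c("CDKN1A", "MKI67", "PCNA", "MCM2", "MCM3", "SA1", "SA2")
  # 10 cells; SASP top 50% = 5 cells (totals 10..6); p21+ among them: cells
  # 1,2,3,5; MKI67+ among those: cells 1,2; PCNA+ among escapes: cell 1;
  # MCM+ among escapes: cells 1 and 2
  m <- matrix(0, nrow = 10, ncol = length(genes),
              dimnames = list(paste0("c", 1:10), genes))
  m[, "SA1"] <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)
  m[c(1, 2, 3, 5), "CDKN1A"] <- 1
  m[c(1, 2, 8), "MKI67"] <- 1
  m[1, "PCNA"] <- 2
  m[1, "MCM2"] <- 1; m[2, "MCM3"] <- 4
  panel <- marker_panel(sasp = c("SA1", "SA2"), mcm = c("MCM2", "MCM3"))
  rep <- detect_escape(m, panel, caller_thresholds(top_quantile = 0.5),
                       clusters = rep(c("A", "B"), each = 5))
  expect_setequal(rep$base_cell_ids, c("c1", "c2", "c3", "c5"))
  expect_setequal(rep$escape_cell_ids, c("c1", "c2"))
  expect_equal(rep$frac_of_p21_sasp_cells_expressing_mki67, 2 / 4)
  expect_equal(rep$frac_escape_expressing_pcna, 1 / 2)
  expect_equal(rep$frac_escape_expressing_mcm, 1)
  expect_equal(sum(rep$cluster_composition$fraction), 1)
  expect_equal(rep$cluster_composition$cluster, "A")

  # no MKI67 in the base set -> escape fraction 0
  m0 <- m; m0[, "MKI67"] <- 0
  rep0 <- detect_escape(m0, panel, caller_thresholds(top_quantile = 0.5))
  expect_equal(rep0$frac_of_p21_sasp_cells_expressing_mki67, 0)
  expect_equal(rep0$n_escape, 0L)

  # empty base set -> flagged undefined
  m1 <- m; m1[, "CDKN1A"] <- 0
  expect_warning(rep1 <- detect_escape(m1, panel,
                                       caller_thresholds(top_quantile = 0.5)),
                 "undefined")
  expect_true(rep1$undefined)
  expect_true(is.na(rep1$frac_of_p21_sasp_cells_expressing_mki67))
})

test_that("planted escape cells are recovered from the simulator", {
  panel <- synthetic_marker_panel(n_up = 20, n_down = 20, n_sasp = 20, n_ecm = 15)
  cfg <- single_cell_config(n_cells = 1500L, n_genes = 600L,
                            frac_senescent = 0.02, frac_escaped = 0.1,
                            seed = 303L)
  sim <- simulate_single_cell(cfg, panel)
  rep <- detect_escape(sim$counts, panel, clusters = sim$clusters)
  recall <- mean(sim$truth$escaped_cell_ids %in% rep$escape_cell_ids)
  expect_gte(recall, 0.95)
})

test_that("the Mann-Whitney comparison matches a brute-force rank count and separates shifted groups", {
  # 4 vs 4 hand example: U = number of (senescent, other) pairs with
  # senescent value greater (+0.5 per tie)
  m <- matrix(c(7, 3, 9, 5, 2, 4, 1, 6), ncol = 1,
              dimnames = list(paste0("c", 1:8), "GENE"))
  calls <- tibble::tibble(cell = rownames(m),
                          senescent = rep(c(TRUE, FALSE), each = 4))
  res <- compare_expression(m, calls, "GENE")
  g1 <- m[1:4, 1]; g2 <- m[5:8, 1]
  u_oracle <- sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  expect_equal(unname(res$U), u_oracle)

  withr::with_seed(9, {
    m2 <- matrix(c(rnorm(20) + 10, rnorm(20)), ncol = 1,
                 dimnames = list(paste0("c", 1:40), "GENE"))
  })
  calls2 <- tibble::tibble(cell = rownames(m2),
                           senescent = rep(c(TRUE, FALSE), each = 20))
  res2 <- compare_expression(m2, calls2, "GENE")
  expect_lt(res2$p, 1e-4)
  expect_equal(res2$stars, "****")

  calls3 <- tibble::tibble(cell = rownames(m2), senescent = rep(TRUE, 40))
  expect_error(compare_expression(m2, calls3, "GENE"), "non-empty")
})
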