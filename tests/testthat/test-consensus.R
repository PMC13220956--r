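# Builds 6 fake per-dataset DE tables with fully controlled direction
# patterns, so consensus behaviour can be checked against enumeration.
pattern_tables <- function(patterns, log2fc = NULL) {
  # patterns: gene -> character vector of per-dataset directions
  n_ds <- length(patterns[[1]])
  lapply(seq_len(n_ds), function(d) {
    genes <- names(patterns)
    dirs <- vapply(patterns, `[`, character(1), d)
    lfc <- if (is.null(log2fc)) ifelse(dirs == "up", 1, ifelse(dirs == "down", -1, 0))
           else vapply(log2fc, `[`, numeric(1), d)
    fake_de_table(genes, lfc, p_adj = ifelse(dirs == "none", 0.9, 0.001),
                  direction = dirs)
  })
}

test_that("consensus membership follows the >=3-datasets same-direction rule with exclusivity", {
  patterns <- list(
    up3 = c("up", "up", "up", "none", "none", "none"),
    up2 = c("up", "up", "none", "none", "none", "none"),
    up4_conflict = c("up", "up", "up", "up", "down", "none"),
    down6 = rep("down", 6),
    down3 = c("none", "none", "none", "down", "down", "down"),
    mixed = c("up", "down", "up", "down", "up", "down"),
    silent = rep("none", 6)
  )
  cons <- consensus_markers(pattern_tables(patterns), consensus_rules())
  got <- setNames(cons$consensus, cons$gene)
  expect_equal(got[["up3"]], "up")            # >=3 datasets, no conflict
  expect_equal(got[["up2"]], "none")          # only 2 datasets
  expect_equal(got[["up4_conflict"]], "none") # exclusive rule: any opposite call vetoes
  expect_equal(got[["down6"]], "down")
  expect_equal(got[["down3"]], "down")
  expect_equal(got[["mixed"]], "none")
  expect_equal(got[["silent"]], "none")

  # majority (non-exclusive) variant admits the conflicted gene
  cons_m <- consensus_markers(pattern_tables(patterns),
                              consensus_rules(exclusive = FALSE))
  expect_equal(setNames(cons_m$consensus, cons_m$gene)[["up4_conflict"]], "up")
})

test_that("consensus equals an exhaustive enumeration oracle over random direction patterns", {
  withr::with_seed(17, {
    genes <- paste0("g", 1:10)
    patterns <- setNames(lapply(genes, function(g)
      sample(c("up", "down", "none"), 6, replace = TRUE)), genes)
  })
  rules <- consensus_rules(min_datasets = 3L)
  cons <- consensus_markers(pattern_tables(patterns), rules)
  oracle <- vapply(patterns, function(p) {
    if (sum(p == "up") >= 3 && sum(p == "down") == 0) "up"
    else if (sum(p == "down") >= 3 && sum(p == "up") == 0) "down"
    else "none"
  }, character(1))
  expect_equal(setNames(cons$consensus, cons$gene)[genes], oracle[genes])
})

test_that("raising min_datasets never enlarges the consensus sets", {
  withr::with_seed(19, {
    genes <- paste0("g", 1:40)
    patterns <- setNames(lapply(genes, function(g)
      sample(c("up", "down", "none"), 6, replace = TRUE)), genes)
  })
  tables <- pattern_tables(patterns)
  sizes <- vapply(1:6, function(k) {
    cons <- consensus_markers(tables, consensus_rules(min_datasets = k))
    sum(cons$consensus != "none")
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # direction exclusivity holds for any input
  cons <- consensus_markers(tables, consensus_rules())
  expect_equal(intersect(cons$gene[cons$consensus == "up"],
                         cons$gene[cons$consensus == "down"]), character(0))
})

test_that("fewer tables than min_datasets is an input error", {
  tables <- pattern_tables(list(g1 = c("up", "up")))
  expect_error(consensus_markers(tables, consensus_rules(min_datasets = 3L)),
               "min_datasets")
})

test_that("common marker lists apply the linear fold-change rules and ranking", {
  # hand-controlled per-dataset log2fc; linear FC thresholds: up > 1.7 in >=4
  # datasets, down < 0.5 in all datasets
  lfc <- list(
    strong_up   = log2(c(1.8, 1.9, 2.0, 1.8, 1.1, 1.2)),  # FC>1.7 in 4/6 -> qualifies
    weak_up     = log2(c(1.8, 1.9, 1.6, 1.5, 1.1, 1.2)),  # FC>1.7 in only 2 -> fails
    top_up      = log2(rep(3.2, 6)),                      # qualifies, largest mean lfc
    strong_down = log2(rep(0.4, 6)),                      # FC<0.5 everywhere -> qualifies
    leaky_down  = log2(c(0.49, 0.45, 0.4, 0.42, 0.44, 0.6)) # one dataset at 0.6 -> fails
  )
  dirs <- list(
    strong_up = rep("up", 6), weak_up = rep("up", 6), top_up = rep("up", 6),
    strong_down = rep("down", 6), leaky_down = rep("down", 6)
  )
  tables <- pattern_tables(dirs, log2fc = lfc)
  rules <- consensus_rules()
  cons <- consensus_markers(tables, rules)
  common <- common_marker_set(tables, cons, rules)
  expect_equal(common$common_up, c("top_up", "strong_up"))
  expect_equal(common$common_down, "strong_down")
})

test_that("common lists equal a sort-and-filter oracle and are truncated", {
  withr::with_seed(23, {
    genes <- paste0("g", 1:30)
    lfc_mat <- matrix(rnorm(30 * 6, mean = rep(rep(c(2, -2), each = 15), 6)),
                      nrow = 30, dimnames = list(genes, NULL))
    lfc <- setNames(lapply(genes, function(g) lfc_mat[g, ]), genes)
    dirs <- setNames(lapply(genes, function(g)
      rep(if (mean(lfc_mat[g, ]) > 0) "up" else "down", 6)), genes)
  })
  rules <- consensus_rules(n_common_up = 8L, n_common_down = 7L)
  tables <- pattern_tables(dirs, log2fc = lfc)
  cons <- consensus_markers(tables, rules)
  common <- common_marker_set(tables, cons, rules)

  up_ok <- genes[vapply(genes, function(g)
    all(dirs[[g]] == "up") && sum(2^lfc_mat[g, ] > 1.7) >= 4, logical(1))]
  oracle_up <- head(up_ok[order(-rowMeans(lfc_mat)[up_ok])], 8)
  down_ok <- genes[vapply(genes, function(g)
    all(dirs[[g]] == "down") && all(2^lfc_mat[g, ] < 0.5), logical(1))]
  oracle_down <- head(down_ok[order(rowMeans(lfc_mat)[down_ok])], 7)
  expect_equal(common$common_up, oracle_up)
  expect_equal(common$common_down, oracle_down)
  expect_lte(length(common$common_up), 8L)
  expect_lte(length(common$common_down), 7L)
})

test_that("region panel keeps all up markers and the most-down subset, ranked", {
  withr::with_seed(29, {
    n_down <- 200L
    genes <- c(paste0("u", 1:20), paste0("d", 1:n_down))
    lfc <- setNames(lapply(genes, function(g) {
      base <- if (startsWith(g, "u")) 1.5 else -runif(1, 0.6, 4)
      rep(base, 6) + rnorm(6, sd = 0.05)
    }), genes)
    dirs <- setNames(lapply(genes, function(g)
      rep(if (startsWith(g, "u")) "up" else "down", 6)), genes)
  })
  tables <- pattern_tables(dirs, log2fc = lfc)
  rules <- consensus_rules(n_region_down = 133L)
  cons <- consensus_markers(tables, rules)
  rp <- region_marker_panel(cons, tables, rules)
  expect_setequal(rp$up, paste0("u", 1:20))
  expect_length(rp$down, 133L)
  # ranking oracle: mean log2fc ascending
  means <- vapply(lfc, mean, numeric(1))
  down_genes <- cons$gene[cons$consensus == "down"]
  expect_equal(rp$down, head(down_genes[order(means[down_genes])], 133L))

  # smaller consensus than requested: all returned with a warning
  small_rules <- consensus_rules(n_region_down = 500L)
  expect_warning(rp2 <- region_marker_panel(cons, tables, small_rules), "taking all")
  expect_length(rp2$down, sum(cons$consensus == "down"))
})

test_that("planted markers are recovered from a simulated six-dataset panel", {
  cfg <- bulk_panel_config(n_genes = 1000L, n_true_up = 40L, n_true_down = 60L,
                           n_replicates_per_group = 4L, seed = 7L)
  sim <- simulate_bulk_panel(cfg)
  tables <- lapply(sim$datasets, function(d)
    call_degs(fit_moderated(d$matrix, d$groups)))
  cons <- consensus_markers(tables)
  up <- cons$gene[cons$consensus == "up"]
  down <- cons$gene[cons$consensus == "down"]
  expect_gt(mean(sim$truth$true_up_genes %in% up), 0.9)
  expect_gt(mean(sim$truth$true_down_genes %in% down), 0.9)
  expect_lt(mean(!c(up, down) %in% c(sim$truth$true_up_genes,
                                     sim$truth$true_down_genes)), 0.05)
})
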