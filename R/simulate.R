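#' Configuration for the multi-dataset bulk expression simulator
#'
#' Defaults emulate the study conditions the pipeline was built for: six
#' microarray-style senescent-vs-proliferating datasets with 2-5 replicates
#' per group, 128 planted up-markers and 461 planted down-markers carrying a
#' 2 log2FC effect in 4 of the 6 datasets over Gaussian log2-intensity noise.
#'
#' @param n_datasets Number of datasets (default 6).
#' @param n_genes Genes per dataset (default 2000).
#' @param n_true_up,n_true_down Planted direction-consistent markers
#'   (defaults 128 and 461).
#' @param n_replicates_per_group Replicates per group; scalar or vector of
#'   length `n_datasets` (default `c(4, 3, 2, 5, 2, 3)`, mirroring the
#'   replicate structure of the source series).
#' @param effect_log2fc Planted log2 effect (default 2); up-markers gain it
#'   in the senescent group, down-markers lose it.
#' @param effect_consistency Number of datasets in which each planted marker
#'   carries the effect (default 4).
#' @param noise_sd Residual Gaussian SD on the log2 scale (default 0.5).
#' @param baseline_mean Mean baseline log2 intensity (default 8).
#' @param seed Integer seed (explicit, never global state).
#' @return A list of class `bulk_panel_config`.
#' @export
bulk_panel_config <- function(n_datasets = 6L, n_genes = 2000L,
                              n_true_up = 128L, n_true_down = 461L,
                              n_replicates_per_group = c(4L, 3L, 2L, 5L, 2L, 3L),
                              effect_log2fc = 2, effect_consistency = 4L,
                              noise_sd = 0.5, baseline_mean = 8, seed = 1L) {
  check_count(n_datasets, "n_datasets", 2L)
  check_count(n_genes, "n_genes", 1L)
  check_count(n_true_up, "n_true_up", 0L)
  check_count(n_true_down, "n_true_down", 0L)
  if (n_true_up + n_true_down > n_genes)
    stop_config("n_true_up + n_true_down must not exceed n_genes")
  if (length(n_replicates_per_group) == 1L)
    n_replicates_per_group <- rep(n_replicates_per_group, n_datasets)
  if (length(n_replicates_per_group) != n_datasets)
    stop_config("n_replicates_per_group must have length 1 or n_datasets")
  for (r in n_replicates_per_group) check_count(r, "n_replicates_per_group", 2L)
  check_number(effect_log2fc, "effect_log2fc")
  check_count(effect_consistency, "effect_consistency", 1L)
  if (effect_consistency > n_datasets)
    stop_config("effect_consistency must not exceed n_datasets")
  check_number(noise_sd, "noise_sd", 0, strict_lower = TRUE)
  check_number(baseline_mean, "baseline_mean")
  check_count(seed, "seed")
  structure(list(n_datasets = n_datasets, n_genes = n_genes,
                 n_true_up = n_true_up, n_true_down = n_true_down,
                 n_replicates_per_group = as.integer(n_replicates_per_group),
                 effect_log2fc = effect_log2fc,
                 effect_consistency = effect_consistency, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, seed = as.integer(seed)),
            class = "bulk_panel_config")
}

#' Simulate a multi-dataset bulk expression panel with planted markers
#'
#' Generates `n_datasets` gene-by-sample log2-intensity matrices with a
#' proliferating and a senescent group. Each planted marker carries
#' `+/- effect_log2fc` in exactly `effect_consistency` randomly chosen
#' datasets, except a designated core subset (the first 8 up and 7 down
#' markers) which carries a 1.5x effect in every dataset — emulating the
#' universal common markers whose fold changes replicate across all source
#' datasets, so that the common-marker selection downstream lands on a
#' knowable gene set. Identical config and seed give bit-identical output.
#'
#' @param cfg A [bulk_panel_config()].
#' @return A list with `datasets` (named list; each element has `matrix`
#'   (genes x samples log2 values) and `groups` (two-level factor,
#'   proliferating first)) and `truth` (`true_up_genes`, `true_down_genes`,
#'   `core_up_genes`, `core_down_genes`, `carrier_datasets` per marker).
#' @export
simulate_bulk_panel <- function(cfg = bulk_panel_config()) {
  stopifnot(inherits(cfg, "bulk_panel_config"))
  genes <- c(sprintf("UPM%03d", seq_len(cfg$n_true_up)),
             sprintf("DNM%03d", seq_len(cfg$n_true_down)),
             sprintf("BG%04d", seq_len(cfg$n_genes - cfg$n_true_up - cfg$n_true_down)))
  up <- genes[seq_len(cfg$n_true_up)]
  down <- genes[cfg$n_true_up + seq_len(cfg$n_true_down)]
  core_up <- head(up, 8L)
  core_down <- head(down, 7L)
  core <- c(core_up, core_down)
  withr::with_seed(cfg$seed, {
    carriers <- lapply(seq_len(cfg$n_true_up + cfg$n_true_down), function(i)
      sort(sample.int(cfg$n_datasets, cfg$effect_consistency)))
    names(carriers) <- c(up, down)
    carriers[core] <- list(seq_len(cfg$n_datasets))
    effect_of <- setNames(rep(cfg$effect_log2fc, length(carriers)),
                          names(carriers))
    effect_of[core] <- 1.5 * cfg$effect_log2fc
    datasets <- lapply(seq_len(cfg$n_datasets), function(d) {
      nrep <- cfg$n_replicates_per_group[[d]]
      groups <- factor(rep(c("proliferating", "senescent"), each = nrep),
                       levels = c("proliferating", "senescent"))
      baseline <- cfg$baseline_mean + rnorm(cfg$n_genes)
      m <- matrix(rnorm(cfg$n_genes * 2L * nrep, sd = cfg$noise_sd),
                  nrow = cfg$n_genes) + baseline
      rownames(m) <- genes
      colnames(m) <- paste0(rep(c("P", "S"), each = nrep), seq_len(nrep))
      carries <- vapply(carriers, function(cd) d %in% cd, logical(1L))
      sen_cols <- which(groups == "senescent")
      up_c <- names(carriers)[carries & names(carriers) %in% up]
      down_c <- names(carriers)[carries & names(carriers) %in% down]
      m[up_c, sen_cols] <- m[up_c, sen_cols] + effect_of[up_c]
      m[down_c, sen_cols] <- m[down_c, sen_cols] - effect_of[down_c]
      list(matrix = m, groups = groups)
    })
  })
  names(datasets) <- sprintf("dataset%d", seq_len(cfg$n_datasets))
  list(datasets = datasets,
       truth = list(true_up_genes = up, true_down_genes = down,
                    core_up_genes = core_up, core_down_genes = core_down,
                    carrier_datasets = carriers))
}

#' Configuration for the single-cell count simulator
#'
#' Defaults emulate a tumor single-cell atlas at desk scale: 5000 cells,
#' 1500 genes, 12 clusters, 2.5% planted senescent cells (the prevalence the
#' four-criterion caller was designed around) and a small planted
#' senescence-escape subpopulation.
#'
#' @param n_cells,n_genes,n_clusters Matrix dimensions and cluster count.
#' @param frac_senescent,frac_escaped Planted subpopulation fractions; their
#'   sum must not exceed 1.
#' @param library_size_mean Mean per-cell total count (default 5000).
#' @param dropout_rate Bernoulli dropout probability applied to counts
#'   (default 0.3); must be < 1.
#' @param up_marker_boost,sasp_boost,ecm_boost Multiplicative expression
#'   elevation of the respective panel genes in planted senescent cells.
#' @param seed Integer seed.
#' @return A list of class `single_cell_config`.
#' @export
single_cell_config <- function(n_cells = 5000L, n_genes = 1500L,
                               n_clusters = 12L, frac_senescent = 0.025,
                               frac_escaped = 0.01, library_size_mean = 5000,
                               dropout_rate = 0.3, up_marker_boost = 100,
                               sasp_boost = 10, ecm_boost = 10, seed = 1L) {
  check_count(n_cells, "n_cells", 1L)
  check_count(n_genes, "n_genes", 1L)
  check_count(n_clusters, "n_clusters", 1L)
  check_number(frac_senescent, "frac_senescent", 0, 1)
  check_number(frac_escaped, "frac_escaped", 0, 1)
  if (frac_senescent + frac_escaped > 1)
    stop_config("frac_senescent + frac_escaped must not exceed 1")
  check_number(library_size_mean, "library_size_mean", 0, strict_lower = TRUE)
  check_number(dropout_rate, "dropout_rate", 0, 1, strict_upper = TRUE)
  check_number(up_marker_boost, "up_marker_boost", 0, strict_lower = TRUE)
  check_number(sasp_boost, "sasp_boost", 0, strict_lower = TRUE)
  check_number(ecm_boost, "ecm_boost", 0, strict_lower = TRUE)
  check_count(seed, "seed")
  structure(list(n_cells = n_cells, n_genes = n_genes, n_clusters = n_clusters,
                 frac_senescent = frac_senescent, frac_escaped = frac_escaped,
                 library_size_mean = library_size_mean,
                 dropout_rate = dropout_rate, up_marker_boost = up_marker_boost,
                 sasp_boost = sasp_boost, ecm_boost = ecm_boost,
                 seed = as.integer(seed)),
            class = "single_cell_config")
}

#' Simulate a single-cell count matrix with planted senescent and escape cells
#'
#' Counts are negative-binomial thinned by Bernoulli dropout. Planted
#' senescent cells satisfy all four caller criteria by construction at the
#' supplied thresholds: up-panel, SASP and ECM genes are boosted
#' multiplicatively and then deterministically topped up where random
#' variation would still fall below the criterion boundary; down-marker
#' counts are hard zeros; CDKN1A is floored at 1. Planted escape cells are
#' CDKN1A-positive with high SASP and express MKI67, PCNA and at least one
#' MCM gene (and retain down-marker expression, so they are never senescent
#' calls). The SASP/ECM top-up raises cells only to the pre-existing
#' top-quantile boundary value, which leaves that boundary unchanged, so the
#' construction guarantee is exact rather than probabilistic.
#'
#' @param cfg A [single_cell_config()].
#' @param panel A [marker_panel()] with non-empty `common_up`, `common_down`,
#'   `sasp`, `ecm` and `cdki` sets (e.g. [synthetic_marker_panel()]).
#' @param thresholds The [caller_thresholds()] the planted cells must pass.
#' @return A list with `counts` (cell x gene integer matrix), `clusters`
#'   (per-cell labels) and `truth` (`senescent_cell_ids`,
#'   `escaped_cell_ids`).
#' @export
simulate_single_cell <- function(cfg = single_cell_config(),
                                 panel = synthetic_marker_panel(),
                                 thresholds = caller_thresholds()) {
  stopifnot(inherits(cfg, "single_cell_config"))
  up_set <- panel[[thresholds$up_panel]]
  for (nm in c("common_down", "sasp", "ecm", "cdki")) {
    if (length(panel[[nm]]) == 0L)
      stop_config("panel set '%s' must be non-empty", nm)
  }
  if (length(up_set) == 0L)
    stop_config("panel set '%s' must be non-empty", thresholds$up_panel)

  fixed <- unique(c(up_set, panel$common_down, panel$sasp, panel$ecm,
                    panel$cdki, panel$mcm, "CDKN1A", "MKI67", "PCNA"))
  if (length(fixed) > cfg$n_genes)
    stop_config("n_genes (%d) is smaller than the panel gene universe (%d)",
                cfg$n_genes, length(fixed))
  genes <- c(fixed, sprintf("BG%04d", seq_len(cfg$n_genes - length(fixed))))
  n <- cfg$n_cells
  cells <- sprintf("cell%05d", seq_len(n))
  n_sen <- round(cfg$frac_senescent * n)
  n_esc <- round(cfg$frac_escaped * n)

  withr::with_seed(cfg$seed, {
    ids <- sample(cells, n_sen + n_esc)
    sen_ids <- sort(ids[seq_len(n_sen)])
    esc_ids <- sort(ids[n_sen + seq_len(n_esc)])
    clusters <- sample(sprintf("C%02d", seq_len(cfg$n_clusters)), n,
                       replace = TRUE)

    # gene-level relative expression; down-markers and proliferation
    # machinery get elevated baseline so their detection is reliable
    w <- exp(rnorm(length(genes), sd = 1))
    names(w) <- genes
    w[panel$common_down] <- mean(w) * 20
    w[c("MKI67", "PCNA", panel$mcm)] <- mean(w) * 5
    w <- w / sum(w)
    mu <- matrix(rep(w * cfg$library_size_mean, each = n), nrow = n,
                 dimnames = list(cells, genes))
    size_factor <- exp(rnorm(n, sd = 0.3))
    mu <- mu * size_factor

    sen <- cells %in% sen_ids
    esc <- cells %in% esc_ids
    mu[sen, intersect(up_set, genes)] <- mu[sen, intersect(up_set, genes)] * cfg$up_marker_boost
    mu[sen, panel$sasp] <- mu[sen, panel$sasp] * cfg$sasp_boost
    mu[sen, panel$ecm] <- mu[sen, panel$ecm] * cfg$ecm_boost
    mu[sen, panel$cdki] <- mu[sen, panel$cdki] * 10
    mu[esc, panel$sasp] <- mu[esc, panel$sasp] * cfg$sasp_boost
    mu[esc, c("CDKN1A", "MKI67", "PCNA", panel$mcm)] <-
      mu[esc, c("CDKN1A", "MKI67", "PCNA", panel$mcm)] * 10

    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 2),
                     nrow = n, dimnames = dimnames(mu))
    keep <- matrix(rbinom(length(counts), 1L, 1 - cfg$dropout_rate),
                   nrow = n)
    counts <- counts * keep

    # construction guarantees for the planted subpopulations; senescent
    # cells are growth-arrested, so their proliferation machinery is silent
    counts[sen, panel$common_down] <- 0L
    counts[sen, unique(c("MKI67", "PCNA", panel$mcm))] <- 0L
    counts[sen, "CDKN1A"] <- pmax(counts[sen, "CDKN1A"], 1L)
    counts[esc, "CDKN1A"] <- pmax(counts[esc, "CDKN1A"], 1L)
    counts[esc, "MKI67"] <- pmax(counts[esc, "MKI67"], 1L)
    counts[esc, "PCNA"] <- pmax(counts[esc, "PCNA"], 1L)
    counts[esc, panel$mcm[1L]] <- pmax(counts[esc, panel$mcm[1L]], 1L)
    counts[esc, panel$common_down[1L]] <- pmax(counts[esc, panel$common_down[1L]], 1L)

    # criterion 1: cumulative up-marker expression strictly above the cut
    up_sum <- rowSums(counts[, intersect(up_set, genes), drop = FALSE])
    deficit <- pmax(0, floor(thresholds$up_sum_min) + 1 - up_sum)
    counts[sen, up_set[1L]] <- counts[sen, up_set[1L]] + deficit[sen]

    # criteria 3/4: top cells up to the current top-quantile boundary value
    top_up_to_boundary <- function(counts, set, which_cells) {
      totals <- rowSums(counts[, set, drop = FALSE])
      v <- top_quantile_threshold(totals, thresholds$top_quantile)
      deficit <- pmax(0, v - totals)
      counts[which_cells, set[1L]] <-
        counts[which_cells, set[1L]] + deficit[which_cells]
      counts
    }
    counts <- top_up_to_boundary(counts, panel$sasp, sen | esc)
    counts <- top_up_to_boundary(counts, panel$ecm, sen)
  })
  storage.mode(counts) <- "integer"
  list(counts = counts, clusters = clusters,
       truth = list(senescent_cell_ids = sen_ids, escaped_cell_ids = esc_ids))
}

#' Simulate a region-by-gene FPKM matrix with one senescent-like region
#'
#' Exactly one region has elevated up-marker and suppressed down-marker
#' expression; all other genes are exchangeable across regions.
#'
#' @param n_regions Number of regions (>= 2).
#' @param panel A [marker_panel()]; `consensus_up`/`consensus_down` (falling
#'   back to the common lists when empty) define the planted structure.
#' @param seed Integer seed.
#' @param up_boost Multiplicative FPKM elevation of up-markers in the true
#'   region (default 3).
#' @param down_factor Multiplicative suppression of down-markers there
#'   (default 0.25).
#' @param noise_sd Log-normal noise SD (default 0.2); 0 gives noise-free
#'   output.
#' @param n_background Extra background genes (default 200).
#' @return A list with `fpkm` (region x gene matrix) and `truth`
#'   (`true_region`).
#' @export
simulate_region_matrix <- function(n_regions = 5L,
                                   panel = synthetic_marker_panel(),
                                   seed = 1L, up_boost = 3, down_factor = 0.25,
                                   noise_sd = 0.2, n_background = 200L) {
  check_count(n_regions, "n_regions", 2L)
  check_number(up_boost, "up_boost", 0, strict_lower = TRUE)
  check_number(down_factor, "down_factor", 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  up <- if (length(panel$consensus_up)) panel$consensus_up else panel$common_up
  down <- if (length(panel$consensus_down)) panel$consensus_down else panel$common_down
  genes <- unique(c(up, down, panel$sasp, panel$ecm,
                    sprintf("BG%04d", seq_len(n_background))))
  regions <- sprintf("R%02d", seq_len(n_regions))
  withr::with_seed(seed, {
    true_region <- sample(regions, 1L)
    baseline <- rlnorm(length(genes), meanlog = 2, sdlog = 1)
    names(baseline) <- genes
    fpkm <- matrix(rep(baseline, each = n_regions), nrow = n_regions,
                   dimnames = list(regions, genes))
    if (noise_sd > 0)
      fpkm <- fpkm * matrix(rlnorm(length(fpkm), 0, noise_sd), nrow = n_regions)
    fpkm[true_region, up] <- fpkm[true_region, up] * up_boost
    fpkm[true_region, down] <- fpkm[true_region, down] * down_factor
  })
  list(fpkm = fpkm, truth = list(true_region = true_region))
}

#' Simulate paired mRNA/protein tables with controlled rank correlation
#'
#' Per-gene mRNA/protein pairs are drawn from a bivariate Gaussian copula
#' whose Pearson parameter `r = 2 sin(pi * rho / 6)` makes the population
#' Spearman correlation equal the set's target.
#'
#' @param n_genes Total genes, divided as evenly as possible among the sets.
#' @param n_samples Shared samples (default 99, the proteogenomic cohort
#'   size the analysis emulates).
#' @param rho_by_set Named numeric vector of target Spearman correlations in
#'   (-1, 1), one per gene set (default `c(markers = 0.6, background = 0.2)`).
#' @param seed Integer seed.
#' @return A list with `mrna` and `protein` (gene x sample matrices), and
#'   `truth` (`set_of_gene` named character vector, `true_rho_per_gene`).
#' @export
simulate_paired_omics <- function(n_genes = 400L, n_samples = 99L,
                                  rho_by_set = c(markers = 0.6, background = 0.2),
                                  seed = 1L) {
  check_count(n_genes, "n_genes", 1L)
  check_count(n_samples, "n_samples", 2L)
  if (is.null(names(rho_by_set)) || any(!nzchar(names(rho_by_set))))
    stop_config("rho_by_set must be a named vector")
  for (rho in rho_by_set)
    check_number(rho, "rho_by_set", -1, 1, strict_lower = TRUE, strict_upper = TRUE)
  sets <- rep(names(rho_by_set), length.out = 0)
  split_sizes <- diff(round(seq(0, n_genes, length.out = length(rho_by_set) + 1L)))
  set_of_gene <- rep(names(rho_by_set), times = split_sizes)
  genes <- sprintf("%s_G%04d", toupper(set_of_gene),
                   unlist(lapply(split_sizes, seq_len)))
  samples <- sprintf("S%03d", seq_len(n_samples))
  rho_target <- rho_by_set[set_of_gene]
  r <- 2 * sin(pi * rho_target / 6)
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_genes * n_samples), nrow = n_genes)
    e <- matrix(rnorm(n_genes * n_samples), nrow = n_genes)
  })
  y <- x * r + e * sqrt(1 - r^2)
  dimnames(x) <- dimnames(y) <- list(genes, samples)
  names(set_of_gene) <- names(rho_target) <- genes
  list(mrna = x, protein = y,
       truth = list(set_of_gene = set_of_gene,
                    true_rho_per_gene = rho_target))
}
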