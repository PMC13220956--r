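#' Star annotation of p values
#'
#' Bins a p value into the conventional significance stars:
#' `0.01 <= p < 0.05` one star, `0.001 <= p < 0.01` two, `0.0001 <= p <
#' 0.001` three, `p < 0.0001` four; `p >= 0.05` is `"ns"`.
#'
#' @param p Numeric vector of p values in (0, 1].
#' @return Character vector of `ns`, `*`, `**`, `***`, `****`.
#' @export
star_annotation <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_input("p values must lie in (0, 1]")
  cut(p, breaks = c(0, 1e-4, 1e-3, 1e-2, 5e-2, 1),
      labels = c("****", "***", "**", "*", "ns"),
      right = FALSE, include.lowest = FALSE) |>
    as.character() |>
    (\(x) ifelse(p == 1, "ns", x))()
}

#' Export significant genes for signalling-pathway impact analysis
#'
#' Restricts a differential table to significant genes with
#' `|log2fc| > lfc_cut_spia` (strictly), the input convention of external
#' pathway-topology tools; the analysis itself is not run here.
#'
#' @param table A `de_table` with `direction` filled.
#' @param thresholds A [deg_thresholds()]; `lfc_cut_spia` (default 1) is the
#'   export cut.
#' @param path Optional TSV output path.
#' @return A tibble `gene`, `log2fc` of exported genes.
#' @export
export_spia_input <- function(table, thresholds = deg_thresholds(), path = NULL) {
  stopifnot(all(c("gene", "log2fc", "direction") %in% names(table)))
  out <- table |>
    filter(.data$direction != "none",
           abs(.data$log2fc) > thresholds$lfc_cut_spia) |>
    select("gene", "log2fc") |>
    as_tibble()
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Pipeline configuration
#'
#' One structured object holding every threshold the pipeline applies, the
#' simulator configs that generate its inputs, the global seed and the
#' output directory. Unknown keys are rejected.
#'
#' @param out_dir Output directory.
#' @param seed Global seed; stage seeds are derived from it.
#' @param deg [deg_thresholds()] overrides (list).
#' @param consensus [consensus_rules()] overrides (list).
#' @param caller [caller_thresholds()] overrides (list).
#' @param bulk [bulk_panel_config()] overrides (list).
#' @param single_cell [single_cell_config()] overrides (list).
#' @param ligrec List with `n_perm` and `alpha`.
#' @param concordance List with `alpha` and `min_pairs`.
#' @param region List with `n_regions`.
#' @param omics List with `n_genes`, `n_samples`, `rho_by_set`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("senescreen_run_"), seed = 1L,
                            deg = list(), consensus = list(), caller = list(),
                            bulk = list(), single_cell = list(),
                            ligrec = list(n_perm = 1000L, alpha = 0.05),
                            concordance = list(alpha = 0.05, min_pairs = 4L),
                            region = list(n_regions = 5L),
                            omics = list(n_genes = 400L, n_samples = 99L,
                                         rho_by_set = c(markers = 0.6,
                                                        background = 0.2))) {
  check_count(seed, "seed")
  known_sub <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop_config("unknown config key(s) in %s: %s", where,
                  paste(extra, collapse = ", "))
    x
  }
  known_sub(ligrec, c("n_perm", "alpha"), "ligrec")
  known_sub(concordance, c("alpha", "min_pairs"), "concordance")
  known_sub(region, c("n_regions", "up_boost", "down_factor", "noise_sd"), "region")
  known_sub(omics, c("n_genes", "n_samples", "rho_by_set"), "omics")
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              deg = do.call(deg_thresholds, deg),
              consensus = do.call(consensus_rules, consensus),
              caller = do.call(caller_thresholds, caller),
              bulk = do.call(bulk_panel_config,
                             modifyList(list(seed = seed), bulk)),
              single_cell = do.call(single_cell_config,
                                    modifyList(list(seed = seed + 1L), single_cell)),
              ligrec = modifyList(list(n_perm = 1000L, alpha = 0.05), ligrec),
              concordance = modifyList(list(alpha = 0.05, min_pairs = 4L), concordance),
              region = modifyList(list(n_regions = 5L, up_boost = 3,
                                       down_factor = 0.25, noise_sd = 0.2), region),
              omics = modifyList(list(n_genes = 400L, n_samples = 99L,
                                      rho_by_set = c(markers = 0.6,
                                                     background = 0.2)), omics))
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' `read_pipeline_config()` rebuilds the validated object, so a parse ->
#' serialize -> parse round trip is the identity on the stored keys.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- lapply(unclass(config), function(x)
    if (is.list(x) || inherits(x, "deg_thresholds")) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("out_dir", "seed", "deg", "consensus", "caller", "bulk",
             "single_cell", "ligrec", "concordance", "region", "omics")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop_config("unknown config key(s): %s", paste(extra, collapse = ", "))
  raw$ligrec$n_perm <- as.integer(raw$ligrec$n_perm %||% 1000L)
  if (!is.null(raw$omics$rho_by_set))
    raw$omics$rho_by_set <- unlist(raw$omics$rho_by_set)
  do.call(pipeline_config, raw)
}

#' Run the senescence-detection pipeline on synthetic inputs
#'
#' Executes the requested stages in dependency order on seeded synthetic
#' data: `simulate` (all generators), `de` (per-dataset moderated DE),
#' `consensus` (marker panel, written as GMT), `sc-call` (four-criterion
#' caller + escape report), `region-score`, `ligrec`, `concordance`,
#' `overlap`, and `report` (run record). Every stage writes its outputs
#' under `config$out_dir` and the run record captures the config, seed,
#' stage timings and package version.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, a list with all in-memory stage results plus
#'   `run_record`.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all") {
  all_stages <- c("simulate", "de", "consensus", "sc-call", "region-score",
                  "ligrec", "concordance", "overlap", "report")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown))
    stop_config("unknown stage(s): %s", paste(unknown, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  timings <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    out <- expr
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    out
  }
  need <- function(what, stage) {
    if (is.null(res[[what]]))
      rlang::abort(sprintf("stage '%s' requires artifact '%s'; run its stage first",
                           stage, what), class = "senescreen_dependency_error")
  }

  if ("simulate" %in% stages) {
    res$bulk <- tick("simulate_bulk", simulate_bulk_panel(config$bulk))
    res$panel_synth <- synthetic_marker_panel()
    res$sc <- tick("simulate_sc",
                   simulate_single_cell(config$single_cell, res$panel_synth,
                                        config$caller))
    res$region <- tick("simulate_region", do.call(simulate_region_matrix,
      c(list(panel = res$panel_synth, seed = config$seed + 2L), config$region)))
    res$omics <- tick("simulate_omics", simulate_paired_omics(
      n_genes = config$omics$n_genes, n_samples = config$omics$n_samples,
      rho_by_set = config$omics$rho_by_set, seed = config$seed + 3L))
    write_ground_truth(list(bulk = res$bulk$truth, single_cell = res$sc$truth,
                            region = res$region$truth,
                            omics = lapply(res$omics$truth, as.list)),
                       file.path(config$out_dir, "ground_truth.json"))
  }

  if ("de" %in% stages) {
    need("bulk", "de")
    res$de_tables <- tick("de", purrr::map(res$bulk$datasets, function(d)
      call_degs(fit_moderated(d$matrix, d$groups), config$deg)))
    purrr::iwalk(res$de_tables, function(tb, nm)
      write_de_tsv(tb, file.path(config$out_dir, paste0("de_", nm, ".tsv"))))
  }

  if ("consensus" %in% stages) {
    need("de_tables", "consensus")
    res$panel <- tick("consensus", derive_marker_panel(
      res$de_tables, config$consensus,
      sasp = res$panel_synth$sasp, ecm = res$panel_synth$ecm))
    write_panel_gmt(res$panel, file.path(config$out_dir, "marker_panel.gmt"))
    cons <- consensus_markers(res$de_tables, config$consensus)
    jsonlite::write_json(
      list(thresholds = unclass(config$consensus),
           votes = cons[cons$consensus != "none", ]),
      file.path(config$out_dir, "consensus_provenance.json"),
      auto_unbox = TRUE, digits = NA)
  }

  if ("sc-call" %in% stages) {
    need("sc", "sc-call"); need("panel", "sc-call")
    res$calls <- tick("sc_call", score_cells(res$sc$counts, res$panel,
                                             config$caller, res$sc$clusters))
    write.table(as_tibble(res$calls), file.path(config$out_dir, "cell_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    comp <- summarize_clusters(res$calls)
    write.table(comp, file.path(config$out_dir, "cluster_composition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$escape <- tick("escape", detect_escape(res$sc$counts, res$panel,
                                               config$caller, res$sc$clusters))
    jsonlite::write_json(res$escape[c("frac_of_p21_sasp_cells_expressing_mki67",
                                      "frac_escape_expressing_pcna",
                                      "frac_escape_expressing_mcm",
                                      "n_base", "n_escape")],
                         file.path(config$out_dir, "escape_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("region-score" %in% stages) {
    need("region", "region-score"); need("panel", "region-score")
    need("de_tables", "region-score")
    rp <- region_marker_panel(consensus_markers(res$de_tables, config$consensus),
                              res$de_tables, config$consensus)
    res$region_scores <- tick("region_score",
                              score_regions(res$region$fpkm, rp$up, rp$down))
    write.table(as_tibble(res$region_scores),
                file.path(config$out_dir, "region_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("ligrec" %in% stages) {
    need("sc", "ligrec")
    sasp <- res$panel_synth$sasp
    pairs <- lr_pairs(ligand = sasp[1:10],
                      receptor = colnames(res$sc$counts)[grep("^BG",
                        colnames(res$sc$counts))][1:10])
    res$ligrec <- tick("ligrec", lr_permutation_test(
      res$sc$counts, res$sc$clusters, pairs,
      n_perm = config$ligrec$n_perm, alpha = config$ligrec$alpha,
      seed = config$seed + 4L))
    write.table(as_tibble(res$ligrec), file.path(config$out_dir, "ligrec.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cm <- count_significant(res$ligrec, config$ligrec$alpha)
    write.table(data.frame(sender = rownames(cm), cm, check.names = FALSE),
                file.path(config$out_dir, "ligrec_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("concordance" %in% stages) {
    need("omics", "concordance")
    rho <- tick("concordance", spearman_per_gene(res$omics$mrna, res$omics$protein,
                                                 min_pairs = config$concordance$min_pairs))
    rho$set <- res$omics$truth$set_of_gene[rho$gene]
    res$concordance <- rho
    sets <- split(rho, rho$set)
    if (all(c("markers", "background") %in% names(sets)))
      res$rho_comparison <- compare_rho_sets(sets$markers$rho, sets$background$rho)
    res$frac_significant <- vapply(sets, function(s)
      fraction_significant(s$p, config$concordance$alpha), numeric(1L))
    write.table(rho, file.path(config$out_dir, "spearman_per_gene.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(fraction_significant = as.list(res$frac_significant),
                              comparison = res$rho_comparison),
                         file.path(config$out_dir, "concordance.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("overlap" %in% stages) {
    need("de_tables", "overlap"); need("panel", "overlap")
    # proteome stand-in: moderated DE on the first simulated dataset serves
    # as the protein-level table for the overlap summary on synthetic runs
    res$overlap <- tick("overlap",
                        proteome_marker_overlap(res$de_tables[[1L]], res$panel))
    jsonlite::write_json(res$overlap, file.path(config$out_dir, "overlap_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("report" %in% stages) {
    res$run_record <- list(
      version = as.character(packageVersion("senescreen")),
      seed = config$seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      stage_timings = timings,
      thresholds = list(deg = unclass(config$deg),
                        consensus = unclass(config$consensus),
                        caller = unclass(config$caller),
                        ligrec = config$ligrec,
                        concordance = config$concordance))
    jsonlite::write_json(res$run_record, file.path(config$out_dir, "run_record.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res)
}
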