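#' Rules for consensus and common marker derivation
#'
#' @param min_datasets Minimum number of datasets in which a gene must be a
#'   same-direction DEG to enter the consensus (default 3).
#' @param common_up_fc Linear fold-change cut for the common up list (default
#'   1.7, applied to `2^log2fc`).
#' @param common_up_min_datasets Number of datasets in which the common-up
#'   fold-change cut must hold (default 4).
#' @param common_down_fc Linear fold-change cut for the common down list
#'   (default 0.5), required in all datasets.
#' @param n_common_up,n_common_down Truncation sizes of the common lists
#'   (defaults 8 and 7).
#' @param n_region_down Size of the most-downregulated panel used for region
#'   scoring (default 133).
#' @param exclusive Logical; when `TRUE` (default) a consensus gene must have
#'   zero opposite-direction DEG calls, when `FALSE` a same-direction majority
#'   of at least `min_datasets` suffices.
#' @return A list of class `consensus_rules`.
#' @export
consensus_rules <- function(min_datasets = 3L, common_up_fc = 1.7,
                            common_up_min_datasets = 4L, common_down_fc = 0.5,
                            n_common_up = 8L, n_common_down = 7L,
                            n_region_down = 133L, exclusive = TRUE) {
  check_count(min_datasets, "min_datasets", 1L)
  check_number(common_up_fc, "common_up_fc", 0, strict_lower = TRUE)
  check_number(common_down_fc, "common_down_fc", 0, strict_lower = TRUE)
  check_count(common_up_min_datasets, "common_up_min_datasets", 1L)
  check_count(n_common_up, "n_common_up", 1L)
  check_count(n_common_down, "n_common_down", 1L)
  check_count(n_region_down, "n_region_down", 1L)
  structure(list(min_datasets = min_datasets, common_up_fc = common_up_fc,
                 common_up_min_datasets = common_up_min_datasets,
                 common_down_fc = common_down_fc, n_common_up = n_common_up,
                 n_common_down = n_common_down, n_region_down = n_region_down,
                 exclusive = isTRUE(exclusive)),
            class = "consensus_rules")
}

# Long per-gene-per-dataset view of a list of DE tables.
de_tables_long <- function(tables) {
  stopifnot(is.list(tables), length(tables) > 0L)
  if (is.null(names(tables))) names(tables) <- paste0("dataset", seq_along(tables))
  purrr::imap_dfr(tables, function(tb, nm) {
    stopifnot(all(c("gene", "log2fc", "direction") %in% names(tb)))
    tibble(dataset = nm, gene = tb$gene, log2fc = tb$log2fc,
           direction = tb$direction)
  })
}

#' Consensus senescence markers across datasets
#'
#' A gene enters `consensus_up` when it is an up-DEG in at least
#' `min_datasets` of the supplied per-dataset tables and (under the default
#' exclusive rule) a down-DEG in none; `consensus_down` is symmetric.
#'
#' @param tables Named list of `de_table`s with `direction` filled (see
#'   [call_degs()]); all tables must share a gene namespace (one row per gene
#'   symbol).
#' @param rules A [consensus_rules()] object.
#' @return A tibble with one row per gene: `gene`, `n_up`, `n_down`,
#'   `n_datasets` (tables in which the gene appears), `mean_log2fc` (across
#'   all tables reporting the gene) and `consensus` in `up`/`down`/`none`.
#' @export
consensus_markers <- function(tables, rules = consensus_rules()) {
  if (length(tables) < rules$min_datasets)
    stop_input("need at least min_datasets = %d tables, got %d",
               rules$min_datasets, length(tables))
  long <- de_tables_long(tables)
  votes <- long |>
    group_by(.data$gene) |>
    summarise(n_up = sum(.data$direction == "up"),
              n_down = sum(.data$direction == "down"),
              n_datasets = dplyr::n(),
              mean_log2fc = mean(.data$log2fc), .groups = "drop")
  if (rules$exclusive) {
    votes <- mutate(votes, consensus = dplyr::case_when(
      .data$n_up >= rules$min_datasets & .data$n_down == 0L ~ "up",
      .data$n_down >= rules$min_datasets & .data$n_up == 0L ~ "down",
      TRUE ~ "none"))
  } else {
    votes <- mutate(votes, consensus = dplyr::case_when(
      .data$n_up >= rules$min_datasets & .data$n_up > .data$n_down ~ "up",
      .data$n_down >= rules$min_datasets & .data$n_down > .data$n_up ~ "down",
      TRUE ~ "none"))
  }
  votes
}

#' Common (core) senescence marker lists
#'
#' From the consensus sets, selects the short lists used by the single-cell
#' caller: the most upregulated genes with linear fold change above
#' `common_up_fc` in at least `common_up_min_datasets` datasets, and the most
#' downregulated genes with linear fold change below `common_down_fc` in all
#' datasets; each ranked by mean log2 fold change and truncated.
#'
#' @inheritParams consensus_markers
#' @param consensus The tibble returned by [consensus_markers()] on the same
#'   tables.
#' @return A list with ordered character vectors `common_up` and
#'   `common_down`.
#' @export
common_marker_set <- function(tables, consensus, rules = consensus_rules()) {
  long <- de_tables_long(tables)
  fc_votes <- long |>
    group_by(.data$gene) |>
    summarise(n_fc_up = sum(2^.data$log2fc > rules$common_up_fc),
              n_fc_down_all = all(2^.data$log2fc < rules$common_down_fc),
              mean_log2fc = mean(.data$log2fc), .groups = "drop")

  up_genes <- consensus$gene[consensus$consensus == "up"]
  down_genes <- consensus$gene[consensus$consensus == "down"]

  common_up <- fc_votes |>
    filter(.data$gene %in% up_genes,
           .data$n_fc_up >= rules$common_up_min_datasets) |>
    arrange(desc(.data$mean_log2fc)) |>
    slice_head(n = rules$n_common_up) |>
    pull("gene")
  common_down <- fc_votes |>
    filter(.data$gene %in% down_genes, .data$n_fc_down_all) |>
    arrange(.data$mean_log2fc) |>
    slice_head(n = rules$n_common_down) |>
    pull("gene")

  if (length(common_up) == 0L) rlang::warn("no gene qualifies for common_up")
  if (length(common_down) == 0L) rlang::warn("no gene qualifies for common_down")
  list(common_up = common_up, common_down = common_down)
}

#' Marker panel for region scoring
#'
#' The region score uses all consensus up markers and the `n_region_down`
#' most downregulated consensus markers (ranked by mean log2 fold change
#' across datasets, ascending).
#'
#' @inheritParams common_marker_set
#' @return A list with `up` (all consensus up genes) and `down` (the
#'   truncated most-down list, most downregulated first).
#' @export
region_marker_panel <- function(consensus, tables, rules = consensus_rules()) {
  long <- de_tables_long(tables)
  mean_fc <- long |>
    group_by(.data$gene) |>
    summarise(mean_log2fc = mean(.data$log2fc), .groups = "drop")
  down_genes <- consensus$gene[consensus$consensus == "down"]
  ranked_down <- mean_fc |>
    filter(.data$gene %in% down_genes) |>
    arrange(.data$mean_log2fc) |>
    pull("gene")
  if (length(ranked_down) < rules$n_region_down)
    rlang::warn(sprintf("only %d consensus down genes available (< n_region_down = %d); taking all",
                        length(ranked_down), rules$n_region_down))
  list(up = consensus$gene[consensus$consensus == "up"],
       down = head(ranked_down, rules$n_region_down))
}

#' Assemble a marker panel from per-dataset DE tables
#'
#' Convenience wrapper running [consensus_markers()], [common_marker_set()]
#' and recording provenance, then merging in SASP/ECM sets (supplied by the
#' user, e.g. from GMT files) and the default CDKi/MCM/proliferation sets.
#'
#' @inheritParams consensus_markers
#' @param sasp,ecm Character vectors of SASP / ECM genes.
#' @return A [marker_panel()].
#' @export
derive_marker_panel <- function(tables, rules = consensus_rules(),
                                sasp = character(), ecm = character()) {
  cons <- consensus_markers(tables, rules)
  common <- common_marker_set(tables, cons, rules)
  marker_panel(
    consensus_up = cons$gene[cons$consensus == "up"],
    consensus_down = cons$gene[cons$consensus == "down"],
    common_up = common$common_up, common_down = common$common_down,
    sasp = sasp, ecm = ecm,
    provenance = list(rules = unclass(rules),
                      n_datasets = length(tables))
  )
}
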