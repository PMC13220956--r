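#' Thresholds for the single-cell senescence caller
#'
#' @param up_sum_min Minimum cumulative expression of the up-marker panel
#'   (criterion 1), in the units of the input matrix; default 1000. Because
#'   the scale depends on the normalisation of the matrix, inspect
#'   [up_sum_distribution()] to recalibrate for other normalisations.
#' @param down_tolerance Maximum summed down-marker expression still counted
#'   as "absent" (criterion 2); default 0, i.e. hard zeros.
#' @param top_quantile Fraction of cells counted as high-SASP / high-ECM
#'   (criteria 3 and 4); default 0.15 (top 15%). Ties at the quantile
#'   boundary all pass.
#' @param min_cdki_expressed Minimum number of CDK-inhibitor genes with
#'   non-zero expression (the CDKi-positivity criterion of the combined
#'   call); default 1.
#' @param up_panel Which panel feeds criterion 1: `"common_up"` (default) or
#'   `"consensus_up"`.
#' @param mcm_rule `"any"` (default): one MCM2-7 gene expressed counts as MCM
#'   complex expression; `"all"`: all six required.
#' @return A list of class `caller_thresholds`.
#' @export
caller_thresholds <- function(up_sum_min = 1000, down_tolerance = 0,
                              top_quantile = 0.15, min_cdki_expressed = 1L,
                              up_panel = c("common_up", "consensus_up"),
                              mcm_rule = c("any", "all")) {
  check_number(up_sum_min, "up_sum_min", 0, strict_lower = TRUE)
  check_number(down_tolerance, "down_tolerance", 0)
  check_number(top_quantile, "top_quantile", 0, 1, strict_lower = TRUE,
               strict_upper = TRUE)
  check_count(min_cdki_expressed, "min_cdki_expressed", 1L)
  structure(list(up_sum_min = up_sum_min, down_tolerance = down_tolerance,
                 top_quantile = top_quantile,
                 min_cdki_expressed = min_cdki_expressed,
                 up_panel = match.arg(up_panel), mcm_rule = match.arg(mcm_rule)),
            class = "caller_thresholds")
}

panel_genes_in_matrix <- function(m, genes, set, required = TRUE) {
  present <- intersect(genes, colnames(m))
  if (length(present) == 0L) {
    if (required)
      stop_input("no gene of panel set '%s' is present in the matrix", set)
  } else if (length(present) < length(genes)) {
    message(sprintf("%d/%d genes of set '%s' absent from the matrix",
                    length(genes) - length(present), length(genes), set))
  }
  present
}

#' Call senescent cells by the four-criterion rule
#'
#' Flags each cell on: (1) cumulative expression of the up-marker panel above
#' `up_sum_min`; (2) summed down-marker expression at or below
#' `down_tolerance` (absence of the downregulated markers); (3) SASP total in
#' the top `top_quantile` of cells; (4) ECM total in the top `top_quantile`;
#' plus CDK-inhibitor positivity (at least `min_cdki_expressed` CDKi genes
#' detected). A cell is called senescent when all criteria hold.
#'
#' @param x Cell-by-gene expression matrix (cells in rows, columns named by
#'   gene), dense or sparse, or a data frame with a leading cell-id column.
#' @param panel A [marker_panel()] providing `common_up`/`consensus_up`,
#'   `common_down`, `sasp`, `ecm`, `cdki` sets.
#' @param thresholds A [caller_thresholds()] object.
#' @param clusters Optional vector of per-cell cluster labels.
#' @return A `senescence_calls` tibble with one row per cell: `cell`,
#'   `cluster`, `c1_up_sum`, `c2_down_absent`, `c3_sasp_top`, `c4_ecm_top`,
#'   `c5_cdki`, `sasp_total`, `ecm_total`, `senescent`.
#' @export
score_cells <- function(x, panel, thresholds = caller_thresholds(),
                        clusters = NULL) {
  m <- as_cell_matrix(x)
  if (nrow(m) == 0L) stop_input("empty expression matrix")
  thr <- thresholds
  up_set <- panel[[thr$up_panel]]
  sets <- list(up = up_set, down = panel$common_down, sasp = panel$sasp,
               ecm = panel$ecm, cdki = panel$cdki)
  present <- purrr::imap(sets, ~ panel_genes_in_matrix(m, .x, .y))

  up_sum <- row_sum_over(m, present$up)
  down_sum <- row_sum_over(m, present$down)
  sasp_total <- row_sum_over(m, present$sasp)
  ecm_total <- row_sum_over(m, present$ecm)
  n_cdki <- row_sum_over(m, present$cdki, count_positive = TRUE)

  sasp_thr <- top_quantile_threshold(sasp_total, thr$top_quantile)
  ecm_thr <- top_quantile_threshold(ecm_total, thr$top_quantile)

  calls <- tibble(
    cell = rownames(m),
    cluster = if (is.null(clusters)) NA_character_ else as.character(clusters),
    c1_up_sum = up_sum,
    c2_down_absent = down_sum <= thr$down_tolerance,
    c3_sasp_top = sasp_total >= sasp_thr,
    c4_ecm_top = ecm_total >= ecm_thr,
    c5_cdki = n_cdki >= thr$min_cdki_expressed,
    sasp_total = sasp_total,
    ecm_total = ecm_total
  )
  calls$senescent <- calls$c1_up_sum > thr$up_sum_min & calls$c2_down_absent &
    calls$c3_sasp_top & calls$c4_ecm_top & calls$c5_cdki
  structure(calls, class = c("senescence_calls", class(calls)),
            thresholds = thr,
            quantile_cutoffs = c(sasp = sasp_thr, ecm = ecm_thr))
}

as_cell_matrix <- function(x) {
  if (is.data.frame(x)) {
    first <- x[[1L]]
    if (is.character(first) || is.factor(first)) {
      m <- as.matrix(x[-1L]); rownames(m) <- as.character(first)
    } else m <- as.matrix(x)
  } else m <- x
  if (!is.matrix(m) && !methods::is(m, "Matrix"))
    stop_input("`x` must be a cell-by-gene matrix or data frame")
  if (nrow(m) == 0L) stop_input("empty expression matrix")
  if (is.null(rownames(m))) rownames(m) <- paste0("cell", seq_len(nrow(m)))
  m
}

row_sum_over <- function(m, genes, count_positive = FALSE) {
  sub <- m[, genes, drop = FALSE]
  if (count_positive) sub <- sub > 0
  as.numeric(Matrix::rowSums(sub))
}

#' Up-marker cumulative-expression distribution
#'
#' Helper for recalibrating `up_sum_min` on differently normalised matrices:
#' returns quantiles of the per-cell up-panel sum.
#'
#' @inheritParams score_cells
#' @param probs Quantile probabilities.
#' @return A tibble of quantiles of the per-cell cumulative up-marker
#'   expression.
#' @export
up_sum_distribution <- function(x, panel, thresholds = caller_thresholds(),
                                probs = c(0.5, 0.75, 0.9, 0.95, 0.99, 1)) {
  m <- as_cell_matrix(x)
  genes <- panel_genes_in_matrix(m, panel[[thresholds$up_panel]],
                                 thresholds$up_panel)
  q <- quantile(row_sum_over(m, genes), probs = probs)
  tibble(quantile = probs, up_sum = as.numeric(q))
}

#' Cluster composition of senescent cells
#'
#' @param calls A `senescence_calls` tibble with cluster labels.
#' @return A tibble `cluster`, `n`, `fraction`; fractions over senescent
#'   cells sum to 1.
#' @export
summarize_clusters <- function(calls) {
  if (any(is.na(calls$cluster)))
    stop_input("cluster labels are required for all cells")
  sen <- filter(calls, .data$senescent)
  if (nrow(sen) == 0L) {
    rlang::warn("no senescent cells called; empty composition")
    return(tibble(cluster = character(), n = integer(), fraction = numeric()))
  }
  sen |>
    count(.data$cluster, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(desc(.data$fraction))
}

#' Detect senescence-escape cells
#'
#' The escape base set is cells expressing p21 (CDKN1A > 0) with SASP totals
#' in the top `top_quantile` (the same high-SASP rule as the main caller).
#' Escape cells are base-set cells that also express the proliferation marker
#' MKI67; the report gives the escape fraction of the base set and, among
#' escape cells, the fractions expressing PCNA and the MCM complex, plus the
#' escape cells' cluster composition.
#'
#' @inheritParams score_cells
#' @return An `escape_report` list: `escape_cell_ids`, `base_cell_ids`,
#'   `frac_of_p21_sasp_cells_expressing_mki67`, `frac_escape_expressing_pcna`,
#'   `frac_escape_expressing_mcm`, `cluster_composition` (tibble), `n_base`,
#'   `n_escape`, `undefined` flag (TRUE when the base set is empty).
#' @export
detect_escape <- function(x, panel, thresholds = caller_thresholds(),
                          clusters = NULL) {
  m <- as_cell_matrix(x)
  for (g in c("CDKN1A", "MKI67", "PCNA"))
    if (!g %in% colnames(m)) stop_input("gene %s is required in the matrix", g)
  mcm_present <- intersect(panel$mcm, colnames(m))
  if (length(mcm_present) == 0L)
    stop_input("at least one MCM2-7 gene is required in the matrix")
  sasp_genes <- panel_genes_in_matrix(m, panel$sasp, "sasp")

  sasp_total <- row_sum_over(m, sasp_genes)
  sasp_thr <- top_quantile_threshold(sasp_total, thresholds$top_quantile)
  base <- as.numeric(m[, "CDKN1A"]) > 0 & sasp_total >= sasp_thr
  escape <- base & as.numeric(m[, "MKI67"]) > 0

  if (!any(base)) {
    rlang::warn("no p21+/high-SASP cells; escape fractions undefined")
    return(structure(list(
      escape_cell_ids = character(), base_cell_ids = character(),
      frac_of_p21_sasp_cells_expressing_mki67 = NA_real_,
      frac_escape_expressing_pcna = NA_real_,
      frac_escape_expressing_mcm = NA_real_,
      cluster_composition = tibble(cluster = character(), n = integer(),
                                   fraction = numeric()),
      n_base = 0L, n_escape = 0L, undefined = TRUE), class = "escape_report"))
  }

  esc_ids <- rownames(m)[escape]
  mcm_pos <- row_sum_over(m, mcm_present, count_positive = TRUE)
  mcm_ok <- if (thresholds$mcm_rule == "all")
    mcm_pos == length(mcm_present) else mcm_pos >= 1
  comp <- if (!is.null(clusters) && any(escape)) {
    tibble(cluster = as.character(clusters)[escape]) |>
      count(.data$cluster, name = "n") |>
      mutate(fraction = .data$n / sum(.data$n)) |>
      arrange(desc(.data$fraction))
  } else tibble(cluster = character(), n = integer(), fraction = numeric())

  structure(list(
    escape_cell_ids = esc_ids,
    base_cell_ids = rownames(m)[base],
    frac_of_p21_sasp_cells_expressing_mki67 = sum(escape) / sum(base),
    frac_escape_expressing_pcna =
      if (any(escape)) mean(as.numeric(m[escape, "PCNA"]) > 0) else NA_real_,
    frac_escape_expressing_mcm =
      if (any(escape)) mean(mcm_ok[escape]) else NA_real_,
    cluster_composition = comp,
    n_base = sum(base), n_escape = sum(escape), undefined = FALSE
  ), class = "escape_report")
}

#' @export
print.escape_report <- function(x, ...) {
  cat("<escape_report>\n")
  cat(sprintf("  p21+/high-SASP cells: %d; escape (MKI67+): %d (%.1f%%)\n",
              x$n_base, x$n_escape,
              100 * x$frac_of_p21_sasp_cells_expressing_mki67))
  if (x$n_escape > 0)
    cat(sprintf("  escape cells PCNA+: %.1f%%; MCM complex+: %.1f%%\n",
                100 * x$frac_escape_expressing_pcna,
                100 * x$frac_escape_expressing_mcm))
  invisible(x)
}

#' @export
tidy.escape_report <- function(x, ...) {
  tibble(
    metric = c("frac_of_p21_sasp_cells_expressing_mki67",
               "frac_escape_expressing_pcna", "frac_escape_expressing_mcm"),
    value = c(x$frac_of_p21_sasp_cells_expressing_mki67,
              x$frac_escape_expressing_pcna, x$frac_escape_expressing_mcm)
  )
}

#' Compare a gene's expression between senescent and non-senescent cells
#'
#' Mann-Whitney U test (normal approximation with tie correction for large
#' samples, exact otherwise), two-sided, with the star annotation of
#' [star_annotation()].
#'
#' @inheritParams score_cells
#' @param calls A `senescence_calls` tibble aligned with the rows of `x`.
#' @param gene Gene (column) name.
#' @return A one-row tibble `gene`, `U`, `p`, `stars`, `median_senescent`,
#'   `median_other`.
#' @export
compare_expression <- function(x, calls, gene) {
  m <- as_cell_matrix(x)
  if (!gene %in% colnames(m)) stop_input("gene %s not in matrix", gene)
  v <- as.numeric(m[, gene])
  g1 <- v[calls$senescent]
  g2 <- v[!calls$senescent]
  if (length(g1) == 0L || length(g2) == 0L)
    stop_input("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(g1, g2, alternative = "two.sided"))
  tibble(gene = gene, U = unname(wt$statistic), p = wt$p.value,
         stars = star_annotation(wt$p.value),
         median_senescent = median(g1), median_other = median(g2))
}

#' @export
glance.senescence_calls <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_senescent = sum(x$senescent),
    frac_senescent = mean(x$senescent),
    n_c1 = sum(x$c1_up_sum > attr(x, "thresholds")$up_sum_min),
    n_c2 = sum(x$c2_down_absent), n_c3 = sum(x$c3_sasp_top),
    n_c4 = sum(x$c4_ecm_top), n_c5 = sum(x$c5_cdki)
  )
}

#' Up-marker sum distribution plot with the calling threshold
#'
#' @param object A `senescence_calls` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.senescence_calls <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$c1_up_sum + 1,
                                       fill = .data$senescent)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.8, position = "identity") +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = thr$up_sum_min, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60")) +
    ggplot2::labs(x = "cumulative up-marker expression (+1)", y = "cells",
                  fill = "senescent") +
    ggplot2::theme_minimal()
}
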