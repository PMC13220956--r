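#' Per-gene Spearman mRNA-protein correlation
#'
#' Average-rank Spearman correlation per gene over pairwise-complete samples,
#' with a two-sided p value from the t approximation. Genes with fewer than
#' `min_pairs` complete mRNA/protein pairs are skipped (logged via message).
#'
#' @param mrna,protein Gene-by-sample numeric matrices (rows named by gene,
#'   columns by sample) or data frames with a leading gene column. Genes and
#'   samples are matched by name; missing values are allowed.
#' @param min_pairs Minimum complete pairs per gene (default 4).
#' @return A tibble `gene`, `n`, `rho`, `p` for tested genes.
#' @export
spearman_per_gene <- function(mrna, protein, min_pairs = 4L) {
  mm <- as_expression_matrix(mrna, "mrna")
  pm <- as_expression_matrix(protein, "protein")
  genes <- intersect(rownames(mm), rownames(pm))
  samples <- intersect(colnames(mm), colnames(pm))
  if (length(genes) == 0L || length(samples) < min_pairs)
    stop_input("mrna and protein must share genes and at least %d samples", min_pairs)
  mm <- mm[genes, samples, drop = FALSE]
  pm <- pm[genes, samples, drop = FALSE]

  res <- purrr::map(genes, function(g) {
    xi <- mm[g, ]; yi <- pm[g, ]
    ok <- is.finite(xi) & is.finite(yi)
    if (sum(ok) < min_pairs) return(NULL)
    ct <- suppressWarnings(cor.test(xi[ok], yi[ok], method = "spearman",
                                    exact = FALSE, alternative = "two.sided"))
    tibble(gene = g, n = sum(ok), rho = unname(ct$estimate), p = ct$p.value)
  })
  skipped <- sum(purrr::map_lgl(res, is.null))
  if (skipped > 0L)
    message(sprintf("%d gene(s) skipped (< %d complete pairs)", skipped, min_pairs))
  bind_rows(res)
}

#' Compare Spearman correlations of a gene set against the background
#'
#' @param rhos_set,rhos_background Numeric vectors of per-gene correlation
#'   coefficients.
#' @return A one-row tibble `median_set`, `median_background`, `U`, `p`
#'   (two-sided Mann-Whitney), `stars`.
#' @export
compare_rho_sets <- function(rhos_set, rhos_background) {
  if (length(rhos_set) == 0L || length(rhos_background) == 0L)
    stop_input("both correlation sets must be non-empty")
  wt <- suppressWarnings(wilcox.test(rhos_set, rhos_background,
                                     alternative = "two.sided"))
  tibble(median_set = median(rhos_set),
         median_background = median(rhos_background),
         U = unname(wt$statistic), p = wt$p.value,
         stars = star_annotation(wt$p.value))
}

#' Fraction of genes with a significant correlation
#'
#' Fraction of tested genes with raw `p < alpha` (raw, not adjusted).
#'
#' @param p Numeric vector of per-gene p values.
#' @param alpha Significance level (default 0.05).
#' @return A single number in \[0, 1\].
#' @export
fraction_significant <- function(p, alpha = 0.05) {
  if (length(p) == 0L) stop_input("need at least one tested gene")
  mean(p < alpha)
}

#' Phosphosite prevalence and tumor-vs-normal comparison
#'
#' Prevalence is the fraction of tumor samples in which the site has a
#' non-missing normalized intensity (detection without imputation); the
#' group comparison is a two-sided Welch t test on available intensities.
#'
#' @param table Long-format phosphosite tibble with columns `protein`,
#'   `residue` (S/T/Y), `position`, `sample`, `class` (`tumor`/`normal`) and
#'   `intensity` (NA = not detected).
#' @param protein,residue,position Site key.
#' @return A one-row tibble `site`, `prevalence_tumor`, `n_tumor`,
#'   `n_normal`, `t`, `df`, `p`, `stars` (test columns NA when a class has
#'   fewer than 2 intensities).
#' @export
phospho_prevalence <- function(table, protein, residue, position) {
  stopifnot(all(c("protein", "residue", "position", "sample", "class",
                  "intensity") %in% names(table)))
  site <- filter(table, .data$protein == !!protein,
                 .data$residue == !!residue, .data$position == !!position)
  if (nrow(site) == 0L)
    stop_input("site %s-%s%d not present in the table", protein, residue, position)
  tum <- filter(site, .data$class == "tumor")
  nor <- filter(site, .data$class == "normal")
  prevalence <- mean(!is.na(tum$intensity))
  ti <- tum$intensity[!is.na(tum$intensity)]
  ni <- nor$intensity[!is.na(nor$intensity)]
  if (length(ti) >= 2L && length(ni) >= 2L) {
    tt <- t.test(ti, ni, var.equal = FALSE, alternative = "two.sided")
    tv <- unname(tt$statistic); dfv <- unname(tt$parameter); pv <- tt$p.value
    stars <- star_annotation(pv)
  } else {
    tv <- NA_real_; dfv <- NA_real_; pv <- NA_real_; stars <- NA_character_
  }
  tibble(site = sprintf("%s-%s%d", protein, residue, position),
         prevalence_tumor = prevalence, n_tumor = nrow(tum),
         n_normal = nrow(nor), t = tv, df = dfv, p = pv, stars = stars)
}

#' Overlap of marker panel sets with a proteome DE table
#'
#' For each panel set, reports how member genes behave in a protein-level
#' differential table: fractions up / down / detected-but-unchanged /
#' not-detected over all members (these four sum to 1), plus the same
#' up/down/unchanged fractions over detected members only, so either
#' denominator convention can be reproduced. Also reports the overall
#' fraction of the combined consensus panel deregulated in either direction.
#'
#' @param protein_de A `de_table` (direction filled) of the proteome.
#' @param panel A [marker_panel()].
#' @param sets Which panel sets to report (default the consensus and
#'   SASP/ECM sets).
#' @return An `overlap_report` tibble with one row per set: `set`, `n_genes`,
#'   `n_detected`, `frac_up`, `frac_down`, `frac_unchanged`, `frac_missing`,
#'   `det_frac_up`, `det_frac_down`, `det_frac_unchanged`. Attribute
#'   `frac_panel_deregulated` gives the combined consensus-panel fraction
#'   (over detected members).
#' @export
proteome_marker_overlap <- function(protein_de, panel,
                                    sets = c("consensus_up", "consensus_down",
                                             "sasp", "ecm")) {
  stopifnot(all(c("gene", "direction") %in% names(protein_de)))
  dir_map <- setNames(protein_de$direction, protein_de$gene)
  one_set <- function(genes, nm) {
    n <- length(genes)
    if (n == 0L)
      return(tibble(set = nm, n_genes = 0L, n_detected = 0L, frac_up = NA_real_,
                    frac_down = NA_real_, frac_unchanged = NA_real_,
                    frac_missing = NA_real_, det_frac_up = NA_real_,
                    det_frac_down = NA_real_, det_frac_unchanged = NA_real_))
    d <- dir_map[genes]
    detected <- !is.na(d)
    nd <- sum(detected)
    tibble(set = nm, n_genes = n, n_detected = nd,
           frac_up = sum(d == "up", na.rm = TRUE) / n,
           frac_down = sum(d == "down", na.rm = TRUE) / n,
           frac_unchanged = sum(d == "none", na.rm = TRUE) / n,
           frac_missing = sum(!detected) / n,
           det_frac_up = if (nd) sum(d == "up", na.rm = TRUE) / nd else NA_real_,
           det_frac_down = if (nd) sum(d == "down", na.rm = TRUE) / nd else NA_real_,
           det_frac_unchanged = if (nd) sum(d == "none", na.rm = TRUE) / nd else NA_real_)
  }
  out <- purrr::map_dfr(sets, function(nm) one_set(panel[[nm]], nm))
  all_markers <- c(panel$consensus_up, panel$consensus_down)
  d_all <- dir_map[all_markers]
  det <- d_all[!is.na(d_all)]
  structure(out, class = c("overlap_report", class(out)),
            frac_panel_deregulated =
              if (length(det)) mean(det != "none") else NA_real_)
}

#' Density plot of per-gene correlation distributions by set
#'
#' @param rho_tables Named list of tibbles from [spearman_per_gene()] (or any
#'   tibble with a `rho` column), one per gene set.
#' @return A ggplot with one density per set, medians in the legend.
#' @export
plot_rho_distributions <- function(rho_tables) {
  stopifnot(is.list(rho_tables), !is.null(names(rho_tables)))
  d <- purrr::imap_dfr(rho_tables, function(tb, nm)
    tibble(set = sprintf("%s (%.2f)", nm, median(tb$rho)), rho = tb$rho))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Spearman rho (mRNA vs protein)", y = "density",
                  colour = "set (median)") +
    ggplot2::theme_minimal()
}
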