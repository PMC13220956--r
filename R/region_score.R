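#' Regional senescence-marker score
#'
#' Scores anatomic regions for enrichment of a marker set: each gene's
#' expression is min-max scaled to 0-1 across regions, contributions of
#' downregulated markers are multiplied by -1, and per-region contributions
#' are summed. The region with the highest sum expresses the panel the most.
#' Genes constant across regions contribute 0 (their scaling is undefined).
#'
#' @param fpkm Region-by-gene expression matrix (regions in rows, e.g. mean
#'   FPKM per anatomic structure), or a data frame with a leading region
#'   column. If multiple samples per region exist, aggregate first with
#'   [aggregate_regions()].
#' @param up_set,down_set Character vectors of up- and down-marker genes;
#'   they must be disjoint. Genes absent from the matrix are dropped with a
#'   warning.
#' @return A `region_scores` tibble `region`, `score`, `n_genes_scored`,
#'   ranked by score; attributes `contributions` (region x gene matrix of
#'   per-gene contributions) and `top_region`.
#' @export
score_regions <- function(fpkm, up_set, down_set = character()) {
  m <- as_region_matrix(fpkm)
  if (nrow(m) < 2L) stop_input("need at least 2 regions (scaling is undefined for 1)")
  up_set <- unique(as.character(up_set)); down_set <- unique(as.character(down_set))
  if (length(intersect(up_set, down_set)) > 0L)
    stop_input("up_set and down_set must be disjoint")
  genes <- c(up_set, down_set)
  present <- intersect(genes, colnames(m))
  if (length(present) == 0L) stop_input("no panel gene present in the matrix")
  if (length(present) < length(genes))
    rlang::warn(sprintf("%d panel genes absent from the matrix; dropped",
                        length(genes) - length(present)))

  sub <- m[, present, drop = FALSE]
  rng <- apply(sub, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  scaled <- sweep(sub, 2L, rng[1L, ], "-")
  ok <- span > 0
  scaled[, ok] <- sweep(scaled[, ok, drop = FALSE], 2L, span[ok], "/")
  scaled[, !ok] <- 0
  sign_vec <- ifelse(present %in% down_set, -1, 1)
  contributions <- sweep(scaled, 2L, sign_vec, "*")

  out <- tibble(region = rownames(m),
                score = as.numeric(rowSums(contributions)),
                n_genes_scored = length(present)) |>
    arrange(desc(.data$score))
  structure(out, class = c("region_scores", class(out)),
            contributions = contributions,
            top_region = out$region[[1L]])
}

as_region_matrix <- function(x) {
  m <- if (is.data.frame(x)) {
    first <- x[[1L]]
    if (is.character(first) || is.factor(first)) {
      mm <- as.matrix(x[-1L]); rownames(mm) <- as.character(first); mm
    } else as.matrix(x)
  } else x
  if (!is.matrix(m)) stop_input("`fpkm` must be a region-by-gene matrix or data frame")
  if (is.null(rownames(m))) rownames(m) <- paste0("region", seq_len(nrow(m)))
  m
}

#' Aggregate per-sample expression to per-region means
#'
#' @param x Sample-by-gene matrix or data frame with a leading sample column.
#' @param regions Per-sample region labels.
#' @param fun `"mean"` (default) or `"median"`.
#' @return A region-by-gene matrix.
#' @export
aggregate_regions <- function(x, regions, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  m <- as_region_matrix(x)
  if (length(regions) != nrow(m))
    stop_input("`regions` must label every sample row")
  split_idx <- split(seq_len(nrow(m)), as.character(regions))
  agg <- t(vapply(split_idx, function(i) {
    if (fun == "mean") colMeans(m[i, , drop = FALSE])
    else apply(m[i, , drop = FALSE], 2L, median)
  }, numeric(ncol(m))))
  colnames(agg) <- colnames(m)
  agg
}

#' Score several marker panels against the same region matrix
#'
#' @inheritParams score_regions
#' @param panels Named list; each element a list with `up` and (optionally)
#'   `down` character vectors (SASP and ECM panels have empty `down`).
#' @return Named list of `region_scores` tibbles.
#' @export
score_panels <- function(fpkm, panels) {
  stopifnot(is.list(panels), !is.null(names(panels)))
  purrr::map(panels, function(p)
    score_regions(fpkm, up_set = p$up, down_set = p$down %||% character()))
}

#' @export
glance.region_scores <- function(x, ...) {
  tibble(n_regions = nrow(x), top_region = attr(x, "top_region"),
         top_score = max(x$score), n_genes_scored = x$n_genes_scored[[1L]])
}

#' Bar plot of region scores
#'
#' @param object A `region_scores` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$region, .data$score),
                                       y = .data$score)) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "senescence score") +
    ggplot2::theme_minimal()
}
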