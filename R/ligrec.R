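#' Ligand-receptor pair list
#'
#' @param ligand Character vector of ligand genes.
#' @param receptor Character vector (same length) of receptor genes; receptor
#'   complexes are given as comma-separated gene lists (the complex score is
#'   the minimum over components).
#' @return A tibble `ligand`, `receptor` with class `lr_pairs`.
#' @export
lr_pairs <- function(ligand, receptor) {
  stopifnot(length(ligand) == length(receptor))
  comp <- strsplit(receptor, ",", fixed = TRUE)
  bad <- purrr::map2_lgl(ligand, comp, ~ .x %in% trimws(.y))
  if (any(bad))
    stop_input("ligand and receptor components must differ within a pair (%s)",
               paste(ligand[bad], collapse = ", "))
  structure(tibble(ligand = as.character(ligand),
                   receptor = as.character(receptor)),
            class = c("lr_pairs", class(tibble())))
}

#' @describeIn lr_pairs Read a two-column TSV (ligand, receptor; complexes
#'   comma-separated).
#' @param path File path.
#' @export
read_lr_pairs <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  lr_pairs(d[[1L]], d[[2L]])
}

# Cluster-mean expression for the genes needed, dropping clusters below the
# minimum size.
cluster_means <- function(m, labels, genes, min_cells = 3L, quiet = FALSE) {
  labels <- as.character(labels)
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_cells]
  if (length(keep) < length(sizes) && !quiet)
    rlang::warn(sprintf("excluding %d cluster(s) with < %d cells",
                        length(sizes) - length(keep), min_cells))
  if (length(keep) < 2L) stop_input("need at least 2 clusters with >= %d cells", min_cells)
  idx <- labels %in% keep
  sub <- m[idx, genes, drop = FALSE]
  lab <- factor(labels[idx], levels = keep)
  cm <- rowsum(as.matrix(sub), lab) / as.vector(table(lab))
  cm
}

# Min-max scale cluster-mean expression per gene over clusters (few rows,
# so pmin/pmax accumulation over rows beats apply over columns).
scale_cluster_means <- function(cm) {
  cmin <- cm[1L, ]; cmax <- cm[1L, ]
  for (i in seq_len(nrow(cm))[-1L]) {
    cmin <- pmin(cmin, cm[i, ]); cmax <- pmax(cmax, cm[i, ])
  }
  span <- cmax - cmin
  span[span == 0] <- 1   # constant genes scale to 0 everywhere
  sweep(sweep(cm, 2L, cmin, "-"), 2L, span, "/")
}

# Scores for all pairs over the full sender x receiver grid, as a bare
# numeric vector in pair-major, sender-fastest order (the permutation loop's
# hot path).
lr_score_vector <- function(cm, scaled, pairs_parsed, grid_s, grid_r) {
  ncomb <- length(grid_s)
  out <- numeric(length(pairs_parsed) * ncomb)
  for (j in seq_along(pairs_parsed)) {
    p <- pairs_parsed[[j]]
    lig_scaled <- scaled[, p$ligand]
    lig_raw <- cm[, p$ligand]
    if (length(p$receptor) == 1L) {
      rec_scaled <- scaled[, p$receptor]
      rec_raw <- cm[, p$receptor]
    } else {
      rec_scaled <- do.call(pmin, asplit(scaled[, p$receptor, drop = FALSE], 2L))
      rec_raw <- do.call(pmin, asplit(cm[, p$receptor, drop = FALSE], 2L))
    }
    score <- (lig_scaled[grid_s] + rec_scaled[grid_r]) / 2
    score[lig_raw[grid_s] == 0 | rec_raw[grid_r] == 0] <- 0
    out[(j - 1L) * ncomb + seq_len(ncomb)] <- score
  }
  out
}

lr_scores_from_means <- function(cm, scaled, pairs_parsed) {
  clusters <- rownames(cm)
  grid <- expand.grid(sender = seq_along(clusters),
                      receiver = seq_along(clusters))
  score <- lr_score_vector(cm, scaled, pairs_parsed, grid$sender, grid$receiver)
  tibble(
    ligand = rep(purrr::map_chr(pairs_parsed, "label_l"), each = nrow(grid)),
    receptor = rep(purrr::map_chr(pairs_parsed, "label_r"), each = nrow(grid)),
    sender = rep(clusters[grid$sender], times = length(pairs_parsed)),
    receiver = rep(clusters[grid$receiver], times = length(pairs_parsed)),
    score = score
  )
}

parse_pairs <- function(pairs, genes_in_matrix) {
  parsed <- purrr::pmap(list(pairs$ligand, pairs$receptor),
                        function(l, r) {
    comps <- trimws(strsplit(r, ",", fixed = TRUE)[[1L]])
    list(ligand = l, receptor = comps, label_l = l, label_r = r)
  })
  ok <- purrr::map_lgl(parsed, function(p)
    p$ligand %in% genes_in_matrix && all(p$receptor %in% genes_in_matrix))
  if (!all(ok))
    rlang::warn(sprintf("skipping %d pair(s) with genes absent from the matrix",
                        sum(!ok)))
  parsed[ok]
}

#' Ligand-receptor interaction scores between clusters
#'
#' For each ligand-receptor pair and ordered (sender, receiver) cluster pair,
#' the score is the mean of the ligand's and the receptor's min-max scaled
#' cluster-mean expression (scaled per gene over clusters); receptor
#' complexes use the minimum over component genes, and the score is 0
#' whenever either side's raw cluster mean is 0.
#'
#' @param x Cell-by-gene expression matrix (columns named by gene).
#' @param labels Per-cell cluster labels; clusters with fewer than
#'   `min_cells` cells are excluded with a warning.
#' @param pairs An [lr_pairs()] tibble.
#' @param min_cells Minimum cluster size (default 3).
#' @return A `lr_result` tibble `ligand`, `receptor`, `sender`, `receiver`,
#'   `score` (and after [lr_permutation_test()]: `p`, `significant`).
#' @export
interaction_scores <- function(x, labels, pairs, min_cells = 3L) {
  m <- as_cell_matrix(x)
  parsed <- parse_pairs(pairs, colnames(m))
  if (length(parsed) == 0L) stop_input("no ligand-receptor pair has all genes in the matrix")
  genes <- unique(unlist(purrr::map(parsed, ~ c(.x$ligand, .x$receptor))))
  cm <- cluster_means(m, labels, genes, min_cells)
  res <- lr_scores_from_means(cm, scale_cluster_means(cm), parsed)
  structure(res, class = c("lr_result", class(res)))
}

#' Permutation test for ligand-receptor interactions
#'
#' Builds the null by globally shuffling the cell-to-cluster assignment
#' (preserving cluster sizes) `n_perm` times and recomputing all interaction
#' scores; `p = (r + 1) / (n_perm + 1)` where `r` counts permuted scores at
#' or above the observed one, so p is never exactly 0.
#'
#' @inheritParams interaction_scores
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance level for the `significant` flag (default 0.05,
#'   `p < alpha`).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @return A `lr_result` tibble with `p` and `significant` filled.
#' @export
lr_permutation_test <- function(x, labels, pairs, n_perm = 1000L,
                                alpha = 0.05, seed = 1L, min_cells = 3L) {
  check_count(n_perm, "n_perm", 1L)
  check_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  m <- as_cell_matrix(x)
  parsed <- parse_pairs(pairs, colnames(m))
  if (length(parsed) == 0L) stop_input("no ligand-receptor pair has all genes in the matrix")
  genes <- unique(unlist(purrr::map(parsed, ~ c(.x$ligand, .x$receptor))))

  labels <- as.character(labels)
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_cells]
  if (length(keep) < 2L) stop_input("need at least 2 clusters with >= %d cells", min_cells)
  if (length(keep) < length(sizes))
    rlang::warn(sprintf("excluding %d cluster(s) with < %d cells",
                        length(sizes) - length(keep), min_cells))
  idx <- which(labels %in% keep)
  sub <- as.matrix(m[idx, genes, drop = FALSE])
  lab <- labels[idx]

  obs_cm <- cluster_means(sub, lab, genes, min_cells, quiet = TRUE)
  obs <- lr_scores_from_means(obs_cm, scale_cluster_means(obs_cm), parsed)

  nclust <- nrow(obs_cm)
  grid <- expand.grid(sender = seq_len(nclust), receiver = seq_len(nclust))
  lab_f <- factor(lab, levels = rownames(obs_cm))
  counts_per <- as.vector(table(lab_f))
  exceed <- numeric(nrow(obs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm_lab <- lab_f[sample.int(length(lab_f))]
      cm <- rowsum(sub, perm_lab) / counts_per
      perm_scores <- lr_score_vector(cm, scale_cluster_means(cm), parsed,
                                     grid$sender, grid$receiver)
      exceed <- exceed + (perm_scores >= obs$score)
    }
  })
  obs$p <- (exceed + 1) / (n_perm + 1)
  obs$significant <- obs$p < alpha
  structure(obs, class = c("lr_result", class(tibble())),
            n_perm = n_perm, alpha = alpha, seed = seed)
}

#' Count significant interactions per cluster pair
#'
#' @param results A `lr_result` tibble with `p` filled.
#' @param alpha Significance level (default 0.05, `p < alpha`).
#' @return An integer sender-by-receiver matrix; asymmetric by construction.
#' @export
count_significant <- function(results, alpha = 0.05) {
  stopifnot("p" %in% names(results))
  clusters <- sort(unique(c(results$sender, results$receiver)))
  mat <- matrix(0L, length(clusters), length(clusters),
                dimnames = list(sender = clusters, receiver = clusters))
  sig <- filter(results, .data$p < alpha)
  if (nrow(sig) > 0L) {
    tab <- sig |> count(.data$sender, .data$receiver)
    mat[cbind(tab$sender, tab$receiver)] <- tab$n
  }
  mat
}

#' @export
glance.lr_result <- function(x, ...) {
  tibble(n_pairs = length(unique(paste(x$ligand, x$receptor))),
         n_cluster_pairs = nrow(x),
         n_significant = if ("significant" %in% names(x))
           sum(x$significant) else NA_integer_,
         n_perm = attr(x, "n_perm") %||% NA_integer_)
}

#' Dot plot of ligand-receptor interaction scores
#'
#' @param object A `lr_result` tibble (with `p` if available).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lr_result <- function(object, ...) {
  d <- mutate(object,
              pair = paste(.data$ligand, .data$receptor, sep = " → "),
              route = paste(.data$sender, .data$receiver, sep = " → "))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$route, y = .data$pair,
                                       size = .data$score))
  if ("p" %in% names(d))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = -log10(.data$p)))
  else p <- p + ggplot2::geom_point(colour = "#34495e")
  p + ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "sender → receiver", y = NULL,
                  size = "scaled mean", colour = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
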