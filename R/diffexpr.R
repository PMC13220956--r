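#' Thresholds for differential-expression calls
#'
#' @param alpha Adjusted-p significance cut-off (default 0.05).
#' @param lfc_cut Absolute log2 fold-change cut-off for DEG calls (default
#'   0.5); both inequalities are strict.
#' @param lfc_cut_spia Absolute log2 fold-change cut-off applied when
#'   exporting genes for signalling-pathway impact analysis (default 1).
#' @return A list of class `deg_thresholds`.
#' @export
deg_thresholds <- function(alpha = 0.05, lfc_cut = 0.5, lfc_cut_spia = 1) {
  check_number(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(lfc_cut, "lfc_cut", 0)
  check_number(lfc_cut_spia, "lfc_cut_spia", 0)
  structure(list(alpha = alpha, lfc_cut = lfc_cut, lfc_cut_spia = lfc_cut_spia),
            class = "deg_thresholds")
}

#' Moderated two-group differential expression
#'
#' Fits a per-gene two-group comparison on log2 expression values and
#' moderates the per-gene variances with the standard empirical-Bayes scheme:
#' the prior degrees of freedom `d0` and prior variance `s0^2` are estimated
#' by method of moments on the log sample variances, each gene's residual
#' variance is shrunk to `(d0*s0^2 + df*s2) / (d0 + df)`, and the moderated t
#' is referenced to a t distribution on `df + d0` degrees of freedom.
#' `log2fc` is `mean(group2) - mean(group1)` where `group2` is the second
#' factor level (put the senescent / treated group second).
#'
#' @param x Gene-by-sample numeric matrix of log2 values (rows named by gene),
#'   or a data frame whose first column holds gene identifiers. Proteome
#'   log2-intensity tables (proteins as rows) are handled identically.
#' @param groups Two-level factor (or character vector) of sample labels,
#'   length `ncol(x)`.
#' @param prior_df Optional override of the prior degrees of freedom: `NULL`
#'   (default) estimates it from the data, `0` disables moderation (ordinary
#'   pooled-variance t), `Inf` shares a single variance across all genes.
#' @return A `de_table` tibble with columns `gene`, `log2fc`, `t_ordinary`,
#'   `t_moderated`, `df_total`, `p`, `p_adj`, `direction` (all `"none"` until
#'   [call_degs()] is applied) and `zero_variance` flags. Attributes
#'   `prior_df` and `prior_var` record the fitted prior.
#' @seealso [call_degs()], [adjust_bh()]
#' @export
fit_moderated <- function(x, groups, prior_df = NULL) {
  m <- as_expression_matrix(x, "x")
  if (is.null(rownames(m))) rownames(m) <- paste0("gene", seq_len(nrow(m)))
  groups <- as.factor(groups)
  if (length(groups) != ncol(m))
    stop_input("`groups` must have one label per sample column (%d != %d)",
               length(groups), ncol(m))
  if (nlevels(droplevels(groups)) != 2L)
    stop_input("`groups` must have exactly two levels")
  groups <- droplevels(groups)
  i1 <- which(groups == levels(groups)[1L])
  i2 <- which(groups == levels(groups)[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop_input("each group needs at least 2 samples (got %d and %d)", n1, n2)

  m1 <- rowMeans(m[, i1, drop = FALSE])
  m2 <- rowMeans(m[, i2, drop = FALSE])
  log2fc <- m2 - m1
  ss1 <- rowSums((m[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / df
  su <- sqrt(1 / n1 + 1 / n2)
  zero_var <- s2 <= 0

  t_ord <- log2fc / (sqrt(s2) * su)
  t_ord[zero_var & log2fc == 0] <- 0

  if (all(zero_var)) {
    rlang::warn("all genes have zero residual variance; p values set to 1 where log2fc is 0")
    d0 <- Inf; s0 <- 0
    s2_post <- s2
    df_total <- rep(df, length(s2))
  } else if (!is.null(prior_df) && prior_df == 0) {
    d0 <- 0; s0 <- NA_real_
    s2_post <- s2
    df_total <- rep(df, length(s2))
  } else {
    eb <- estimate_variance_prior(s2[!zero_var], df)
    if (!is.null(prior_df)) {
      d0 <- prior_df
      s0 <- eb$prior_var
    } else {
      d0 <- eb$prior_df
      s0 <- eb$prior_var
    }
    if (is.infinite(d0)) {
      s2_post <- rep(s0, length(s2))
      df_total <- rep(Inf, length(s2))
    } else {
      s2_post <- (d0 * s0 + df * s2) / (d0 + df)
      df_total <- rep(df + d0, length(s2))
    }
  }

  t_mod <- log2fc / (sqrt(s2_post) * su)
  t_mod[s2_post <= 0 & log2fc == 0] <- 0
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p[!is.finite(t_mod)] <- 0
  p[s2_post <= 0 & log2fc == 0] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  out <- tibble(
    gene = rownames(m),
    log2fc = unname(log2fc),
    t_ordinary = unname(t_ord),
    t_moderated = unname(t_mod),
    df_total = unname(df_total),
    p = unname(p),
    p_adj = adjust_bh(unname(p)),
    direction = "none",
    zero_variance = unname(zero_var)
  )
  structure(out, class = c("de_table", class(out)),
            prior_df = d0, prior_var = unname(s0), residual_df = df)
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior from
# the marginal distribution of log sample variances (s2 ~ s0^2 F(df, d0)).
estimate_variance_prior <- function(s2, df) {
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  n <- length(e)
  if (n < 2L) return(list(prior_df = Inf, prior_var = exp(mean(e))))
  evar <- mean((e - mean(e))^2) * n / (n - 1L) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond the chi-square: infinite prior df, common
    # variance estimated by the arithmetic mean of the sample variances
    d0 <- Inf
    s0 <- mean(s2)
  }
  list(prior_df = d0, prior_var = s0)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#' Input p values must lie in (0, 1].
#'
#' @param p Numeric vector of raw p values.
#' @return Adjusted p values in (0, 1], same order as the input.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_input("p values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Assigns `direction` by the strict-inequality rule: `up` when
#' `p_adj < alpha` and `log2fc > lfc_cut`; `down` when `p_adj < alpha` and
#' `log2fc < -lfc_cut`; otherwise `none`.
#'
#' @param table A `de_table` from [fit_moderated()] (any data frame with
#'   `gene`, `log2fc`, `p_adj` columns works).
#' @param thresholds A [deg_thresholds()] object.
#' @return The table with `direction` filled, keeping the `de_table` class;
#'   attribute `deg_counts` holds the up/down totals.
#' @export
call_degs <- function(table, thresholds = deg_thresholds()) {
  stopifnot(all(c("gene", "log2fc", "p_adj") %in% names(table)))
  out <- dplyr::mutate(table, direction = dplyr::case_when(
    .data$p_adj < thresholds$alpha & .data$log2fc > thresholds$lfc_cut ~ "up",
    .data$p_adj < thresholds$alpha & .data$log2fc < -thresholds$lfc_cut ~ "down",
    TRUE ~ "none"
  ))
  if (!inherits(out, "de_table")) class(out) <- c("de_table", class(out))
  attr(out, "deg_counts") <- c(up = sum(out$direction == "up"),
                               down = sum(out$direction == "down"))
  out
}

#' @export
glance.de_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    prior_df = attr(x, "prior_df") %||% NA_real_,
    prior_var = attr(x, "prior_var") %||% NA_real_,
    residual_df = attr(x, "residual_df") %||% NA_real_
  )
}

#' Volcano plot of a differential-expression table
#'
#' @param object A `de_table`.
#' @param thresholds Thresholds drawn as guide lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_table <- function(object, thresholds = deg_thresholds(), ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_adj),
                                       colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * thresholds$lfc_cut, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(thresholds$alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            none = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a differential-expression table as TSV
#'
#' Fixed column order: gene, log2fc, t, p, p_adj, direction.
#'
#' @param table A `de_table`.
#' @param path Output path.
#' @export
write_de_tsv <- function(table, path) {
  out <- dplyr::select(as_tibble(table), "gene", "log2fc",
                       t = "t_moderated", "p", "p_adj", "direction")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
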