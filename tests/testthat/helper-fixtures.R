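# Small shared fixture builders for the test suite; everything is generated
# in code, nothing is read from disk.

# A de_table-shaped tibble built directly from vectors (bypassing the fit),
# for testing the threshold/consensus logic in isolation.
fake_de_table <- function(genes, log2fc, p_adj = rep(0.01, length(genes)),
                          direction = NULL) {
  tb <- tibble::tibble(gene = genes, log2fc = log2fc, p = p_adj, p_adj = p_adj,
                       direction = direction %||% "none")
  class(tb) <- c("de_table", class(tb))
  tb
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# A toy cell-by-gene matrix whose panel structure is fully hand-controlled.
toy_panel <- function() {
  marker_panel(
    consensus_up = c("UP1", "UP2"), consensus_down = c("DN1", "DN2"),
    common_up = c("UP1", "UP2"), common_down = c("DN1", "DN2"),
    sasp = c("SA1", "SA2"), ecm = c("EC1", "EC2"),
    cdki = c("CDKN1A", "CDKN2A"), mcm = c("MCM2", "MCM3")
  )
}

toy_cell_matrix <- function(n_cells = 20L, seed = 11L) {
  genes <- c("UP1", "UP2", "DN1", "DN2", "SA1", "SA2", "EC1", "EC2",
             "CDKN1A", "CDKN2A", "MCM2", "MCM3", "MKI67", "PCNA", "BG1")
  withr::with_seed(seed, {
    m <- matrix(rpois(n_cells * length(genes), 4), nrow = n_cells,
                dimnames = list(sprintf("cell%02d", seq_len(n_cells)), genes))
  })
  m
}

# Independent brute-force re-implementation of the four-criterion caller,
# cell by cell, used as the oracle against score_cells().
brute_force_caller <- function(m, panel, thr) {
  up <- intersect(panel[[thr$up_panel]], colnames(m))
  down <- intersect(panel$common_down, colnames(m))
  sasp <- intersect(panel$sasp, colnames(m))
  ecm <- intersect(panel$ecm, colnames(m))
  cdki <- intersect(panel$cdki, colnames(m))
  sasp_tot <- apply(m[, sasp, drop = FALSE], 1, sum)
  ecm_tot <- apply(m[, ecm, drop = FALSE], 1, sum)
  k <- max(1L, ceiling(thr$top_quantile * nrow(m)))
  sasp_cut <- sort(sasp_tot, decreasing = TRUE)[k]
  ecm_cut <- sort(ecm_tot, decreasing = TRUE)[k]
  vapply(seq_len(nrow(m)), function(i) {
    sum(m[i, up]) > thr$up_sum_min &&
      sum(m[i, down]) <= thr$down_tolerance &&
      sasp_tot[i] >= sasp_cut &&
      ecm_tot[i] >= ecm_cut &&
      sum(m[i, cdki] > 0) >= thr$min_cdki_expressed
  }, logical(1L))
}
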