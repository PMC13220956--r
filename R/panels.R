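#' Marker panels: named senescence gene sets
#'
#' A `marker_panel` bundles the gene sets the pipeline consumes: the consensus
#' up/down senescence markers, the short "common" marker lists used by the
#' single-cell caller, SASP (senescence-associated secretory phenotype), ECM
#' (extracellular matrix), CDK-inhibitor, MCM-complex and proliferation sets,
#' together with a provenance record of the thresholds each set was derived
#' with.
#'
#' @param consensus_up,consensus_down Character vectors of consensus marker
#'   genes (direction-consistent across datasets).
#' @param common_up,common_down Ordered character vectors, the short common
#'   marker lists (subsets of the consensus sets).
#' @param sasp,ecm Character vectors of SASP / ECM component genes.
#' @param cdki Cyclin-dependent kinase inhibitor genes. Defaults to the INK4
#'   family (CDKN2A/B/C/D) plus the CIP/KIP family (CDKN1A/B/C).
#' @param mcm MCM replicative-helicase complex genes, default MCM2-MCM7.
#' @param proliferation Proliferation marker genes, default MKI67, PCNA and the
#'   MCM genes.
#' @param provenance Named list of threshold records describing how each set
#'   was derived.
#' @return An object of class `marker_panel` (a named list of character
#'   vectors plus a `provenance` attribute).
#' @export
marker_panel <- function(consensus_up = character(), consensus_down = character(),
                         common_up = character(), common_down = character(),
                         sasp = character(), ecm = character(),
                         cdki = cdki_genes(), mcm = mcm_genes(),
                         proliferation = c("MKI67", "PCNA", mcm_genes()),
                         provenance = list()) {
  sets <- list(
    consensus_up = unique(as.character(consensus_up)),
    consensus_down = unique(as.character(consensus_down)),
    common_up = as.character(common_up),
    common_down = as.character(common_down),
    sasp = unique(as.character(sasp)),
    ecm = unique(as.character(ecm)),
    cdki = unique(as.character(cdki)),
    mcm = unique(as.character(mcm)),
    proliferation = unique(as.character(proliferation))
  )
  if (length(intersect(sets$consensus_up, sets$consensus_down)) > 0L)
    stop_input("consensus_up and consensus_down must be disjoint")
  if (length(sets$common_up) && length(sets$consensus_up) &&
      !all(sets$common_up %in% sets$consensus_up))
    stop_input("common_up must be a subset of consensus_up")
  if (length(sets$common_down) && length(sets$consensus_down) &&
      !all(sets$common_down %in% sets$consensus_down))
    stop_input("common_down must be a subset of consensus_down")
  structure(c(sets, list(provenance = provenance)), class = "marker_panel")
}

#' @rdname marker_panel
#' @export
cdki_genes <- function() c("CDKN2A", "CDKN2B", "CDKN2C", "CDKN2D",
                           "CDKN1A", "CDKN1B", "CDKN1C")

#' @rdname marker_panel
#' @export
mcm_genes <- function() paste0("MCM", 2:7)

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>\n")
  for (nm in setdiff(names(x), "provenance"))
    cat(sprintf("  %-14s %4d genes%s\n", nm, length(x[[nm]]),
                if (length(x[[nm]])) paste0(": ", paste(head(x[[nm]], 4L), collapse = ", "),
                                            if (length(x[[nm]]) > 4L) ", ..." else "") else ""))
  invisible(x)
}

#' @export
tidy.marker_panel <- function(x, ...) {
  sets <- x[setdiff(names(x), "provenance")]
  purrr::imap_dfr(sets, function(genes, set)
    tibble(set = set, gene = as.character(genes)))
}

#' Synthetic marker panel for simulations
#'
#' Builds a fully synthetic `marker_panel` whose gene identifiers drive the
#' data generators: fixed-name genes the caller requires (CDK inhibitors,
#' MKI67, PCNA, MCM2-7) plus clearly synthetic SASP/ECM/marker identifiers.
#' The common up/down lists are subsets of the consensus lists, as in panels
#' derived from real data.
#'
#' @param n_up,n_down Number of consensus up / down markers.
#' @param n_common_up,n_common_down Sizes of the common marker lists (default
#'   8 and 7).
#' @param n_sasp,n_ecm Sizes of the SASP and ECM sets.
#' @return A `marker_panel`.
#' @export
synthetic_marker_panel <- function(n_up = 128L, n_down = 461L,
                                   n_common_up = 8L, n_common_down = 7L,
                                   n_sasp = 50L, n_ecm = 40L) {
  check_count(n_up, "n_up", 1L); check_count(n_down, "n_down", 1L)
  if (n_common_up > n_up || n_common_down > n_down)
    stop_config("common set sizes cannot exceed consensus set sizes")
  up <- sprintf("UPM%03d", seq_len(n_up))
  down <- sprintf("DNM%03d", seq_len(n_down))
  marker_panel(
    consensus_up = up, consensus_down = down,
    common_up = up[seq_len(n_common_up)],
    common_down = down[seq_len(n_common_down)],
    sasp = sprintf("SASP%03d", seq_len(n_sasp)),
    ecm = sprintf("ECM%03d", seq_len(n_ecm)),
    provenance = list(origin = "synthetic")
  )
}

#' Read and write GMT gene-set files
#'
#' `read_gmt()` parses a GMT file into a named list of gene sets;
#' `write_gmt()` writes one line per set (`name <TAB> description <TAB>
#' genes...`).
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param description Description field written to the second GMT column.
#' @return `read_gmt()` a named list of character vectors; `write_gmt()` the
#'   path, invisibly.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "senescreen") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- purrr::imap_chr(sets, function(genes, nm)
    paste(c(nm, description, as.character(genes)), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @describeIn read_gmt Write every set of a `marker_panel` as one GMT line.
#' @param panel A `marker_panel`.
#' @export
write_panel_gmt <- function(panel, path, description = "senescreen") {
  stopifnot(inherits(panel, "marker_panel"))
  write_gmt(panel[setdiff(names(panel), "provenance")], path, description)
}

#' @describeIn read_gmt Rebuild a `marker_panel` from a GMT written by
#'   `write_panel_gmt()`.
#' @export
read_panel_gmt <- function(path) {
  sets <- read_gmt(path)
  args <- sets[intersect(names(sets), c("consensus_up", "consensus_down",
                                        "common_up", "common_down", "sasp",
                                        "ecm", "cdki", "mcm", "proliferation"))]
  do.call(marker_panel, args)
}
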