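#' Default cell-marker gene sets
#'
#' The packaged cell-type marker lists used to pool normalised expression
#' into per-class regional maps: excitatory neurons (CUX2, THEMIS, RORB,
#' FEZF2), inhibitory neurons (PAX6, RELN, VIP, SV2C, TLE4, PVALB, SST),
#' astrocytes, endothelial cells, microglia and oligodendrocytes. With
#' `per_gene = TRUE`, singleton sets for each excitatory and inhibitory
#' marker gene are appended, giving the 16 cellular comparisons that,
#' together with 8 microarchitectural annotation maps, form a 24-comparison
#' FDR family per t-map.
#'
#' @param per_gene append singleton sets for individual excitatory and
#'   inhibitory marker genes.
#' @return named list of character vectors (marker sets).
#' @export
default_marker_sets <- function(per_gene = TRUE) {
  sets <- list(
    excitatory_neurons = c("CUX2", "THEMIS", "RORB", "FEZF2"),
    inhibitory_neurons = c("PAX6", "RELN", "VIP", "SV2C", "TLE4", "PVALB", "SST"),
    astrocytes = c("AQP4", "GFAP"),
    endothelial_cells = c("CLDN5", "SEMA3G", "EFNB2", "MFSD2A", "SLC16A1",
                          "C1QA", "HBB", "ACTA2", "CNN1", "VWF", "TSHZ2"),
    microglia = c("CD74", "PTPRC"),
    oligodendrocytes = c("PDGFRA", "BCAS1", "PLP1", "MBP", "RASGRF1", "ANKRD18A"))
  if (per_gene) {
    singles <- c(sets$excitatory_neurons, sets$inhibitory_neurons)
    sets <- c(sets, stats::setNames(as.list(singles), singles))
  }
  sets
}

#' Pooled cell-marker expression map
#'
#' Per-region sum of the normalised expression of the genes in a marker
#' set. Markers absent from the expression table are skipped with a
#' warning; a set with no present marker is an error.
#'
#' @param expression regions x genes numeric matrix (region ids as
#'   rownames, gene symbols as colnames).
#' @param markers character vector of gene symbols.
#' @return named numeric regional map.
#' @export
pooled_marker_map <- function(expression, markers) {
  markers <- unique(markers)
  present <- markers[markers %in% colnames(expression)]
  absent <- setdiff(markers, present)
  if (!length(present))
    stop("none of the marker genes are present in the expression table")
  if (length(absent))
    warning("marker gene(s) absent from expression table, skipped: ",
            paste(absent, collapse = ", "))
  m <- expression[, present, drop = FALSE]
  stats::setNames(rowSums(m), rownames(expression))
}

#' Contextualise a t-map against a family of annotation maps
#'
#' Runs [spin_test()] of the t-map against every annotation and adjusts the
#' spin p values by Benjamini-Hochberg FDR across the full family supplied
#' in this call (one family per t-map): q_spin is only meaningful for the
#' declared family, so shrinking the family changes q, never p.
#'
#' @param t_map named numeric regional map (e.g. the group-difference
#'   t-map); this is the map that is spun.
#' @param annotations named list of regional maps (pooled marker maps,
#'   cytoarchitectural axes, laminar thicknesses, gene-set maps, ...).
#' @param spins `spin_ensemble`.
#' @return data.frame of class `context_table` with columns `annotation`,
#'   `rho`, `p_spin`, `q_spin`.
#' @export
contextualise <- function(t_map, annotations, spins) {
  if (!length(annotations)) stop("empty annotation family")
  if (is.null(names(annotations)))
    names(annotations) <- paste0("annotation", seq_along(annotations))
  res <- lapply(annotations, function(ann) spin_test(t_map, ann, spins))
  p <- vapply(res, `[[`, numeric(1), "p_spin")
  out <- data.frame(annotation = names(annotations),
                    rho = vapply(res, `[[`, numeric(1), "rho_observed"),
                    p_spin = p, q_spin = fdr(p))
  rownames(out) <- NULL
  class(out) <- c("context_table", "data.frame")
  out
}

#' Unimodal-to-transmodal rank map from network labels
#'
#' Assigns each region the rank of its functional network in the supplied
#' unimodal-to-transmodal ordering; regions within a network are tied.
#'
#' @param network_labels named character vector: region id -> network name.
#' @param ordering character vector of network names from unimodal to
#'   transmodal.
#' @return named numeric regional map of network ranks.
#' @export
axis_rank_map <- function(network_labels, ordering) {
  if (anyNA(network_labels) || any(network_labels == ""))
    stop("every region must be tagged with a network")
  rk <- match(network_labels, ordering)
  if (anyNA(rk))
    stop("network label(s) missing from ordering: ",
         paste(unique(network_labels[is.na(rk)]), collapse = ", "))
  stats::setNames(as.numeric(rk), names(network_labels))
}
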