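#' Induce the cell-type-specific subnetwork
#'
#' Selects all interactome edges connecting two genes specific to the
#' given cell type.  The node set is the set of endpoints of those edges:
#' a specific gene not connected to another specific gene is not part of
#' the cell network.
#'
#' @param net parent [InteractionNetwork-class] (after universe
#'   restriction).
#' @param specific character vector of the cell type's specific genes
#'   (must be a subset of the interactome's genes).
#' @param cellType cell-type label.
#' @param tissue optional tissue label.
#' @return a [CellNetwork-class]; empty (with a warning) when no two
#'   specific genes are connected.
#' @examples
#' f <- tempfile(); writeLines(c("a\tb", "b\tc", "c\td"), f)
#' net <- readEdgeList(f)
#' cn <- induceCellNetwork(net, c("a", "b", "d"), "CT1")
#' genes(cn)  # "a" "b"; d is isolated among the specific genes
#' @export
induceCellNetwork <- function(net, specific, cellType,
                              tissue = NA_character_) {
  stopifnot(is(net, "InteractionNetwork"), is.character(cellType))
  extra <- setdiff(specific, genes(net))
  if (length(extra))
    stop("specific genes absent from the interactome: ",
         paste(utils::head(extra, 5), collapse = ", "),
         " (restrict to the common universe first)")
  sub <- igraph::induced_subgraph(net@graph, unique(specific))
  iso <- igraph::degree(sub) == 0
  sub <- igraph::delete_vertices(sub, igraph::V(sub)[iso])
  if (igraph::vcount(sub) == 0)
    warning(sprintf("cell network '%s' is empty", cellType))
  new("CellNetwork", graph = sub, cellType = cellType,
      tissue = as.character(tissue))
}

#' One-sided hypergeometric tail (Fisher's exact test, greater)
#'
#' The p-value of the one-sided Fisher's exact test for enrichment of a
#' 2x2 table equals the upper hypergeometric tail
#' \eqn{P(X \ge k)} with \eqn{X \sim Hypergeom(N, K, n)}.  Vectorized
#' over all arguments.
#'
#' @param k observed overlap count(s).
#' @param K size of the first category (e.g. disease genes in universe).
#' @param n size of the second category (e.g. network genes in universe).
#' @param N universe size.
#' @return numeric vector of p-values.
#' @export
hypergeomTailP <- function(k, K, n, N) {
  stopifnot(all(K <= N), all(n <= N), all(k >= 0))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Disease-gene enrichment of cell-type-specific networks
#'
#' For every (cell network, disease) pair, tests whether the number of
#' disease-associated genes inside the network is higher than random
#' expectation, by a one-sided Fisher's exact test over the restricted
#' gene universe, with Benjamini-Hochberg adjustment applied jointly
#' across all pairs.
#'
#' @param cellnets list of [CellNetwork-class] objects.
#' @param diseaseSets [DiseaseGeneSets-class] (restricted to the
#'   universe).
#' @param universe character vector: the restricted gene universe
#'   (interactome genes with expression data).
#' @return data.frame with columns `cell_type`, `tissue`, `disease`,
#'   `n_network_genes`, `n_disease_genes`, `n_overlap`, `odds_ratio`,
#'   `p_value`, `p_adjusted`, `flag` (`"empty_disease_set"` rows get
#'   p = 1).
#' @export
diseaseGeneEnrichment <- function(cellnets, diseaseSets, universe) {
  stopifnot(is.list(cellnets), is(diseaseSets, "DiseaseGeneSets"))
  N <- length(universe)
  allNodes <- unique(unlist(lapply(cellnets, genes), use.names = FALSE))
  if (!all(allNodes %in% universe))
    stop("universe must contain all cell-network genes")
  rows <- list()
  for (cn in cellnets) {
    netGenes <- genes(cn)
    for (d in names(diseaseSets@sets)) {
      dg <- intersect(diseaseSets@sets[[d]], universe)
      k <- length(intersect(netGenes, dg))
      flag <- ""
      if (length(dg) == 0) {
        p <- 1; or <- NA_real_; flag <- "empty_disease_set"
      } else {
        p <- hypergeomTailP(k, length(dg), length(netGenes), N)
        a <- k
        b <- length(dg) - k
        cc <- length(netGenes) - k
        dd <- N - length(dg) - length(netGenes) + k
        or <- if (b * cc == 0) Inf else (a * dd) / (b * cc)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = cn@cellType, tissue = cn@tissue, disease = d,
        n_network_genes = length(netGenes), n_disease_genes = length(dg),
        n_overlap = k, odds_ratio = or, p_value = p, flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("cell_type", "tissue", "disease", "n_network_genes",
          "n_disease_genes", "n_overlap", "odds_ratio", "p_value",
          "p_adjusted", "flag")]
}
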