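#' @describeIn InteractionNetwork gene symbols (node names).
#' @param x,object an `InteractionNetwork`.
#' @export
setMethod("genes", "InteractionNetwork", function(x, ...) {
  if (igraph::vcount(x@graph) == 0) character() else igraph::V(x@graph)$name
})

#' @describeIn InteractionNetwork number of nodes.
#' @export
setMethod("nodeCount", "InteractionNetwork",
          function(x) igraph::vcount(x@graph))

#' @describeIn InteractionNetwork number of edges.
#' @export
setMethod("edgeCount", "InteractionNetwork",
          function(x) igraph::ecount(x@graph))

#' @describeIn InteractionNetwork edge table (`from`, `to`, `sources`).
#' @export
setMethod("edgeTable", "InteractionNetwork", function(x) {
  if (igraph::ecount(x@graph) == 0) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(x@graph)
  df <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  if ("sources" %in% igraph::edge_attr_names(x@graph))
    df$sources <- igraph::E(x@graph)$sources
  df
})

#' @describeIn InteractionNetwork the wrapped igraph object.
#' @export
setMethod("asIgraph", "InteractionNetwork", function(x) x@graph)

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("%s with %d genes and %d interactions\n",
              class(object), nodeCount(object), edgeCount(object)))
})

setMethod("show", "CellNetwork", function(object) {
  cat(sprintf(
    "CellNetwork '%s'%s: %d genes, %d interactions\n",
    object@cellType,
    if (is.na(object@tissue)) "" else sprintf(" (%s)", object@tissue),
    nodeCount(object), edgeCount(object)))
})

#' Cell-type label of a cell network
#' @param x a [CellNetwork-class].
#' @return character scalar.
#' @export
cellType <- function(x) {
  stopifnot(is(x, "CellNetwork"))
  x@cellType
}

#' @describeIn DiseaseGeneSets the disease -> gene-set list.
#' @param x,object a `DiseaseGeneSets`.
#' @export
setMethod("geneSets", "DiseaseGeneSets", function(x) x@sets)

#' @describeIn DiseaseGeneSets union of all associated genes.
#' @export
setMethod("genes", "DiseaseGeneSets",
          function(x, ...) sort(unique(unlist(x@sets, use.names = FALSE))))

setMethod("show", "DiseaseGeneSets", function(object) {
  cat(sprintf("DiseaseGeneSets: %d diseases\n", length(object@sets)))
  for (d in names(object@sets))
    cat(sprintf("  %s: %d genes [%s]\n", d, length(object@sets[[d]]),
                object@evidence[[d]]))
})

#' Disease labels of a DiseaseGeneSets object
#' @param x a [DiseaseGeneSets-class].
#' @return character vector.
#' @export
diseases <- function(x) {
  stopifnot(is(x, "DiseaseGeneSets"))
  names(x@sets)
}

#' Evidence flags of a DiseaseGeneSets object
#'
#' `"gwas-only"` for a disease iff every contributing association record
#' was GWAS-derived, otherwise `"all"`.
#'
#' @param x a [DiseaseGeneSets-class].
#' @return named character vector.
#' @export
evidenceFlags <- function(x) {
  stopifnot(is(x, "DiseaseGeneSets"))
  x@evidence
}

#' @describeIn PathwayCatalog the pathway -> gene-set list.
#' @param x,object a `PathwayCatalog`.
#' @export
setMethod("geneSets", "PathwayCatalog", function(x) x@sets)

#' @describeIn PathwayCatalog union of all pathway genes.
#' @export
setMethod("genes", "PathwayCatalog",
          function(x, ...) sort(unique(unlist(x@sets, use.names = FALSE))))

#' @describeIn PathwayCatalog hierarchy depths (NA without hierarchy).
#' @export
setMethod("depths", "PathwayCatalog", function(x) x@depth)

setMethod("show", "PathwayCatalog", function(object) {
  cat(sprintf("%s: %d pathways, %d genes%s\n", class(object),
              length(object@sets), length(genes(object)),
              if (all(is.na(object@depth))) "" else
                sprintf(", depths %s",
                        paste(sort(unique(stats::na.omit(object@depth))),
                              collapse = "/"))))
})

#' Pathway identifiers of a catalog
#' @param x a [PathwayCatalog-class].
#' @return character vector.
#' @export
pathwayIds <- function(x) {
  stopifnot(is(x, "PathwayCatalog"))
  names(x@sets)
}

setMethod("show", "FilteredCatalog", function(object) {
  callNextMethod()
  cat(sprintf("  redundancy-filtered at overlap > %.2f; %d removed; mean residual overlap %.4f\n",
              object@threshold, nrow(object@removalLog),
              object@meanResidualOverlap))
})

#' Removal log of a redundancy-filtered catalog
#' @param x a [FilteredCatalog-class].
#' @return data.frame with columns `removed`, `kept`, `overlap`.
#' @export
removalLog <- function(x) {
  stopifnot(is(x, "FilteredCatalog"))
  x@removalLog
}

setMethod("show", "SpecificityCalls", function(object) {
  cat(sprintf("SpecificityCalls (|e| >= %.2f x IQR): %d cell types\n",
              object@k, length(object@calls)))
  n <- lengths(object@calls)
  cat(sprintf("  specific genes per cell type: %s\n",
              paste(sprintf("%s=%d", names(n), n), collapse = ", ")))
})

#' Specific-gene calls per cell type
#' @param x a [SpecificityCalls-class].
#' @return named list of character vectors.
#' @export
specificGenes <- function(x) {
  stopifnot(is(x, "SpecificityCalls"))
  x@calls
}

#' @describeIn GeneScoreVector raw propagation scores.
#' @param x,object a `GeneScoreVector`.
#' @export
setMethod("scores", "GeneScoreVector", function(x) x@score)

#' @describeIn GeneScoreVector z-standardized scores.
#' @export
setMethod("zscores", "GeneScoreVector", function(x) x@z)

setMethod("show", "GeneScoreVector", function(object) {
  cat(sprintf("GeneScoreVector cell='%s' disease='%s': %d genes%s\n",
              object@cellType, object@disease, length(object@score),
              if (length(object@z)) " (z filled)" else ""))
})

#' @describeIn TopScoringSet member genes of S.
#' @param x,object a `TopScoringSet`.
#' @export
setMethod("topGenes", "TopScoringSet", function(x) x@genes)

setMethod("show", "TopScoringSet", function(object) {
  cat(sprintf("TopScoringSet cell='%s' disease='%s': |S| = %d of %d (%s)\n",
              object@cellType, object@disease, length(object@genes),
              object@networkSize, object@rule))
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario (seed %d): %d genes, %d edges, %d cell types, %d diseases, %d pathways\n",
              object@seed, nodeCount(object@network),
              edgeCount(object@network), ncol(object@expression),
              length(object@diseases@sets), length(object@pathways@sets)))
})

#' Planted ground truth of a synthetic scenario
#' @param x a [SyntheticScenario-class].
#' @return list describing the planted structure.
#' @export
groundTruth <- function(x) {
  stopifnot(is(x, "SyntheticScenario"))
  x@truth
}
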