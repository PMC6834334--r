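#' Gene symbols contained in an object
#'
#' @param x an object holding genes (network, disease sets, catalog, ...).
#' @param ... unused.
#' @return character vector of gene symbols.
#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))

#' Gene sets contained in an object
#'
#' @param x a [DiseaseGeneSets-class] or [PathwayCatalog-class].
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Number of nodes of a network
#' @param x an [InteractionNetwork-class].
#' @return integer.
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' Number of edges of a network
#' @param x an [InteractionNetwork-class].
#' @return integer.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Edge table of a network
#' @param x an [InteractionNetwork-class].
#' @return data.frame with columns `from`, `to` and, when present,
#'   `sources`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Underlying igraph object
#' @param x an [InteractionNetwork-class].
#' @return the wrapped \code{igraph} graph.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Hierarchy depths of a pathway catalog
#' @param x a [PathwayCatalog-class].
#' @return named integer vector (NA when no hierarchy was supplied).
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' Raw propagation scores
#' @param x a [GeneScoreVector-class].
#' @return named numeric vector.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' Standardized propagation scores
#' @param x a [GeneScoreVector-class].
#' @return named numeric vector of z-scores.
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' Genes of a top-scoring set
#' @param x a [TopScoringSet-class].
#' @return character vector.
#' @export
setGeneric("topGenes", function(x) standardGeneric("topGenes"))
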