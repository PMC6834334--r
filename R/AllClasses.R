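#' @import methods
#' @importFrom S4Vectors metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setOldClass("igraph")

#' InteractionNetwork: an undirected gene-gene interaction graph
#'
#' Wraps an undirected, simple \pkg{igraph} graph whose vertices are gene
#' symbols.  Edges may carry a `sources` attribute recording which input
#' networks contributed them.  Self-loops and duplicate edges are never
#' present (enforced by the validity method).
#'
#' @slot graph an undirected simple \code{igraph} object with vertex
#'   attribute `name` (gene symbols).
#'
#' @seealso [readEdgeList()], [mergeNetworks()]
#' @export
setClass("InteractionNetwork", representation(graph = "igraph"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g))
    msg <- c(msg, "graph must be undirected")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    msg <- c(msg, "vertices must be named with gene symbols")
  if (igraph::any_loop(g))
    msg <- c(msg, "graph must not contain self-loops")
  if (igraph::any_multiple(g))
    msg <- c(msg, "graph must not contain duplicate edges")
  if (length(msg)) msg else TRUE
})

#' CellNetwork: the subnetwork induced by one cell type's specific genes
#'
#' An [InteractionNetwork-class] restricted to edges whose both endpoints
#' are specific to one cell type.  Every node has degree >= 1 within the
#' network: isolated specific genes are dropped at construction.
#'
#' @slot cellType label of the cell type.
#' @slot tissue tissue label (may be `NA`).
#'
#' @seealso [induceCellNetwork()]
#' @export
setClass("CellNetwork", contains = "InteractionNetwork",
         representation(cellType = "character", tissue = "character"))

setValidity("CellNetwork", function(object) {
  g <- object@graph
  if (igraph::vcount(g) > 0 && any(igraph::degree(g) == 0))
    return("cell network must not contain isolated genes")
  TRUE
})

#' DiseaseGeneSets: disease -> associated-gene-set mapping
#'
#' @slot sets named list of character vectors (disease label -> gene
#'   symbols).
#' @slot evidence named character vector, per disease: `"gwas-only"` iff
#'   every contributing association record was GWAS-derived, otherwise
#'   `"all"`.
#'
#' @seealso [readGeneDiseaseTable()]
#' @export
setClass("DiseaseGeneSets",
         representation(sets = "list", evidence = "character"))

setValidity("DiseaseGeneSets", function(object) {
  msg <- character()
  if (length(object@sets) && is.null(names(object@sets)))
    msg <- c(msg, "sets must be named by disease")
  if (any(vapply(object@sets, function(s)
        !is.character(s) || any(!nzchar(s)), logical(1))))
    msg <- c(msg, "gene symbols must be non-empty strings")
  if (length(object@evidence) != length(object@sets))
    msg <- c(msg, "evidence must have one entry per disease")
  if (length(msg)) msg else TRUE
})

#' PathwayCatalog: pathway gene sets with optional hierarchy depth
#'
#' @slot sets named list of character vectors (pathway id -> gene symbols).
#' @slot description named character vector of pathway names/descriptions.
#' @slot depth named integer vector of hierarchy depths (`NA` when no
#'   hierarchy was provided).
#'
#' @seealso [readGmt()], [selectDepth()], [filterRedundantPathways()]
#' @export
setClass("PathwayCatalog",
         representation(sets = "list", description = "character",
                        depth = "integer"))

setValidity("PathwayCatalog", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "pathway ids must be unique and non-NULL")
    if (any(lengths(object@sets) == 0))
      msg <- c(msg, "pathway gene sets must be non-empty")
  }
  if (length(object@depth) != length(object@sets) ||
      length(object@description) != length(object@sets))
    msg <- c(msg, "description and depth must parallel sets")
  if (any(!is.na(object@depth) & object@depth < 0))
    msg <- c(msg, "depths must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FilteredCatalog: a PathwayCatalog after redundancy filtering
#'
#' @slot removalLog data.frame with columns `removed`, `kept`, `overlap`:
#'   one row per removed pathway, naming the larger pathway it overlapped
#'   with and the Sorensen-Dice overlap that triggered the removal.
#' @slot threshold the overlap threshold used (pairs with overlap strictly
#'   greater are resolved).
#' @slot meanResidualOverlap mean pairwise Sorensen-Dice overlap among the
#'   surviving pathways.
#'
#' @seealso [filterRedundantPathways()]
#' @export
setClass("FilteredCatalog", contains = "PathwayCatalog",
         representation(removalLog = "data.frame", threshold = "numeric",
                        meanResidualOverlap = "numeric"))

#' NormalizedExpression: per-gene median/MAD standardized expression
#'
#' Extends \code{SummarizedExperiment}.  The single assay `"e"` holds
#' \eqn{e_{g,c} = (E_{g,c} - M_g) / MAD_g}, where \eqn{M_g} and
#' \eqn{MAD_g} are the median and the (raw, unscaled) median absolute
#' deviation of gene \eqn{g} across all cell types.  Genes with
#' \eqn{MAD_g = 0} are excluded; their symbols are kept in
#' \code{metadata(x)$excluded}.  Row metadata columns `M` and `MAD`
#' record the per-gene location and spread that were divided out.
#'
#' @seealso [normalizeExpression()], [callSpecificGenes()]
#' @export
setClass("NormalizedExpression", contains = "SummarizedExperiment")

setValidity("NormalizedExpression", function(object) {
  msg <- character()
  if (!"e" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'e' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("M", "MAD") %in% colnames(rd)))
    msg <- c(msg, "rowData columns 'M' and 'MAD' are required")
  else if (nrow(object) > 0 && any(rd$MAD <= 0))
    msg <- c(msg, "retained genes must have MAD > 0")
  if (length(msg)) msg else TRUE
})

#' SpecificityCalls: cell-type-specific gene calls under the k x IQR rule
#'
#' @slot calls named list (cell type -> character vector of specific
#'   genes).
#' @slot k threshold multiplier applied to the per-gene IQR (default 1.5).
#' @slot iqr named numeric vector: per-gene IQR of the normalized
#'   expression across cell types.
#' @slot zeroIqrGenes genes with IQR = 0, never callable as specific.
#'
#' @seealso [callSpecificGenes()]
#' @export
setClass("SpecificityCalls",
         representation(calls = "list", k = "numeric", iqr = "numeric",
                        zeroIqrGenes = "character"))

setValidity("SpecificityCalls", function(object) {
  if (length(object@k) != 1 || object@k <= 0)
    return("k must be a single positive number")
  TRUE
})

#' GeneScoreVector: propagation scores for one (cell type, disease)
#'
#' @slot cellType,disease labels of the cell network and seed disease.
#' @slot score named numeric vector of raw propagation scores, one per
#'   cell-network gene.
#' @slot z named numeric vector of z-scores (empty until
#'   [standardizeScores()] is applied; standardized with the population
#'   standard deviation over the network's genes).
#' @slot params list of propagation parameters (repetitions, iterations,
#'   damping, method, seed coverage).
#' @slot degenerate `TRUE` when all scores are equal and z was forced
#'   to 0.
#'
#' @seealso [propagateScores()], [standardizeScores()],
#'   [selectTopScoring()]
#' @export
setClass("GeneScoreVector",
         representation(cellType = "character", disease = "character",
                        score = "numeric", z = "numeric",
                        params = "list", degenerate = "logical"))

#' TopScoringSet: the top-scoring gene set S of one (cell type, disease)
#'
#' @slot cellType,disease labels.
#' @slot genes the selected genes (z at or above the cutoff).
#' @slot rule text describing the selection rule, for provenance.
#' @slot cutoff the z cutoff used.
#' @slot networkSize number of genes in the parent cell network.
#'
#' @seealso [selectTopScoring()], [multimorbidityScore()]
#' @export
setClass("TopScoringSet",
         representation(cellType = "character", disease = "character",
                        genes = "character", rule = "character",
                        cutoff = "numeric", networkSize = "integer"))

#' SyntheticScenario: a generated dataset with planted ground truth
#'
#' @slot seed the RNG seed the scenario was generated from.
#' @slot network the synthetic interactome.
#' @slot expression raw expression SummarizedExperiment (assay `"exprs"`).
#' @slot diseases planted disease gene sets.
#' @slot pathways pathway catalog with hierarchy depths.
#' @slot truth list of planted ground truth: per-cell-type specific genes,
#'   disease module locations, multimorbid cell types, planted pathways,
#'   redundant pathway pairs, effect-size parameters.
#' @slot config the full configuration list the generators were called
#'   with.
#'
#' @seealso [generateScenario()]
#' @export
setClass("SyntheticScenario",
         representation(seed = "integer", network = "InteractionNetwork",
                        expression = "SummarizedExperiment",
                        diseases = "DiseaseGeneSets",
                        pathways = "PathwayCatalog",
                        truth = "list", config = "list"))
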