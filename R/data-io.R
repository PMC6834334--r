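#' @importFrom utils read.delim write.table packageVersion
NULL

## internal: build an InteractionNetwork from a two-column edge matrix,
## trimming symbols, dropping self-loops and collapsing duplicates.
.makeNetwork <- function(from, to, source = NULL) {
  from <- trimws(from); to <- trimws(to)
  loops <- from == to
  if (any(loops))
    message(sum(loops), " self-loop(s) dropped")
  from <- from[!loops]; to <- to[!loops]
  if (!is.null(source)) source <- source[!loops]
  ## unordered uniqueness
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (length(a) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = character())
    return(new("InteractionNetwork", graph = g))
  }
  if (is.null(source)) {
    keep <- !duplicated(key)
    g <- igraph::graph_from_data_frame(
      data.frame(from = a[keep], to = b[keep]), directed = FALSE)
  } else {
    src <- vapply(split(source, key), function(s)
      paste(sort(unique(s)), collapse = ";"), character(1))
    keep <- !duplicated(key)
    g <- igraph::graph_from_data_frame(
      data.frame(from = a[keep], to = b[keep],
                 sources = src[key[keep]]), directed = FALSE)
  }
  new("InteractionNetwork", graph = g)
}

#' Read an interaction network from an edge-list file
#'
#' Accepts a plain two-column tab-separated gene-pair list or the SIF
#' dialect (`node1<TAB>relation<TAB>node2`).  Gene symbols are
#' whitespace-trimmed; self-loops are dropped with a message and duplicate
#' (unordered) pairs are collapsed.  Extra columns (e.g. confidence
#' weights) are read but ignored: the interactome is treated as
#' unweighted.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (two gene columns) or `"sif"` (gene, relation,
#'   gene).
#' @param source optional source name to tag every edge with (used by
#'   [mergeNetworks()] provenance).
#' @return an [InteractionNetwork-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\ta", "c\tc", "b\tc"), f)
#' net <- readEdgeList(f)
#' edgeCount(net)  # 2: a-b deduplicated, c-c dropped
#' @export
readEdgeList <- function(path, dialect = c("tsv", "sif"), source = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(.makeNetwork(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ## fall back to any-whitespace splitting for space-separated files
  if (any(lengths(parts) < 2))
    parts <- strsplit(trimws(lines), "[[:space:]]+")
  need <- if (dialect == "sif") 3L else 2L
  bad <- which(lengths(parts) < need)
  if (length(bad))
    stop(sprintf("malformed line %d in '%s': fewer than %d fields",
                 bad[1], path, need))
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), if (dialect == "sif") 3L else 2L)
  src <- if (is.null(source)) NULL else rep(source, length(from))
  .makeNetwork(from, to, src)
}

#' Merge interaction networks into one interactome
#'
#' Takes the union of nodes and edges.  When input edges carry `sources`
#' tags, the merged edge records every contributing source
#' (";"-separated, sorted); the merge is commutative and idempotent on
#' node and edge sets.
#'
#' @param networks list of [InteractionNetwork-class] objects (length >= 1).
#' @return an [InteractionNetwork-class].
#' @examples
#' f <- tempfile(); writeLines("a\tb", f)
#' g <- tempfile(); writeLines(c("a\tb", "b\tc"), g)
#' net <- mergeNetworks(list(readEdgeList(f, source = "one"),
#'                           readEdgeList(g, source = "two")))
#' edgeTable(net)
#' @export
mergeNetworks <- function(networks) {
  stopifnot(is.list(networks), length(networks) >= 1,
            all(vapply(networks, is, logical(1), "InteractionNetwork")))
  tabs <- lapply(networks, edgeTable)
  from <- unlist(lapply(tabs, `[[`, "from"), use.names = FALSE)
  to <- unlist(lapply(tabs, `[[`, "to"), use.names = FALSE)
  src <- unlist(lapply(tabs, function(t)
    if (is.null(t$sources)) rep(NA_character_, nrow(t)) else t$sources),
    use.names = FALSE)
  if (all(is.na(src))) src <- NULL
  else {
    src[is.na(src)] <- ""
    ## re-split multi-source tags so the union re-sorts them
    reps <- strsplit(src, ";", fixed = TRUE)
    reps <- lapply(reps, function(s) if (length(s)) s else "")
    n <- lengths(reps)
    from <- rep(from, n); to <- rep(to, n)
    src <- unlist(reps, use.names = FALSE)
  }
  merged <- .makeNetwork(from, to, src)
  ## preserve isolated nodes present in any input
  allGenes <- unique(unlist(lapply(networks, genes), use.names = FALSE))
  missing <- setdiff(allGenes, genes(merged))
  if (length(missing))
    merged@graph <- igraph::add_vertices(merged@graph, length(missing),
                                         name = missing)
  validObject(merged)
  merged
}

#' Read a pathway catalog from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `id<TAB>description<TAB>gene1<TAB>gene2...`.  Duplicate genes within a
#' set are collapsed.  An optional hierarchy table
#' (`pathway<TAB>parent<TAB>depth`) attaches depths for
#' [selectDepth()].
#'
#' @param path path to the GMT file.
#' @param hierarchy optional path to a tab-separated hierarchy file with
#'   header columns `pathway`, `parent`, `depth`, or a data.frame with
#'   those columns.
#' @return a [PathwayCatalog-class].
#' @export
readGmt <- function(path, hierarchy = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descr <- character()
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3)
    if (length(bad))
      stop(sprintf("malformed GMT line %d in '%s': fewer than 3 fields",
                   bad[1], path))
    ids <- vapply(parts, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
      stop("duplicate pathway id: ", ids[duplicated(ids)][1])
    descr <- stats::setNames(vapply(parts, `[[`, character(1), 2L), ids)
    sets <- stats::setNames(
      lapply(parts, function(p) unique(trimws(p[-(1:2)]))), ids)
  }
  depth <- stats::setNames(rep(NA_integer_, length(sets)), names(sets))
  if (!is.null(hierarchy)) {
    h <- if (is.data.frame(hierarchy)) hierarchy else
      read.delim(hierarchy, stringsAsFactors = FALSE)
    stopifnot(all(c("pathway", "depth") %in% colnames(h)))
    idx <- match(names(sets), h$pathway)
    depth[!is.na(idx)] <- as.integer(h$depth[idx[!is.na(idx)]])
  }
  new("PathwayCatalog", sets = sets, description = descr, depth = depth)
}

#' Read gene-disease associations from a table
#'
#' Expects a tab-separated file with header columns `gene`, `disease`,
#' `evidence`.  Associations for the same (gene, disease) pair coming
#' from several sources are collapsed to one.  A disease is flagged
#' `"gwas-only"` iff every one of its association records carries the
#' `gwas` evidence token; any other mix yields `"all"`.
#'
#' @param path path to the table.
#' @param gwasOnly if `TRUE`, keep only GWAS-derived association records
#'   before building the sets.
#' @return a [DiseaseGeneSets-class].
#' @export
readGeneDiseaseTable <- function(path, gwasOnly = FALSE) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("gene", "disease", "evidence") %in% colnames(tab)))
  .diseaseSetsFromRecords(tab$gene, tab$disease, tab$evidence, gwasOnly)
}

.evidenceTokens <- c("gwas", "curated", "experimental", "literature")

.diseaseSetsFromRecords <- function(gene, disease, evidence,
                                    gwasOnly = FALSE) {
  gene <- trimws(gene); disease <- trimws(disease)
  evidence <- trimws(tolower(evidence))
  unknown <- setdiff(unique(evidence), .evidenceTokens)
  if (length(unknown))
    stop("unknown evidence token(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(.evidenceTokens, collapse = ", "), ")")
  if (gwasOnly) {
    keep <- evidence == "gwas"
    gene <- gene[keep]; disease <- disease[keep]; evidence <- evidence[keep]
  }
  sets <- lapply(split(gene, disease), function(g) sort(unique(g)))
  flags <- vapply(split(evidence, disease), function(e)
    if (all(e == "gwas")) "gwas-only" else "all", character(1))
  new("DiseaseGeneSets", sets = sets, evidence = flags[names(sets)])
}

#' Read a gene x cell-type expression matrix
#'
#' Tab-separated, header row of cell-type labels, first column gene
#' symbols.  Column labels may carry a tissue as `"tissue|cell_type"`;
#' plain cell-type labels are also accepted.  Genes with any non-numeric
#' value are dropped with a message listing them; duplicate gene rows are
#' an error.
#'
#' @param path path to the file.
#' @return a \code{SummarizedExperiment} with assay `"exprs"`, rownames =
#'   genes, and colData columns `tissue` (NA when absent from the label)
#'   and `cell_type`.
#' @export
readExpressionMatrix <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
  geneCol <- tab[[1]]
  if (anyDuplicated(geneCol))
    stop("duplicate gene row: ", geneCol[duplicated(geneCol)][1])
  body <- tab[, -1, drop = FALSE]
  num <- as.matrix(as.data.frame(lapply(body, function(col)
    suppressWarnings(as.numeric(col))), check.names = FALSE))
  badRows <- apply(num, 1, function(r) any(!is.finite(r)))
  if (any(badRows))
    message("dropped ", sum(badRows), " gene(s) with non-numeric values: ",
            paste(utils::head(geneCol[badRows], 10), collapse = ", "))
  num <- num[!badRows, , drop = FALSE]
  rownames(num) <- geneCol[!badRows]
  colnames(num) <- colnames(body)
  makeExpressionSE(num)
}

#' Build an expression SummarizedExperiment from a matrix
#'
#' Column names may follow the `"tissue|cell_type"` convention; the
#' tissue part is split into colData.
#'
#' @param mat numeric matrix, rownames = gene symbols, colnames =
#'   cell-type labels.
#' @return SummarizedExperiment with assay `"exprs"`.
#' @export
makeExpressionSE <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat),
            !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (anyDuplicated(rownames(mat))) stop("duplicate gene labels")
  if (anyDuplicated(colnames(mat))) stop("duplicate cell-type labels")
  if (any(!is.finite(mat))) stop("expression values must be finite")
  lab <- colnames(mat)
  hasTissue <- grepl("|", lab, fixed = TRUE)
  tissue <- ifelse(hasTissue, sub("\\|.*$", "", lab), NA_character_)
  ct <- ifelse(hasTissue, sub("^[^|]*\\|", "", lab), lab)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(tissue = tissue, cell_type = ct,
                                   row.names = lab))
}

#' Restrict all inputs to the common gene universe
#'
#' The analysis universe is the intersection of the interactome's genes
#' with the expression matrix's genes: genes absent from either are
#' removed from every input, and disease or pathway sets left empty are
#' dropped.  Applying the restriction twice equals applying it once.
#'
#' @param net [InteractionNetwork-class].
#' @param expr SummarizedExperiment from [readExpressionMatrix()].
#' @param diseases [DiseaseGeneSets-class] or `NULL`.
#' @param pathways [PathwayCatalog-class] or `NULL`.
#' @return list with elements `network`, `expression`, `diseases`,
#'   `pathways`, `universe` and `removed` (a per-input report of removed
#'   gene counts and dropped set names).
#' @export
restrictToCommonUniverse <- function(net, expr, diseases = NULL,
                                     pathways = NULL) {
  universe <- intersect(genes(net), rownames(expr))
  if (length(universe) == 0)
    stop("empty universe: interactome and expression data share no genes")
  removed <- list(
    network = setdiff(genes(net), universe),
    expression = setdiff(rownames(expr), universe))
  g <- igraph::induced_subgraph(net@graph,
                                intersect(genes(net), universe))
  rnet <- new("InteractionNetwork", graph = g)
  rexpr <- expr[intersect(rownames(expr), universe), , drop = FALSE]
  rdis <- diseases
  if (!is.null(diseases)) {
    sets <- lapply(diseases@sets, intersect, universe)
    removed$diseases <- sum(lengths(diseases@sets)) - sum(lengths(sets))
    keep <- lengths(sets) > 0
    removed$droppedDiseases <- names(sets)[!keep]
    rdis <- new("DiseaseGeneSets", sets = sets[keep],
                evidence = diseases@evidence[keep])
  }
  rpath <- pathways
  if (!is.null(pathways)) {
    sets <- lapply(pathways@sets, intersect, universe)
    removed$pathways <- sum(lengths(pathways@sets)) - sum(lengths(sets))
    keep <- lengths(sets) > 0
    removed$droppedPathways <- names(sets)[!keep]
    rpath <- new("PathwayCatalog", sets = sets[keep],
                 description = pathways@description[keep],
                 depth = pathways@depth[keep])
  }
  list(network = rnet, expression = rexpr, diseases = rdis,
       pathways = rpath, universe = sort(universe), removed = removed)
}

## ---- writers ------------------------------------------------------------

.provenanceLine <- function(config = NULL) {
  hash <- if (is.null(config)) "none" else configHash(config)
  sprintf("# multimorbinet %s, config %s",
          as.character(utils::packageVersion("multimorbinet")), hash)
}

#' Hash of a configuration list
#'
#' Canonical md5 of the deparsed configuration, used to stamp output
#' files and pipeline manifests.
#'
#' @param config a list.
#' @return character md5 digest.
#' @export
configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Write an interaction network as a two-column edge list
#'
#' @param net [InteractionNetwork-class].
#' @param path output path.
#' @param provenance write a commented provenance line first.
#' @param config optional configuration list hashed into the provenance
#'   line.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path, provenance = TRUE, config = NULL) {
  tab <- edgeTable(net)
  con <- file(path, "w")
  on.exit(close(con))
  if (provenance) writeLines(.provenanceLine(config), con)
  writeLines(paste(tab$from, tab$to, sep = "\t"), con)
  invisible(path)
}

#' Write a pathway catalog in GMT format
#'
#' @param catalog [PathwayCatalog-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(catalog, path) {
  lines <- vapply(names(catalog@sets), function(id)
    paste(c(id, catalog@description[[id]], catalog@sets[[id]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV with a provenance header
#'
#' @param tab data.frame.
#' @param path output path.
#' @param config optional configuration list hashed into the provenance
#'   line.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(tab, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceLine(config), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
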