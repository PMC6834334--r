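#' Perturbation Score of a pathway for a disease in a cell network
#'
#' Two variants are provided because two readings of the score coexist:
#'
#' * `"printed"` — the ratio of the pathway's representation in the cell
#'   network to the top-scoring set's share of the network:
#'   \deqn{PS = (n_p^{net} / n_p^{total}) / (|S| / N)}
#'   This matches the worked arithmetic (e.g. (9/20) / (13/225) = 7.79)
#'   and is independent of which genes are in S given |S|.
#' * `"overlap"` — the enrichment of pathway genes inside S:
#'   \deqn{PS = (|p \cap S| / |S|) / (n_p^{net} / N)}
#'   which depends on S's composition and is the variant recommended for
#'   analyses where pathway-specific signal matters.
#'
#' @param nPathwayTotal total number of genes annotated to the pathway.
#' @param pathwayNetGenes genes of the pathway present in the cell
#'   network (character vector), or for the printed variant optionally
#'   just their count.
#' @param topSet [TopScoringSet-class] (or a character vector of S's
#'   genes together with `networkSize`).
#' @param networkSize number of genes N in the cell network (taken from
#'   `topSet` when it is a [TopScoringSet-class]).
#' @param variant `"printed"` (default) or `"overlap"`.
#' @return numeric PS (> 0 when defined); `NA` with a warning when
#'   |S| = 0 or the pathway has no annotated gene.
#' @examples
#' S <- as.character(1:13)
#' perturbationScore(20, as.character(101:109), S, networkSize = 225)
#' # (9/20) / (13/225) = 7.79
#' @export
perturbationScore <- function(nPathwayTotal, pathwayNetGenes, topSet,
                              networkSize = NULL,
                              variant = c("printed", "overlap")) {
  variant <- match.arg(variant)
  if (is(topSet, "TopScoringSet")) {
    networkSize <- topSet@networkSize
    S <- topGenes(topSet)
  } else S <- unique(as.character(topSet))
  if (is.null(networkSize))
    stop("networkSize is required when topSet is not a TopScoringSet")
  nNet <- if (is.numeric(pathwayNetGenes) && length(pathwayNetGenes) == 1)
    pathwayNetGenes else length(unique(pathwayNetGenes))
  if (nPathwayTotal < nNet) stop("nPathwayTotal must be >= pathway genes in network")
  if (length(S) == 0 || nPathwayTotal == 0) {
    warning("undefined perturbation score (empty S or pathway)")
    return(NA_real_)
  }
  if (variant == "printed") {
    (nNet / nPathwayTotal) / (length(S) / networkSize)
  } else {
    if (is.numeric(pathwayNetGenes) && length(pathwayNetGenes) == 1)
      stop("the overlap variant needs the identities of the pathway's in-network genes")
    if (nNet == 0) {
      warning("undefined perturbation score (pathway absent from network)")
      return(NA_real_)
    }
    (length(intersect(unique(pathwayNetGenes), S)) / length(S)) /
      (nNet / networkSize)
  }
}

#' Randomization null test for Perturbation Scores
#'
#' Builds the null by re-running the propagation and top-scoring
#' selection from degree-matched random seed sets of the same size as
#' the disease's seeds, recomputing PS for each draw, and applying the
#' add-one upper-tail estimator
#' \eqn{p = (1 + \#\{PS_{perm} \ge PS_{obs}\}) / (1 + n_{perm})}.
#' Several pathways can be tested in one call: the permuted top-scoring
#' sets are shared, as they only depend on the seeds.
#'
#' @param cellnet [CellNetwork-class].
#' @param pathways named list: pathway id -> full pathway gene set.
#' @param seeds character vector of the disease's seed genes.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed (mandatory).
#' @param variant PS variant, see [perturbationScore()].
#' @param zCutoff,repetitions,iterations,damping,method propagation and
#'   selection parameters.
#' @return data.frame with one row per pathway: observed PS, counts, the
#'   add-one p-value, and a flag for pathways with no gene in the
#'   network (no p is computed for those).
#' @export
psNullTest <- function(cellnet, pathways, seeds, nPerm = 1000L, seed,
                       variant = c("printed", "overlap"),
                       zCutoff = 2.0, repetitions = 3L, iterations = 2L,
                       damping = 0.25, method = "netscore") {
  variant <- match.arg(variant)
  stopifnot(is(cellnet, "CellNetwork"), is.list(pathways))
  if (missing(seed)) stop("an RNG seed is mandatory")
  g <- genes(cellnet)
  N <- length(g)
  adj <- .adjacency(cellnet)
  seedIdx <- match(intersect(unique(seeds), g), g)
  if (length(seedIdx) == 0)
    stop("no seed gene inside the cell network")
  obsMat <- matrix(FALSE, N, 1)
  obsMat[seedIdx, 1] <- TRUE
  Sobs <- .topSetMatrix(adj, obsMat, repetitions, iterations, damping,
                        method, zCutoff)[, 1]
  set.seed(seed)
  seedMat <- .degreeMatchedSeeds(rowSums(adj), seedIdx, nPerm)
  Sperm <- .topSetMatrix(adj, seedMat, repetitions, iterations, damping,
                         method, zCutoff)
  sizeObs <- sum(Sobs)
  sizePerm <- colSums(Sperm)
  rows <- list()
  for (pid in names(pathways)) {
    pg <- unique(pathways[[pid]])
    inNet <- intersect(pg, g)
    nNet <- length(inNet)
    flag <- ""
    psObs <- NA_real_; p <- NA_real_
    if (nNet == 0) {
      flag <- "pathway_not_in_network"
    } else if (sizeObs == 0) {
      flag <- "empty_top_set"
    } else {
      if (variant == "printed") {
        psObs <- (nNet / length(pg)) / (sizeObs / N)
        psPerm <- ifelse(sizePerm == 0, NA,
                         (nNet / length(pg)) / (sizePerm / N))
      } else {
        idx <- match(inNet, g)
        ovObs <- sum(Sobs[idx])
        psObs <- (ovObs / sizeObs) / (nNet / N)
        ovPerm <- colSums(Sperm[idx, , drop = FALSE])
        psPerm <- ifelse(sizePerm == 0, NA,
                         (ovPerm / sizePerm) / (nNet / N))
      }
      ok <- !is.na(psPerm)
      p <- (1 + sum(psPerm[ok] >= psObs)) / (1 + sum(ok))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cell_type = cellnet@cellType, pathway = pid,
      PS = psObs, n_pathway_total = length(pg), n_pathway_net = nNet,
      S_size = sizeObs, n_pathway_in_S =
        if (nNet) sum(Sobs[match(inNet, g)]) else 0L,
      network_size = N, p_value = p, n_perm = nPerm, variant = variant,
      flag = flag, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Perturbation table across cell networks, pathways and diseases
#'
#' Runs [psNullTest()] for every (cell network, disease) against all
#' pathways of a catalog.
#'
#' @param cellnets list of [CellNetwork-class] objects.
#' @param catalog [PathwayCatalog-class].
#' @param diseaseSets [DiseaseGeneSets-class].
#' @param nPerm,seed,variant,zCutoff,repetitions,iterations,damping,method
#'   see [psNullTest()].
#' @return data.frame (rows of [psNullTest()] plus a `disease` column).
#' @export
perturbationTable <- function(cellnets, catalog, diseaseSets,
                              nPerm = 1000L, seed,
                              variant = c("printed", "overlap"),
                              zCutoff = 2.0, repetitions = 3L,
                              iterations = 2L, damping = 0.25,
                              method = "netscore") {
  variant <- match.arg(variant)
  if (missing(seed)) stop("an RNG seed is mandatory")
  rows <- list()
  for (ci in seq_along(cellnets)) {
    cn <- cellnets[[ci]]
    if (nodeCount(cn) < 2) next
    for (di in seq_along(diseaseSets@sets)) {
      d <- names(diseaseSets@sets)[di]
      if (length(intersect(diseaseSets@sets[[d]], genes(cn))) == 0) next
      tab <- psNullTest(cn, geneSets(catalog), diseaseSets@sets[[d]],
                        nPerm = nPerm, seed = seed + 131L * ci + di,
                        variant = variant, zCutoff = zCutoff,
                        repetitions = repetitions,
                        iterations = iterations, damping = damping,
                        method = method)
      tab$disease <- d
      rows[[length(rows) + 1L]] <- tab
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Call multimorbidity mechanisms from a perturbation table
#'
#' A pathway is a candidate mechanism of multimorbidity in a cell type
#' when it is significantly perturbed (p < alpha) by two or more
#' diseases there.  One row is emitted per (cell type, pathway), keyed
#' by the maximal combination of significant diseases (e.g. a pathway
#' significant for all three diseases is reported once, under the triple
#' label).
#'
#' @param psTable data.frame from [perturbationTable()] (or
#'   [psNullTest()] results with a `disease` column).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `cell_type`, `pathway`,
#'   `combination`, `n_diseases`, `min_p`; zero rows when no pathway
#'   qualifies.
#' @export
callMechanisms <- function(psTable, alpha = 0.05) {
  stopifnot(is.data.frame(psTable),
            all(c("cell_type", "pathway", "disease", "p_value") %in%
                  colnames(psTable)))
  sig <- psTable[!is.na(psTable$p_value) & psTable$p_value < alpha, ]
  if (nrow(sig) == 0)
    return(data.frame(cell_type = character(), pathway = character(),
                      combination = character(), n_diseases = integer(),
                      min_p = numeric(), stringsAsFactors = FALSE))
  keys <- split(sig, paste(sig$cell_type, sig$pathway, sep = "\r"))
  rows <- lapply(keys, function(s) {
    ds <- sort(unique(s$disease))
    if (length(ds) < 2) return(NULL)
    data.frame(cell_type = s$cell_type[1], pathway = s$pathway[1],
               combination = paste(ds, collapse = "+"),
               n_diseases = length(ds), min_p = min(s$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(cell_type = character(), pathway = character(),
                      combination = character(), n_diseases = integer(),
                      min_p = numeric(), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
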