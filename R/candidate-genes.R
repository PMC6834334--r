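#' Find candidate multimorbidity genes by top-set membership
#'
#' A gene is a candidate for a disease pair when it belongs to both
#' diseases' top-scoring sets in the same cell type, and for the full
#' triple when it belongs to all three.
#'
#' @param topSets named list: disease -> [TopScoringSet-class], all from
#'   one cell type (>= 2 diseases).
#' @return data.frame with columns `gene`, `cell_type`, `combination`,
#'   `member_diseases`; one row per (gene, combination of >= 2 diseases
#'   whose sets all contain the gene).
#' @export
findCandidates <- function(topSets) {
  stopifnot(is.list(topSets), length(topSets) >= 2,
            all(vapply(topSets, is, logical(1), "TopScoringSet")))
  ct <- unique(vapply(topSets, function(s) s@cellType, character(1)))
  if (length(ct) > 1) stop("top sets must come from one cell type")
  dis <- names(topSets)
  rows <- list()
  for (m in 2:length(dis)) {
    for (combo in utils::combn(dis, m, simplify = FALSE)) {
      common <- Reduce(intersect, lapply(topSets[combo], topGenes))
      for (gene in common)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, cell_type = ct,
          combination = paste(combo, collapse = "+"),
          member_diseases = m, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(), cell_type = character(),
                      combination = character(),
                      member_diseases = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Gene-level multimorbidity score for a disease combination
#'
#' The arithmetic mean of the gene's standardized propagation z-scores
#' over the combination's diseases, within one cell network.
#'
#' @param zByDisease named numeric vector: disease -> the gene's z-score
#'   in this cell network.
#' @param combination character vector of disease labels.
#' @return numeric mean z.
#' @export
scoreCandidate <- function(zByDisease, combination) {
  if (!all(combination %in% names(zByDisease)))
    stop("missing z-score for: ",
         paste(setdiff(combination, names(zByDisease)), collapse = ", "))
  mean(zByDisease[combination])
}

#' Rank candidate genes and flag novel ones
#'
#' Builds the per-cell-type candidate table: for every candidate gene,
#' the mean z-score over each combination it belongs to, a descending
#' sort on the mean of its available combination scores (stable
#' lexicographic tie-break on the gene symbol), and a novelty flag that
#' is `TRUE` iff the gene is absent from every input disease gene set.
#'
#' @param scoresByDisease named list: disease -> [GeneScoreVector-class]
#'   with z filled, all from one cell network.
#' @param topSets named list: disease -> [TopScoringSet-class] (same
#'   diseases).
#' @param diseaseSets [DiseaseGeneSets-class]: the input association
#'   sets used for the novelty flag.
#' @param tissue optional tissue label carried into the table.
#' @return data.frame with columns `cell_type`, `tissue`, `gene`, one
#'   column per combination (mean z; `NA` when the gene is not a
#'   candidate for it), `mean_score`, `novel`, `member_sets`.
#' @export
rankAndFlag <- function(scoresByDisease, topSets, diseaseSets,
                        tissue = NA_character_) {
  stopifnot(is.list(scoresByDisease), is.list(topSets),
            is(diseaseSets, "DiseaseGeneSets"))
  cand <- findCandidates(topSets)
  if (nrow(cand) == 0)
    return(data.frame(cell_type = character(), tissue = character(),
                      gene = character(), mean_score = numeric(),
                      novel = logical(), member_sets = character(),
                      stringsAsFactors = FALSE))
  ct <- cand$cell_type[1]
  combos <- unique(cand$combination)
  geneRows <- unique(cand$gene)
  zmat <- vapply(scoresByDisease, zscores,
                 numeric(length(zscores(scoresByDisease[[1]]))))
  out <- data.frame(cell_type = ct, tissue = tissue, gene = geneRows,
                    stringsAsFactors = FALSE)
  for (combo in combos) {
    ds <- strsplit(combo, "+", fixed = TRUE)[[1]]
    inCombo <- cand$gene[cand$combination == combo]
    out[[combo]] <- ifelse(
      out$gene %in% inCombo,
      vapply(out$gene, function(gene)
        mean(zmat[gene, ds]), numeric(1)),
      NA_real_)
  }
  comboCols <- as.data.frame(out[, combos, drop = FALSE])
  out$mean_score <- rowMeans(comboCols, na.rm = TRUE)
  known <- unique(unlist(geneSets(diseaseSets), use.names = FALSE))
  out$novel <- !(out$gene %in% known)
  memb <- split(cand$combination, cand$gene)
  out$member_sets <- vapply(out$gene, function(gene)
    paste(sort(memb[[gene]]), collapse = ";"), character(1))
  out <- out[order(-out$mean_score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full candidate-gene table for a set of cell networks
#'
#' Propagates every disease on every cell network, selects top-scoring
#' sets, and assembles the ranked candidate table per cell type.
#'
#' @param cellnets list of [CellNetwork-class] objects.
#' @param diseaseSets [DiseaseGeneSets-class].
#' @param zCutoff,repetitions,iterations,damping,method propagation and
#'   selection parameters.
#' @return data.frame: the union of per-cell-type [rankAndFlag()]
#'   tables.
#' @export
candidateGeneTable <- function(cellnets, diseaseSets, zCutoff = 2.0,
                               repetitions = 3L, iterations = 2L,
                               damping = 0.25, method = "netscore") {
  rows <- list()
  for (cn in cellnets) {
    if (nodeCount(cn) < 2) next
    g <- genes(cn)
    withSeeds <- names(diseaseSets@sets)[vapply(
      diseaseSets@sets, function(s) length(intersect(s, g)) > 0,
      logical(1))]
    if (length(withSeeds) < 2) next
    gsvs <- lapply(stats::setNames(withSeeds, withSeeds), function(d)
      standardizeScores(propagateScores(
        cn, diseaseSets@sets[[d]], disease = d,
        repetitions = repetitions, iterations = iterations,
        damping = damping, method = method)))
    tops <- lapply(gsvs, selectTopScoring, zCutoff = zCutoff)
    tab <- rankAndFlag(gsvs, tops, diseaseSets, tissue = cn@tissue)
    if (nrow(tab)) rows[[length(rows) + 1L]] <- tab
  }
  if (length(rows) == 0) return(NULL)
  ## align columns across cell types (combinations may differ)
  cols <- unique(unlist(lapply(rows, colnames)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(cols, colnames(r))) r[[cc]] <- NA
    r[, cols, drop = FALSE]
  })
  do.call(rbind, rows)
}
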