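#' Multimorbidity Score of two or three top-scoring gene sets
#'
#' The Sorensen-Dice overlap between the top-scoring gene sets of the
#' diseases in one cell type: for two diseases
#' \deqn{MS = 2 |S_1 \cap S_2| / (|S_1| + |S_2|)}
#' and for three, the generalized form
#' \eqn{3 |S_1 \cap S_2 \cap S_3| / (|S_1| + |S_2| + |S_3|)} (or,
#' with `variant = "mean-pairwise"`, the mean of the three pairwise
#' scores).  MS = 0 means detached mechanisms, MS = 1 identical ones.
#' An empty set yields MS = 0 with a `degenerate` attribute.
#'
#' @param sets list of 2 or 3 [TopScoringSet-class] objects from the
#'   same cell type, or plain character vectors.
#' @param variant for 3 sets: `"generalized"` (default) or
#'   `"mean-pairwise"`.
#' @return numeric MS in \[0, 1\]; attribute `degenerate = TRUE` when
#'   any input set was empty.
#' @examples
#' multimorbidityScore(list(as.character(1:6), as.character(6:52)))
#' # 2*1/(6+47) = 0.0377...
#' @export
multimorbidityScore <- function(sets, variant = c("generalized",
                                                  "mean-pairwise")) {
  variant <- match.arg(variant)
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L))
  isTop <- vapply(sets, is, logical(1), "TopScoringSet")
  if (any(isTop)) {
    stopifnot(all(isTop))
    ct <- unique(vapply(sets, function(s) s@cellType, character(1)))
    if (length(ct) > 1)
      stop("top-scoring sets come from different cell types: ",
           paste(ct, collapse = ", "))
    sets <- lapply(sets, topGenes)
  }
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (length(sets) == 2 || variant == "generalized") {
    common <- Reduce(intersect, sets)
    length(sets) * length(common) / sum(lengths(sets))
  } else {
    pairs <- utils::combn(3, 2)
    mean(apply(pairs, 2, function(ij)
      sorensenDice(sets[[ij[1]]], sets[[ij[2]]])))
  }
}

## internal: degree-matched random seed sets within log2 degree bins.
## Returns an n x nPerm indicator matrix.  Bins with fewer candidates
## than needed are widened by merging with the nearest bins (warning).
.degreeMatchedSeeds <- function(deg, seedIdx, nPerm) {
  n <- length(deg)
  bins <- floor(log2(pmax(deg, 1)))
  seedBins <- bins[seedIdx]
  need <- table(seedBins)
  out <- matrix(FALSE, n, nPerm)
  candidatesByBin <- split(seq_len(n), bins)
  for (b in names(need)) {
    k <- need[[b]]
    cand <- candidatesByBin[[b]]
    width <- 0
    while (length(cand) < k) {
      width <- width + 1
      lo <- as.numeric(b) - width; hi <- as.numeric(b) + width
      cand <- unique(unlist(candidatesByBin[
        names(candidatesByBin)[as.numeric(names(candidatesByBin)) >= lo &
                               as.numeric(names(candidatesByBin)) <= hi]]))
      if (width > 64) stop("cannot satisfy degree-matched sampling")
    }
    if (width > 0)
      warning(sprintf(
        "degree bin %s widened by %d to find %d candidates", b, width, k))
    for (j in seq_len(nPerm))
      out[sample(cand, k), j] <- TRUE
  }
  out
}

#' Degree-matched permutation test for a Multimorbidity Score
#'
#' Replaces each disease's seed genes by random gene sets of equal size
#' drawn within logarithmic (log2) degree bins of the cell network, so
#' the null preserves the hubness profile of the real seeds.  For every
#' permutation the propagation and top-scoring selection are re-run and
#' MS recomputed.  The p-value uses the add-one estimator
#' \deqn{p = (1 + \#\{MS_{perm} \ge MS_{obs}\}) / (1 + n_{perm})}
#' which is never 0 and never exceeds 1.
#'
#' @param cellnet [CellNetwork-class].
#' @param seedsByDisease named list: disease -> character vector of seed
#'   genes.
#' @param observedMS the observed MS; when `NULL` it is computed from
#'   `seedsByDisease` under the same propagation settings.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed (mandatory; all permutation loops are
#'   reproducible).
#' @param zCutoff,repetitions,iterations,damping,method propagation and
#'   selection parameters, see [propagateScores()] and
#'   [selectTopScoring()].
#' @param variant three-disease MS variant, see [multimorbidityScore()].
#' @return list with `p` (add-one permutation p-value), `observedMS`,
#'   `permMS` (numeric vector of permuted scores) and `nPerm`.
#' @export
msPermutationTest <- function(cellnet, seedsByDisease, observedMS = NULL,
                              nPerm = 1000L, seed,
                              zCutoff = 2.0, repetitions = 3L,
                              iterations = 2L, damping = 0.25,
                              method = "netscore",
                              variant = "generalized") {
  stopifnot(is(cellnet, "CellNetwork"), is.list(seedsByDisease),
            length(seedsByDisease) %in% c(2L, 3L), nPerm >= 1)
  if (missing(seed)) stop("an RNG seed is mandatory")
  g <- genes(cellnet)
  adj <- .adjacency(cellnet)
  deg <- rowSums(adj)
  seedIdx <- lapply(seedsByDisease, function(s)
    match(intersect(unique(s), g), g))
  if (any(lengths(seedIdx) == 0))
    stop("every disease needs at least one seed inside the cell network")
  if (is.null(observedMS)) {
    obsSets <- lapply(seedIdx, function(idx) {
      m <- matrix(FALSE, length(g), 1)
      m[idx, 1] <- TRUE
      S <- .topSetMatrix(adj, m, repetitions, iterations, damping,
                         method, zCutoff)
      g[S[, 1]]
    })
    observedMS <- as.numeric(multimorbidityScore(obsSets,
                                                 variant = variant))
  }
  set.seed(seed)
  Smats <- lapply(seedIdx, function(idx) {
    seedMat <- .degreeMatchedSeeds(deg, idx, nPerm)
    .topSetMatrix(adj, seedMat, repetitions, iterations, damping,
                  method, zCutoff)
  })
  sizes <- vapply(Smats, colSums, numeric(nPerm))
  if (nPerm == 1) sizes <- matrix(sizes, nrow = 1)
  inter <- colSums(Reduce(`&`, Smats))
  denom <- rowSums(sizes)
  k <- length(Smats)
  permMS <- ifelse(denom == 0 | apply(sizes == 0, 1, any), 0,
                   k * inter / denom)
  if (variant == "mean-pairwise" && k == 3) {
    pairMS <- sapply(utils::combn(3, 2, simplify = FALSE), function(ij) {
      i2 <- colSums(Smats[[ij[1]]] & Smats[[ij[2]]])
      den <- sizes[, ij[1]] + sizes[, ij[2]]
      ifelse(den == 0, 0, 2 * i2 / den)
    })
    permMS <- rowMeans(pairMS)
  }
  p <- (1 + sum(permMS >= observedMS)) / (1 + nPerm)
  list(p = p, observedMS = observedMS, permMS = permMS, nPerm = nPerm)
}

#' Multimorbidity Scores across cell networks and disease combinations
#'
#' Convenience wrapper: for every cell network and every pair (and the
#' full triple when three diseases are supplied), propagates the seeds,
#' selects top-scoring sets, computes MS and (optionally) the
#' degree-matched permutation p-value.
#'
#' @param cellnets list of [CellNetwork-class] objects.
#' @param diseaseSets [DiseaseGeneSets-class].
#' @param nPerm permutations for the MS test; 0 skips testing.
#' @param seed RNG seed (mandatory when `nPerm > 0`).
#' @param zCutoff,repetitions,iterations,damping,method propagation and
#'   selection parameters.
#' @return data.frame with columns `cell_type`, `tissue`, `combination`,
#'   `MS`, set sizes, `n_intersection`, `p_value`, `n_perm`, `flag`.
#' @export
multimorbidityTable <- function(cellnets, diseaseSets, nPerm = 1000L,
                                seed = NULL, zCutoff = 2.0,
                                repetitions = 3L, iterations = 2L,
                                damping = 0.25, method = "netscore") {
  stopifnot(is.list(cellnets), is(diseaseSets, "DiseaseGeneSets"))
  if (nPerm > 0 && is.null(seed)) stop("an RNG seed is mandatory")
  dis <- names(diseaseSets@sets)
  combos <- utils::combn(dis, 2, simplify = FALSE)
  if (length(dis) == 3) combos <- c(combos, list(dis))
  rows <- list()
  for (ci in seq_along(cellnets)) {
    cn <- cellnets[[ci]]
    g <- genes(cn)
    tops <- list()
    for (d in dis) {
      if (length(g) < 2) { tops[[d]] <- NULL; next }
      gsv <- standardizeScores(propagateScores(
        cn, diseaseSets@sets[[d]], disease = d,
        repetitions = repetitions, iterations = iterations,
        damping = damping, method = method))
      tops[[d]] <- selectTopScoring(gsv, zCutoff)
    }
    for (combo in combos) {
      lab <- paste(combo, collapse = "+")
      flag <- ""
      if (length(g) < 2 ||
          any(vapply(combo, function(d)
            length(intersect(diseaseSets@sets[[d]], g)) == 0,
            logical(1)))) {
        ms <- 0; p <- NA_real_; flag <- "degenerate"
        sizes <- rep(0L, length(combo)); ninter <- 0L
      } else {
        sets <- tops[combo]
        ms <- multimorbidityScore(sets)
        if (isTRUE(attr(ms, "degenerate"))) flag <- "degenerate"
        ms <- as.numeric(ms)
        sizes <- vapply(sets, function(s) length(topGenes(s)), integer(1))
        ninter <- length(Reduce(intersect, lapply(sets, topGenes)))
        p <- NA_real_
        if (nPerm > 0 && flag == "") {
          p <- msPermutationTest(
            cn, diseaseSets@sets[combo], observedMS = ms, nPerm = nPerm,
            seed = seed + 7L * ci + sum(utf8ToInt(lab)) %% 1000L,
            zCutoff = zCutoff, repetitions = repetitions,
            iterations = iterations, damping = damping,
            method = method)$p
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = cn@cellType, tissue = cn@tissue, combination = lab,
        MS = ms, sizes = paste(sizes, collapse = "/"),
        n_intersection = ninter, p_value = p, n_perm = nPerm,
        flag = flag, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
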