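#' Sorensen-Dice overlap of two gene sets
#'
#' \deqn{SD(A, B) = 2 |A \cap B| / (|A| + |B|)}
#' A symmetric set-similarity index in \[0, 1\]: 1 iff the sets are
#' equal, 0 iff they are disjoint.
#'
#' @param a,b character vectors (duplicates are collapsed).  At least one
#'   must be non-empty.
#' @return numeric in \[0, 1\].
#' @examples
#' sorensenDice(letters[1:6], c("a", letters[7:26], LETTERS))  # 2/53
#' @export
sorensenDice <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0)
    stop("sorensenDice is undefined for two empty sets")
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Keep only pathways at a given hierarchy depth
#'
#' Broad, shallow pathways annotate many genes loosely; deep ones are
#' small and specific.  Selecting one depth of the hierarchy fixes that
#' trade-off; depth 3 is the default working level.
#'
#' @param catalog a [PathwayCatalog-class] with hierarchy depths.
#' @param depth integer depth to retain (default 3).
#' @return a [PathwayCatalog-class].
#' @export
selectDepth <- function(catalog, depth = 3L) {
  stopifnot(is(catalog, "PathwayCatalog"))
  if (all(is.na(catalog@depth)))
    stop("catalog has no hierarchy depths; supply a hierarchy table")
  keep <- !is.na(catalog@depth) & catalog@depth == depth
  if (!any(keep))
    stop("no pathway at depth ", depth)
  new("PathwayCatalog", sets = catalog@sets[keep],
      description = catalog@description[keep],
      depth = catalog@depth[keep])
}

## internal: full pairwise Sorensen-Dice matrix via incidence crossprod
.pairwiseDice <- function(sets) {
  ids <- names(sets)
  allGenes <- unique(unlist(sets, use.names = FALSE))
  inc <- vapply(sets, function(s) allGenes %in% s,
                logical(length(allGenes)))
  inc <- matrix(as.numeric(inc), nrow = length(allGenes))
  inter <- crossprod(inc)
  sizes <- lengths(lapply(sets, unique))
  dice <- 2 * inter / outer(sizes, sizes, `+`)
  dimnames(dice) <- list(ids, ids)
  dice
}

#' Remove redundant pathways by pairwise Sorensen-Dice overlap
#'
#' Repeatedly finds the pair of surviving pathways with the largest
#' overlap strictly above `threshold` and removes the one with fewer
#' genes, recomputing until no pair exceeds the threshold (greedy by
#' worst pair, deterministic).  Ties on overlap are resolved toward the
#' lexicographically earliest pair key; ties on size remove the
#' lexicographically later pathway id.  The result is independent of the
#' catalog's input order.
#'
#' @param catalog a [PathwayCatalog-class].
#' @param threshold overlap threshold in (0, 1\]; pairs with overlap
#'   strictly greater are resolved (default 0.5, i.e. "> 50% overlap").
#' @return a [FilteredCatalog-class] carrying the removal log and the
#'   mean residual pairwise overlap.
#' @export
filterRedundantPathways <- function(catalog, threshold = 0.5) {
  stopifnot(is(catalog, "PathwayCatalog"),
            threshold > 0, threshold <= 1)
  ## canonical order makes the greedy procedure order-independent
  ord <- order(names(catalog@sets))
  sets <- catalog@sets[ord]
  log <- data.frame(removed = character(), kept = character(),
                    overlap = numeric(), stringsAsFactors = FALSE)
  if (length(sets) >= 2) {
    dice <- .pairwiseDice(sets)
    diag(dice) <- 0
    alive <- rep(TRUE, nrow(dice))
    names(alive) <- rownames(dice)
    sizes <- lengths(lapply(sets, unique))
    repeat {
      d <- dice[alive, alive, drop = FALSE]
      if (max(d) <= threshold) break
      idx <- which(d == max(d), arr.ind = TRUE)
      ## deterministic pair pick: earliest (row, col) names
      pairNames <- cbind(rownames(d)[idx[, 1]], colnames(d)[idx[, 2]])
      key <- paste(pmin(pairNames[, 1], pairNames[, 2]),
                   pmax(pairNames[, 1], pairNames[, 2]))
      pick <- which(key == min(key))[1]
      p1 <- pairNames[pick, 1]; p2 <- pairNames[pick, 2]
      drop <- if (sizes[p1] < sizes[p2]) p1
              else if (sizes[p2] < sizes[p1]) p2
              else max(p1, p2)  # size tie: later id removed
      keep <- setdiff(c(p1, p2), drop)
      log <- rbind(log, data.frame(removed = drop, kept = keep,
                                   overlap = max(d),
                                   stringsAsFactors = FALSE))
      alive[drop] <- FALSE
    }
    sets <- sets[names(alive)[alive]]
  }
  keepIds <- names(sets)
  mean_res <- if (length(sets) >= 2) {
    dd <- .pairwiseDice(sets)
    mean(dd[upper.tri(dd)])
  } else 0
  new("FilteredCatalog",
      sets = sets,
      description = catalog@description[keepIds],
      depth = catalog@depth[keepIds],
      removalLog = log, threshold = threshold,
      meanResidualOverlap = mean_res)
}

#' Map a pathway's genes onto a cell network
#'
#' @param pathwayGenes character vector of a pathway's genes.
#' @param cellnet [CellNetwork-class].
#' @return the pathway genes present in the cell network.
#' @export
mapPathwayToNetwork <- function(pathwayGenes, cellnet) {
  stopifnot(is(cellnet, "CellNetwork"))
  intersect(unique(pathwayGenes), genes(cellnet))
}

#' Connectivity of a pathway within a cell network
#'
#' The quantitative definition of pathway connectivity inside a cell
#' network is implementation-defined here; two natural candidates are
#' emitted side by side: the number of cell-network edges internal to
#' the pathway, and the fraction of in-network pathway genes having at
#' least one such internal edge.
#'
#' @param pathwayGenes character vector of a pathway's genes.
#' @param cellnet [CellNetwork-class].
#' @return list with `nEdgesWithin` (integer) and `fractionConnected`
#'   (numeric in \[0, 1\]; 0 when no pathway gene is in the network).
#' @export
pathwayConnectivity <- function(pathwayGenes, cellnet) {
  inNet <- mapPathwayToNetwork(pathwayGenes, cellnet)
  if (length(inNet) == 0)
    return(list(nEdgesWithin = 0L, fractionConnected = 0))
  sub <- igraph::induced_subgraph(cellnet@graph, inNet)
  nE <- igraph::ecount(sub)
  frac <- if (length(inNet) == 0) 0 else
    sum(igraph::degree(sub) > 0) / length(inNet)
  list(nEdgesWithin = as.integer(nE), fractionConnected = frac)
}

#' Association test between two pathway catalogs
#'
#' For every pair (pathway in `catA`, pathway in `catB`), a one-sided
#' Fisher's exact test of gene-set overlap over the shared universe,
#' with Benjamini-Hochberg adjustment across all pairs.  The log odds
#' ratio is reported with the Haldane-Anscombe 0.5 correction whenever a
#' table cell is zero.
#'
#' @param catA,catB [PathwayCatalog-class] objects (restricted to the
#'   universe).
#' @param universe character vector of background genes.
#' @return data.frame with columns `pathwayA`, `pathwayB`, `n_overlap`,
#'   `odds_ratio`, `log_odds_ratio`, `p_value`, `p_adjusted`.
#' @export
catalogAssociation <- function(catA, catB, universe) {
  stopifnot(is(catA, "PathwayCatalog"), is(catB, "PathwayCatalog"))
  N <- length(universe)
  rows <- list()
  for (pa in names(catA@sets)) {
    A <- intersect(catA@sets[[pa]], universe)
    for (pb in names(catB@sets)) {
      B <- intersect(catB@sets[[pb]], universe)
      k <- length(intersect(A, B))
      p <- hypergeomTailP(k, length(A), length(B), N)
      a <- k; b <- length(A) - k; cc <- length(B) - k
      dd <- N - length(A) - length(B) + k
      if (any(c(a, b, cc, dd) == 0)) {
        a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; dd <- dd + 0.5
      }
      or <- (a * dd) / (b * cc)
      rows[[length(rows) + 1L]] <- data.frame(
        pathwayA = pa, pathwayB = pb, n_overlap = k, odds_ratio = or,
        log_odds_ratio = log(or), p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
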