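# shared fixtures and independent oracles, built in code

# write an edge list to a temp file and read it back as a network
netFromEdges <- function(edges, ...) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(vapply(edges, function(e)
    paste(e, collapse = "\t"), character(1)), f)
  readEdgeList(f, ...)
}

# cell network over all genes of an edge set
cellNetFromEdges <- function(edges, cellType = "CT") {
  net <- netFromEdges(edges)
  suppressWarnings(induceCellNetwork(net, genes(net), cellType))
}

# expression SummarizedExperiment from a named row list
seFromRows <- function(rows, cellTypes = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(cellTypes)) cellTypes <- paste0("ct", seq_len(ncol(m)))
  colnames(m) <- cellTypes
  makeExpressionSE(m)
}

# brute-force one-sided hypergeometric tail by combinatorial enumeration
# (independent of stats::phyper): P(X >= k), X ~ Hyper(N, K, n)
bruteTailP <- function(k, K, n, N) {
  js <- max(k, 0):min(K, n)
  js <- js[n - js <= N - K]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# bitmask subset helpers for set-overlap oracles
maskToSet <- function(mask, universe) universe[
  bitwAnd(mask, bitwShiftL(1L, seq_along(universe) - 1L)) != 0L]

popcount <- function(x) {
  n <- 0L
  while (any(x > 0)) { n <- n + (x %% 2L); x <- x %/% 2L }
  n
}

# tiny adjacency-based BFS distances (oracle for propagation ordering)
bfsDist <- function(adj, src) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[src] <- 0; q <- src
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (u in which(adj[v, ] != 0)) if (is.infinite(d[u])) {
      d[u] <- d[v] + 1; q <- c(q, u)
    }
  }
  d
}

# adjacency matrices of standard small graphs
pathAdj <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) { a[i, i + 1] <- 1; a[i + 1, i] <- 1 }
  a
}
cycleAdj <- function(n) {
  a <- pathAdj(n); a[1, n] <- 1; a[n, 1] <- 1
  a
}
starAdj <- function(nLeaves) {
  n <- nLeaves + 1
  a <- matrix(0, n, n)
  a[1, 2:n] <- 1; a[2:n, 1] <- 1
  a
}
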