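test_that("propagation is deterministic and orders a path by seed distance", {
  cn <- cellNetFromEdges(list(c("a", "b"), c("b", "c"), c("c", "d")))
  g1 <- propagateScores(cn, "a", "dis")
  g2 <- propagateScores(cn, "a", "dis")
  expect_identical(scores(g1), scores(g2))
  s <- scores(g1)[c("a", "b", "c", "d")]
  expect_true(all(diff(s) < 0))  # strictly decreasing with distance
  expect_equal(unname(s["a"]), 1)

  # empty seed set -> all scores zero
  z <- propagateScores(cn, character(0), "dis")
  expect_true(all(scores(z) == 0))
  # seeds outside the network are counted but do not score
  out <- propagateScores(cn, c("a", "zz"), "dis")
  expect_equal(out@params$nSeedsInNetwork, 1L)
  expect_equal(out@params$nSeeds, 2L)

  expect_error(propagateAdjacency(pathAdj(3), 1, repetitions = 0),
               ">= 1")
  expect_error(propagateAdjacency(pathAdj(3), 1, iterations = 0), ">= 1")
})

test_that("symmetric nodes receive identical scores", {
  # star: seeding the hub scores all leaves equally
  s <- propagateAdjacency(starAdj(5), 1)
  expect_equal(length(unique(round(s[-1], 12))), 1L)

  # cycle: rotation equivariance
  n <- 6
  s1 <- propagateAdjacency(cycleAdj(n), 1)
  s3 <- propagateAdjacency(cycleAdj(n), 3)
  rot <- ((seq_len(n) - 1 + 2) %% n) + 1  # shift by 2 positions
  expect_equal(s3[rot], s1, tolerance = 1e-12)

  # path: reflection equivariance
  p1 <- propagateAdjacency(pathAdj(5), 1)
  p5 <- propagateAdjacency(pathAdj(5), 5)
  expect_equal(p5, rev(p1), tolerance = 1e-12)
})

test_that("the rwr substitute scorer also ranks by proximity", {
  cn <- cellNetFromEdges(list(c("a", "b"), c("b", "c"), c("c", "d")))
  s <- scores(propagateScores(cn, "a", "dis", method = "rwr"))
  expect_true(all(diff(s[c("a", "b", "c", "d")]) < 0))
})

test_that("z-standardization uses the population sd and is location-invariant", {
  mk <- function(sc) new("GeneScoreVector", cellType = "c",
                         disease = "d",
                         score = setNames(sc, paste0("g", seq_along(sc))),
                         z = numeric(0), params = list(),
                         degenerate = FALSE)
  z <- zscores(standardizeScores(mk(c(0, 1))))
  expect_equal(unname(z), c(-1, 1))  # population sd = 0.5

  zc <- standardizeScores(mk(rep(0.3, 4)))
  expect_true(all(zscores(zc) == 0))
  expect_true(zc@degenerate)

  base <- zscores(standardizeScores(mk(c(0.1, 0.4, 0.9, 0.2))))
  shifted <- zscores(standardizeScores(mk(c(0.1, 0.4, 0.9, 0.2) + 5)))
  expect_equal(shifted, base, tolerance = 1e-12)

  # mean 0, unit population sd over the network's genes
  set.seed(3)
  zr <- zscores(standardizeScores(mk(runif(50))))
  expect_equal(mean(zr), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(zr^2)), 1, tolerance = 1e-12)

  expect_error(standardizeScores(mk(0.5)), "at least 2")
})

test_that("top-scoring selection thresholds z and shrinks as the cutoff rises", {
  gsv <- new("GeneScoreVector", cellType = "c", disease = "d",
             score = setNames(c(0.9, 0.5, 0.1), paste0("g", 1:3)),
             z = setNames(c(3.1, 0.2, -1.0), paste0("g", 1:3)),
             params = list(), degenerate = FALSE)
  expect_equal(topGenes(selectTopScoring(gsv, 2.0)), "g1")
  expect_setequal(topGenes(selectTopScoring(gsv, -Inf)),
                  paste0("g", 1:3))
  for (cut in c(-1, 0, 1, 2, 3)) {
    lo <- topGenes(selectTopScoring(gsv, cut))
    hi <- topGenes(selectTopScoring(gsv, cut + 0.5))
    expect_true(all(hi %in% lo))
  }
  noz <- new("GeneScoreVector", cellType = "c", disease = "d",
             score = c(g1 = 1), z = numeric(0), params = list(),
             degenerate = FALSE)
  expect_error(selectTopScoring(noz), "z not filled")
})

test_that("top-set size varies across degree-matched random seed draws", {
  set.seed(8)
  net <- generateInteractome(300, 8, seed = 8)
  cn <- suppressWarnings(induceCellNetwork(net, genes(net), "all"))
  adj <- multimorbinet:::.adjacency(cn)
  seedIdx <- sample(nodeCount(cn), 10)
  seedMat <- multimorbinet:::.degreeMatchedSeeds(rowSums(adj), seedIdx,
                                                 60)
  S <- multimorbinet:::.topSetMatrix(adj, seedMat, 3L, 2L, 0.25,
                                     "netscore", 2.0)
  sizes <- colSums(S)
  expect_gt(sd(sizes), 0)  # the PS null needs a non-degenerate |S|
})
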