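test_that("Sorensen-Dice overlap behaves as a set-similarity index", {
  a <- letters[1:6]
  expect_equal(sorensenDice(a, a), 1)
  expect_equal(sorensenDice(a, LETTERS[1:5]), 0)
  b <- c("a", sprintf("x%02d", 1:46))  # |B| = 47, shares only "a"
  expect_equal(sorensenDice(a, b), 2 / 53)
  expect_equal(sorensenDice(a, b), sorensenDice(b, a))
  expect_equal(sorensenDice(c("a", "a", "b"), c("a", "b")), 1) # dedupe
  expect_error(sorensenDice(character(), character()), "undefined")
})

test_that("depth selection keeps exactly the requested hierarchy level", {
  cat1 <- new("PathwayCatalog",
              sets = list(P1 = "a", P2 = "b", P3 = c("c", "d"), P4 = "e"),
              description = setNames(rep("", 4), paste0("P", 1:4)),
              depth = setNames(c(1L, 2L, 3L, 3L), paste0("P", 1:4)))
  expect_setequal(pathwayIds(selectDepth(cat1, 3)), c("P3", "P4"))
  expect_equal(pathwayIds(selectDepth(cat1, 1)), "P1")
  expect_error(selectDepth(cat1, 7), "no pathway at depth")

  noH <- new("PathwayCatalog", sets = list(P = "a"),
             description = c(P = ""), depth = c(P = NA_integer_))
  expect_error(selectDepth(noH, 3), "no hierarchy")
})

test_that("redundancy filtering removes the smaller of overlapping pairs", {
  mk <- function(sets) new("PathwayCatalog", sets = sets,
                           description = setNames(rep("", length(sets)),
                                                  names(sets)),
                           depth = setNames(rep(NA_integer_,
                                                length(sets)),
                                            names(sets)))
  # overlap 2*3/(4+3) = 6/7 > 0.5 -> smaller P2 removed
  f1 <- filterRedundantPathways(mk(list(P1 = letters[1:4],
                                        P2 = letters[1:3])))
  expect_equal(pathwayIds(f1), "P1")
  expect_equal(removalLog(f1)$removed, "P2")
  expect_equal(removalLog(f1)$overlap, 6 / 7, tolerance = 1e-12)

  # disjoint -> both kept
  f2 <- filterRedundantPathways(mk(list(P1 = c("a", "b"),
                                        P2 = c("x", "y"))))
  expect_setequal(pathwayIds(f2), c("P1", "P2"))

  # boundary: overlap exactly 0.5 is NOT removed (strict inequality)
  f3 <- filterRedundantPathways(mk(list(P1 = c("a", "b"),
                                        P2 = c("a", "c"))))
  expect_setequal(pathwayIds(f3), c("P1", "P2"))

  # size tie: lexicographically later id removed
  f4 <- filterRedundantPathways(mk(list(Q = c("a", "b", "c"),
                                        B = c("a", "b", "c"))))
  expect_equal(pathwayIds(f4), "B")
  expect_equal(removalLog(f4)$removed, "Q")
})

test_that("redundancy filtering is order-independent and bounds residual overlap", {
  set.seed(21)
  pool <- sprintf("g%02d", 1:40)
  sets <- lapply(1:12, function(i) sample(pool, sample(5:15, 1)))
  names(sets) <- sprintf("P%02d", 1:12)
  mk <- function(s) new("PathwayCatalog", sets = s,
                        description = setNames(rep("", length(s)),
                                               names(s)),
                        depth = setNames(rep(NA_integer_, length(s)),
                                         names(s)))
  ref <- filterRedundantPathways(mk(sets), 0.4)
  for (i in 1:5) {
    shuffled <- sets[sample(length(sets))]
    expect_setequal(pathwayIds(filterRedundantPathways(mk(shuffled), 0.4)),
                    pathwayIds(ref))
  }
  surv <- geneSets(ref)
  if (length(surv) >= 2) {
    pairs <- combn(length(surv), 2)
    maxOv <- max(apply(pairs, 2, function(ij)
      sorensenDice(surv[[ij[1]]], surv[[ij[2]]])))
    expect_lte(maxOv, 0.4)
    expect_equal(ref@meanResidualOverlap,
                 mean(apply(pairs, 2, function(ij)
                   sorensenDice(surv[[ij[1]]], surv[[ij[2]]]))))
  }
})

test_that("pathway-to-network mapping and connectivity are computed on the induced subgraph", {
  cn <- cellNetFromEdges(list(c("a", "b"), c("b", "c"), c("c", "a"),
                              c("c", "d")))
  expect_setequal(mapPathwayToNetwork(c("a", "b", "zz"), cn), c("a", "b"))
  expect_equal(mapPathwayToNetwork(c("q", "r"), cn), character(0))
  expect_setequal(mapPathwayToNetwork(c("a", "d"), cn), c("a", "d"))

  pc <- pathwayConnectivity(c("a", "b", "d"), cn)
  expect_equal(pc$nEdgesWithin, 1L)          # only a-b internal
  expect_equal(pc$fractionConnected, 2 / 3)  # d has no internal edge

  expect_equal(pathwayConnectivity(c("b", "d"), cn),
               list(nEdgesWithin = 0L, fractionConnected = 0))

  clique <- pathwayConnectivity(c("a", "b", "c"), cn)
  expect_equal(clique$nEdgesWithin, 3L)
  expect_equal(clique$fractionConnected, 1)
})

test_that("catalog association tests overlap with Haldane-Anscombe-corrected LOR", {
  universe <- sprintf("u%02d", 1:50)
  mk <- function(s) new("PathwayCatalog", sets = s,
                        description = setNames(rep("", length(s)),
                                               names(s)),
                        depth = setNames(rep(NA_integer_, length(s)),
                                         names(s)))
  A <- mk(list(pa = universe[1:5]))
  B <- mk(list(pb = universe[1:5], pc = universe[40:44]))
  res <- catalogAssociation(A, B, universe)
  ident <- res[res$pathwayB == "pb", ]
  expect_equal(ident$p_value, bruteTailP(5, 5, 5, 50), tolerance = 1e-12)
  disj <- res[res$pathwayB == "pc", ]
  expect_equal(disj$p_value, 1)
  expect_true(is.finite(disj$log_odds_ratio))  # 0.5-corrected zero cell
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
})
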