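test_that("multimorbidity scores are generalized Sorensen-Dice overlaps", {
  s6 <- as.character(1:6)
  s47 <- as.character(6:52)  # shares exactly "6"
  expect_equal(multimorbidityScore(list(s6, s47)), 2 / 53)

  same <- letters[1:5]
  expect_equal(multimorbidityScore(list(same, same, same)), 1)
  expect_equal(multimorbidityScore(list(letters[1:3], letters[4:6],
                                        letters[7:9])), 0)

  # empty set -> 0 with degeneracy flag
  msE <- multimorbidityScore(list(character(0), letters[1:3]))
  expect_equal(as.numeric(msE), 0)
  expect_true(attr(msE, "degenerate"))

  # symmetry under reordering
  expect_equal(multimorbidityScore(list(s6, s47)),
               multimorbidityScore(list(s47, s6)))

  # nested sets: MS = 2|S1|/(|S1|+|S2|), the maximum for that size
  s1 <- letters[1:4]; s2 <- letters[1:10]
  expect_equal(multimorbidityScore(list(s1, s2)), 8 / 14)
  for (i in 1:20) {
    other <- sample(letters, 4)
    expect_lte(multimorbidityScore(list(other, s2)), 8 / 14)
  }

  # mean-pairwise variant for triples
  t1 <- letters[1:4]; t2 <- letters[3:6]; t3 <- letters[5:8]
  mp <- mean(c(sorensenDice(t1, t2), sorensenDice(t1, t3),
               sorensenDice(t2, t3)))
  expect_equal(multimorbidityScore(list(t1, t2, t3),
                                   variant = "mean-pairwise"), mp)

  # consistent relabeling leaves MS unchanged
  relab <- function(s) paste0("X_", s)
  expect_equal(multimorbidityScore(list(relab(s6), relab(s47))),
               multimorbidityScore(list(s6, s47)))
})

test_that("MS rejects top sets from different cell types", {
  mkTop <- function(ct, genes) new("TopScoringSet", cellType = ct,
                                   disease = "d", genes = genes,
                                   rule = "z >= 2", cutoff = 2,
                                   networkSize = 100L)
  expect_error(multimorbidityScore(list(mkTop("c1", letters[1:3]),
                                        mkTop("c2", letters[2:4]))),
               "different cell types")
  expect_equal(multimorbidityScore(list(mkTop("c1", letters[1:3]),
                                        mkTop("c1", letters[2:4]))),
               2 * 2 / 6)
})

test_that("the degree-matched MS permutation test uses the add-one estimator", {
  set.seed(31)
  net <- generateInteractome(200, 8, seed = 31)
  cn <- suppressWarnings(induceCellNetwork(net, genes(net), "all"))
  g <- genes(cn)
  seeds <- list(D1 = sample(g, 8), D2 = sample(g, 8))

  # impossible observed MS -> estimator floor 1/(1+n)
  r <- msPermutationTest(cn, seeds, observedMS = 2, nPerm = 99,
                         seed = 1)
  expect_equal(r$p, 1 / 100)
  # observed below every permutation -> p = 1
  r2 <- msPermutationTest(cn, seeds, observedMS = -1, nPerm = 99,
                          seed = 1)
  expect_equal(r2$p, 1)

  r3 <- msPermutationTest(cn, seeds, nPerm = 50, seed = 7)
  expect_gt(r3$p, 0)
  expect_lte(r3$p, 1)
  expect_length(r3$permMS, 50)
  expect_true(all(r3$permMS >= 0 & r3$permMS <= 1))

  expect_error(msPermutationTest(cn, seeds, nPerm = 10),
               "seed is mandatory")
  expect_error(msPermutationTest(cn, list(D1 = "zzz", D2 = g[1]),
                                 nPerm = 10, seed = 1),
               "seed inside the cell network")
})

test_that("permutation is reproducible under a fixed seed", {
  set.seed(77)
  net <- generateInteractome(150, 6, seed = 77)
  cn <- suppressWarnings(induceCellNetwork(net, genes(net), "all"))
  g <- genes(cn)
  seeds <- list(A = sample(g, 6), B = sample(g, 6))
  a <- msPermutationTest(cn, seeds, nPerm = 30, seed = 123)
  b <- msPermutationTest(cn, seeds, nPerm = 30, seed = 123)
  expect_identical(a$permMS, b$permMS)
  expect_identical(a$p, b$p)
})

test_that("the MS table covers pairs and the triple per cell type", {
  scen <- generateScenario(seed = 314)
  r <- restrictToCommonUniverse(scen@network, scen@expression,
                                scen@diseases, scen@pathways)
  norm <- suppressMessages(normalizeExpression(r$expression))
  calls <- callSpecificGenes(norm)
  cns <- lapply(c("CT1", "CT3"), function(ct)
    suppressWarnings(induceCellNetwork(
      r$network, intersect(specificGenes(calls)[[ct]],
                           genes(r$network)), ct)))
  tab <- multimorbidityTable(cns, r$diseases, nPerm = 0)
  expect_setequal(unique(tab$combination),
                  c("D1+D2", "D1+D3", "D2+D3", "D1+D2+D3"))
  expect_equal(nrow(tab), 8L)
  expect_true(all(tab$MS >= 0 & tab$MS <= 1))
  # planted multimorbid cell type outranks a background one
  expect_gt(max(tab$MS[tab$cell_type == "CT1"]),
            max(tab$MS[tab$cell_type == "CT3"]))
})
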