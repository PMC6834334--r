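test_that("synthetic interactomes are connected, sized and reproducible", {
  net <- generateInteractome(100, 4, seed = 1)
  expect_equal(nodeCount(net), 100L)
  expect_true(igraph::is_connected(asIgraph(net)))
  expect_gt(edgeCount(net), 150)
  expect_lt(edgeCount(net), 250)

  net2 <- generateInteractome(100, 4, seed = 1)
  expect_identical(edgeTable(net2), edgeTable(net))

  dense <- generateInteractome(10, 9, seed = 2)
  expect_gt(igraph::edge_density(asIgraph(dense)), 0.5)

  cfgNet <- generateInteractome(120, 6, model = "configuration",
                                seed = 3)
  expect_true(igraph::is_connected(asIgraph(cfgNet)))
  expect_false(igraph::any_multiple(asIgraph(cfgNet)))

  expect_error(generateInteractome(5, 2, seed = 1), ">= 10")
  expect_error(generateInteractome(50, 50, seed = 1), "infeasible")
  expect_error(generateInteractome(50, 5), "seed is mandatory")
})

test_that("planted specific genes are recovered by the IQR rule at the default effect", {
  net <- generateInteractome(500, 10, seed = 1)
  ex <- generateExpression(net, paste0("CT", 1:8), fracSpecific = 0.1,
                           seed = 1)
  norm <- suppressMessages(normalizeExpression(ex$expression))
  calls <- callSpecificGenes(norm)
  sens <- fp <- c()
  for (ct in names(ex$specificSets)) {
    pl <- intersect(ex$specificSets[[ct]], rownames(norm))
    got <- specificGenes(calls)[[ct]]
    sens <- c(sens, mean(pl %in% got))
    fp <- c(fp, mean(setdiff(rownames(norm), pl) %in% got))
  }
  expect_gte(mean(sens), 0.95)
  expect_lte(mean(fp), 0.05)

  # zero effect: planted recovery collapses to the false-positive rate
  ex0 <- generateExpression(net, paste0("CT", 1:8), fracSpecific = 0.1,
                            specificityEffect = 0, seed = 1)
  norm0 <- suppressMessages(normalizeExpression(ex0$expression))
  calls0 <- callSpecificGenes(norm0)
  rec0 <- mean(unlist(lapply(names(ex0$specificSets), function(ct)
    intersect(ex0$specificSets[[ct]], rownames(norm0)) %in%
      specificGenes(calls0)[[ct]])))
  expect_lt(rec0, 0.15)

  # near-noiseless limit: every planted pair recovered
  exQ <- generateExpression(net, paste0("CT", 1:8), fracSpecific = 0.1,
                            noiseScale = 0.01, seed = 1)
  normQ <- suppressMessages(normalizeExpression(exQ$expression))
  callsQ <- callSpecificGenes(normQ)
  recQ <- mean(unlist(lapply(names(exQ$specificSets), function(ct)
    intersect(exQ$specificSets[[ct]], rownames(normQ)) %in%
      specificGenes(callsQ)[[ct]])))
  expect_gte(recQ, 0.995)
  # genes planted in a single cell type are recovered without exception
  cnt <- table(unlist(exQ$specificSets))
  rec1 <- unlist(lapply(names(exQ$specificSets), function(ct) {
    pl <- exQ$specificSets[[ct]]
    pl <- intersect(pl[cnt[pl] == 1], rownames(normQ))
    pl %in% specificGenes(callsQ)[[ct]]
  }))
  expect_equal(mean(rec1), 1)
})

test_that("disease modules are connected with controllable overlap", {
  net <- generateInteractome(300, 8, seed = 4)
  g <- asIgraph(net)

  # modules induce connected subgraphs across many seeds
  for (sd in 1:20) {
    dm <- generateDiseaseModules(net, 3, 10, 0.3, seed = sd)
    for (mod in dm$modules$sets)
      expect_true(igraph::is_connected(
        igraph::induced_subgraph(g, mod)))
    expect_equal(lengths(dm$modules$sets), c(D1 = 10L, D2 = 10L,
                                             D3 = 10L))
  }

  disj <- generateDiseaseModules(net, 3, 10, 0, seed = 5)
  sets <- geneSets(disj$diseases)
  expect_equal(length(Reduce(intersect, sets)), 0L)
  expect_equal(length(intersect(sets$D1, sets$D2)), 0L)

  ident <- generateDiseaseModules(net, 3, 10, 1, seed = 6)
  sets1 <- geneSets(ident$diseases)
  expect_equal(sets1$D1, sets1$D2)
  expect_equal(sets1$D2, sets1$D3)

  mid <- generateDiseaseModules(net, 2, 10, 0.4, seed = 7)
  expect_equal(sorensenDice(mid$modules$sets$D1, mid$modules$sets$D2),
               0.4)

  expect_error(generateDiseaseModules(net, 3, 200, 0, seed = 1),
               "larger than the graph")
})

test_that("pathway generation plants recoverable structure", {
  net <- generateInteractome(300, 8, seed = 9)
  dm <- generateDiseaseModules(net, 2, 12, 0.5, seed = 9)
  pw <- generatePathways(net, nPathways = 9, sizeRange = c(6, 12),
                         plantedInModules = list(m1 = dm$modules$sets$D1),
                         redundancyPairs = 2, seed = 9)
  cat1 <- pw$pathways

  # planted pathway sits inside its module
  pl <- pw$truth$planted
  expect_length(pl, 1L)
  expect_true(all(geneSets(cat1)[[pl]] %in% dm$modules$sets$D1))

  # each constructed redundant pair is resolved down to one survivor
  filt <- filterRedundantPathways(cat1, 0.5)
  for (pair in pw$truth$redundantPairs) {
    expect_true(pair[["removed"]] %in% removalLog(filt)$removed)
    expect_true(pair[["kept"]] %in% pathwayIds(filt))
  }

  # depth labels cycle over 1,2,3: selecting 3 keeps that third
  bg <- depths(cat1)[startsWith(pathwayIds(cat1), "BG")]
  expect_equal(as.vector(table(bg)), c(3L, 3L, 3L))
  expect_true(all(depths(selectDepth(cat1, 3)) == 3L))
})

test_that("scenario generation is deterministic and writes a complete file set", {
  outDir <- withr::local_tempdir()
  scen <- generateScenario(seed = 55, outDir = outDir)
  files <- c("interactome.tsv", "expr.tsv", "disease_genes.tsv",
             "pathways.gmt", "hierarchy.tsv", "truth.json")
  expect_true(all(file.exists(file.path(outDir, files))))

  outDir2 <- withr::local_tempdir()
  scen2 <- generateScenario(seed = 55, outDir = outDir2)
  for (f in files)
    expect_identical(readLines(file.path(outDir, f)),
                     readLines(file.path(outDir2, f)),
                     info = f)

  tr <- groundTruth(scen)
  expect_length(tr$multimorbidCellTypes, 2L)
  expect_true(all(unlist(tr$modules$sets) %in% genes(scen@network)))

  # null configuration plants nothing
  nul <- generateScenario(scenarioConfig(diseaseModel = "random"),
                          seed = 56)
  trN <- groundTruth(nul)
  expect_length(trN$multimorbidCellTypes, 0L)
  expect_length(trN$plantedPathways, 0L)
  expect_equal(trN$effect$pairwiseOverlap, 0)

  expect_error(generateScenario(seed = 1,
                                config = scenarioConfig(bogus = 1)),
               "unknown configuration field")
})

test_that("raising planted module overlap raises recovered MS", {
  levels <- c(0, 0.2, 0.4, 0.6, 0.8)
  reps <- 6
  msOf <- function(ov, sd) {
    scen <- generateScenario(scenarioConfig(pairwiseOverlap = ov,
                                            nDiseases = 2L),
                             seed = sd)
    r <- restrictToCommonUniverse(scen@network, scen@expression,
                                  scen@diseases, scen@pathways)
    norm <- suppressMessages(normalizeExpression(r$expression))
    calls <- callSpecificGenes(norm)
    ct <- groundTruth(scen)$multimorbidCellTypes[1]
    cn <- suppressWarnings(induceCellNetwork(
      r$network, intersect(specificGenes(calls)[[ct]],
                           genes(r$network)), ct))
    tab <- multimorbidityTable(list(cn), r$diseases, nPerm = 0)
    tab$MS[tab$combination == "D1+D2"]
  }
  mean_ms <- vapply(levels, function(ov)
    mean(vapply(seq_len(reps), function(i)
      msOf(ov, 9000 + i), numeric(1))), numeric(1))
  expect_gt(cor(levels, mean_ms, method = "spearman"), 0)
  expect_gt(mean_ms[5], mean_ms[1])
})
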