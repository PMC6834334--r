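test_that("edge lists are deduplicated, self-loops dropped, lines validated", {
  expect_message(net <- netFromEdges(list(c("a", "b"), c("b", "a"),
                                          c("c", "c"))),
                 "self-loop")
  expect_setequal(genes(net), c("a", "b"))
  expect_equal(edgeCount(net), 1L)

  empty <- netFromEdges(list())
  expect_equal(nodeCount(empty), 0L)
  expect_equal(edgeCount(empty), 0L)

  chain <- netFromEdges(list(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_equal(nodeCount(chain), 4L)
  expect_equal(edgeCount(chain), 3L)

  f <- withr::local_tempfile()
  writeLines(c("a\tb", "lonely"), f)
  expect_error(readEdgeList(f), "line 2")

  writeLines(c("a\tbinds\tb", "b\tbinds\tc"), f)
  sif <- readEdgeList(f, dialect = "sif")
  expect_equal(edgeCount(sif), 2L)
  expect_setequal(genes(sif), c("a", "b", "c"))

  # whitespace trimming
  writeLines(c(" a \t b "), f)
  expect_setequal(genes(readEdgeList(f)), c("a", "b"))
})

test_that("network merging takes unions, tags sources, and is idempotent", {
  n1 <- netFromEdges(list(c("a", "b")), source = "one")
  n2 <- netFromEdges(list(c("a", "b"), c("b", "c")), source = "two")
  m <- mergeNetworks(list(n1, n2))
  tab <- edgeTable(m)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$sources[tab$from == "a" & tab$to == "b"], "one;two")

  d1 <- netFromEdges(list(c("a", "b")))
  d2 <- netFromEdges(list(c("x", "y"), c("y", "z")))
  expect_equal(edgeCount(mergeNetworks(list(d1, d2))), 3L)

  self <- mergeNetworks(list(n2, n2))
  expect_setequal(genes(self), genes(n2))
  expect_equal(edgeCount(self), edgeCount(n2))

  # commutativity on node/edge sets
  ab <- mergeNetworks(list(n1, n2))
  ba <- mergeNetworks(list(n2, n1))
  expect_setequal(genes(ab), genes(ba))
  eab <- edgeTable(ab); eba <- edgeTable(ba)
  expect_setequal(paste(eab$from, eab$to), paste(eba$from, eba$to))
})

test_that("GMT parsing collapses duplicates and validates structure", {
  f <- withr::local_tempfile()
  writeLines(c("P1\tdesc\ta\tb\ta", "P2\tdesc\tb\tc"), f)
  cat1 <- readGmt(f)
  expect_setequal(geneSets(cat1)$P1, c("a", "b"))
  expect_setequal(geneSets(cat1)$P2, c("b", "c"))
  expect_true(all(is.na(depths(cat1))))

  writeLines(c("P1\td\ta", "P1\td\tb"), f)
  expect_error(readGmt(f), "duplicate pathway id")

  writeLines(c("P1\tonly-desc"), f)
  expect_error(readGmt(f), "fewer than 3")

  writeLines(c("P1\td\ta\tb", "P2\td\tc"), f)
  h <- withr::local_tempfile()
  writeLines(c("pathway\tparent\tdepth", "P1\tROOT\t3"), h)
  cat2 <- readGmt(f, hierarchy = h)
  expect_equal(unname(depths(cat2)["P1"]), 3L)
  expect_true(is.na(depths(cat2)["P2"]))
})

test_that("gene-disease tables collapse sources and flag GWAS-only evidence", {
  f <- withr::local_tempfile()
  writeLines(c("gene\tdisease\tevidence",
               "g1\tA\tcurated", "g1\tA\tgwas",
               "g1\tD\tgwas", "g2\tA\texperimental"), f)
  ds <- readGeneDiseaseTable(f)
  expect_setequal(geneSets(ds)$A, c("g1", "g2"))
  expect_equal(geneSets(ds)$D, "g1")  # shared gene in both sets
  expect_equal(unname(evidenceFlags(ds)["A"]), "all")
  expect_equal(unname(evidenceFlags(ds)["D"]), "gwas-only")

  gw <- readGeneDiseaseTable(f, gwasOnly = TRUE)
  expect_equal(geneSets(gw)$A, "g1")

  writeLines(c("gene\tdisease\tevidence", "g1\tA\thearsay"), f)
  expect_error(readGeneDiseaseTable(f), "unknown evidence token")

  writeLines("gene\tdisease\tevidence", f)
  expect_length(geneSets(readGeneDiseaseTable(f)), 0L)
})

test_that("expression matrices reject duplicates and drop non-numeric genes", {
  f <- withr::local_tempfile()
  writeLines(c("gene\tct1\tct2", "g1\t1\t2", "g2\t3\t4"), f)
  se <- readExpressionMatrix(f)
  expect_equal(dim(se), c(2L, 2L))
  expect_equal(SummarizedExperiment::assay(se)["g2", "ct2"], 4)

  writeLines(c("gene\tliver|ct1\tct2", "g1\t1\t2"), f)
  se2 <- readExpressionMatrix(f)
  cd <- SummarizedExperiment::colData(se2)
  expect_equal(cd$tissue, c("liver", NA))
  expect_equal(cd$cell_type, c("ct1", "ct2"))

  writeLines(c("gene\tct1\tct2", "g1\tNA\t2", "g2\t3\t4"), f)
  expect_message(se3 <- readExpressionMatrix(f), "g1")
  expect_equal(rownames(se3), "g2")

  writeLines(c("gene\tct1\tct2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(readExpressionMatrix(f), "duplicate gene row")
})

test_that("universe restriction intersects all inputs and is idempotent", {
  net <- netFromEdges(list(c("a", "b"), c("b", "c")))
  se <- seFromRows(list(b = c(1, 2), c = c(3, 4), d = c(5, 6)))
  dis <- readGeneDiseaseTable({
    f <- withr::local_tempfile()
    writeLines(c("gene\tdisease\tevidence", "a\tA\tcurated",
                 "b\tA\tcurated"), f)
    f
  })
  gmtF <- withr::local_tempfile()
  writeLines(c("P1\td\tb\tc", "P2\td\tzzz"), gmtF)
  pw <- readGmt(gmtF)

  r <- restrictToCommonUniverse(net, se, dis, pw)
  expect_setequal(r$universe, c("b", "c"))
  expect_equal(geneSets(r$diseases)$A, "b")
  expect_equal(pathwayIds(r$pathways), "P1")  # P2 entirely outside
  expect_equal(r$removed$droppedPathways, "P2")

  # idempotence
  r2 <- restrictToCommonUniverse(r$network, r$expression, r$diseases,
                                 r$pathways)
  expect_equal(r2$universe, r$universe)
  expect_equal(geneSets(r2$diseases), geneSets(r$diseases))
  expect_equal(edgeTable(r2$network), edgeTable(r$network))

  # already-inside inputs pass through unchanged
  net3 <- netFromEdges(list(c("b", "c")))
  r3 <- restrictToCommonUniverse(net3, se[c("b", "c"), ], dis = NULL)
  expect_setequal(r3$universe, c("b", "c"))

  seFar <- seFromRows(list(x = c(1, 2)))
  expect_error(restrictToCommonUniverse(net, seFar), "empty universe")
})

test_that("edge lists and GMT catalogs round-trip through write/read", {
  net <- netFromEdges(list(c("a", "b"), c("b", "c"), c("a", "d")))
  f <- withr::local_tempfile()
  writeEdgeList(net, f, provenance = FALSE)
  back <- readEdgeList(f)
  expect_equal(edgeTable(back), edgeTable(net))
  # second write is byte-identical
  f2 <- withr::local_tempfile()
  writeEdgeList(back, f2, provenance = FALSE)
  expect_identical(readLines(f), readLines(f2))

  gmtF <- withr::local_tempfile()
  writeLines(c("P1\tfirst\ta\tb", "P2\tsecond\tc"), gmtF)
  cat1 <- readGmt(gmtF)
  out <- withr::local_tempfile()
  writeGmt(cat1, out)
  expect_identical(readLines(out), readLines(gmtF))

  # provenance-stamped result tables start with a comment line
  tf <- withr::local_tempfile()
  writeResultTable(data.frame(x = 1), tf, config = list(seed = 1))
  expect_match(readLines(tf)[1], "^# multimorbinet")
})
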