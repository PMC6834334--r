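#' Validate a pipeline run configuration
#'
#' A run configuration names the input files (or a synthetic scenario),
#' the analysis parameters and a mandatory RNG seed.  Numeric
#' parameters are checked against their documented ranges.
#'
#' @param config a list, or path to a YAML file holding one.
#' @return the validated configuration list.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed))
    stop("configuration error: field 'seed' is mandatory")
  defaults <- list(k = 1.5, depth = 3L, overlapThreshold = 0.5,
                   zCutoff = 2.0, repetitions = 3L, iterations = 2L,
                   damping = 0.25, method = "netscore", nPerm = 1000L,
                   alpha = 0.05, psVariant = "printed",
                   gwasOnly = FALSE, useHierarchy = TRUE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  with(config, {
    if (k <= 0) stop("configuration error: k must be positive")
    if (overlapThreshold <= 0 || overlapThreshold > 1)
      stop("configuration error: overlapThreshold must be in (0, 1]")
    if (repetitions < 1 || iterations < 1)
      stop("configuration error: repetitions and iterations must be >= 1")
    if (alpha <= 0 || alpha >= 1)
      stop("configuration error: alpha must be in (0, 1)")
    if (!psVariant %in% c("printed", "overlap"))
      stop("configuration error: unknown psVariant")
  })
  config$seed <- as.integer(config$seed)
  config
}

.stageSeed <- function(seed, stage) {
  (seed + 1000003L * stage) %% 2147480017L
}

#' Run the full multimorbidity pipeline
#'
#' Executes, in order: input loading and universe restriction,
#' normalization, specificity calling, cell-network construction,
#' disease-gene enrichment, pathway depth selection and redundancy
#' filtering, propagation with top-scoring selection, Multimorbidity
#' Scores with permutation tests, Perturbation Scores with mechanism
#' calls, and candidate-gene ranking.  Every stage output is written to
#' `outDir` as a TSV stamped with the configuration hash, and a
#' manifest records each stage with its output file hashes and wall
#' time.  Identical config and seed give identical outputs.
#'
#' @param config list or YAML path, see [validateRunConfig()].  Input
#'   fields: either `scenario` (a [SyntheticScenario-class]) /
#'   `synthetic: TRUE` (generate one from `scenarioOptions`), or file
#'   paths `interactome` (vector of edge lists), `expression`,
#'   `diseaseGenes`, `pathways` (GMT) and optionally `hierarchy`.
#'   `excludePathwayPatterns` (character vector of regexes) drops
#'   matching pathways by id or description before depth selection.
#' @param outDir output directory.
#' @return invisibly, a list with all stage results and the manifest
#'   data.frame.
#' @export
runPipeline <- function(config, outDir = tempfile("multimorbinet_run_")) {
  cfg <- validateRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, outputs) {
    hashes <- if (length(outputs))
      paste(sprintf("%s=%s", basename(outputs),
                    substr(tools::md5sum(outputs), 1, 8)),
            collapse = ";") else ""
    t1 <- proc.time()[["elapsed"]]
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = name, outputs = hashes, wall_s = round(t1 - t0, 3),
      stringsAsFactors = FALSE)
    t0 <<- t1
  }
  fail <- function(name, e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)

  ## 1: inputs + universe restriction
  res <- tryCatch({
    if (!is.null(cfg$scenario) || isTRUE(cfg$synthetic)) {
      scen <- cfg$scenario
      if (is.null(scen))
        scen <- generateScenario(
          scenarioConfig(cfg$scenarioOptions %||% list()),
          seed = .stageSeed(cfg$seed, 0L))
      net <- scen@network; expr <- scen@expression
      dis <- scen@diseases; pw <- scen@pathways
    } else {
      nets <- lapply(cfg$interactome, function(p)
        readEdgeList(p, source = basename(p)))
      net <- mergeNetworks(nets)
      expr <- readExpressionMatrix(cfg$expression)
      dis <- readGeneDiseaseTable(cfg$diseaseGenes,
                                  gwasOnly = isTRUE(cfg$gwasOnly))
      pw <- readGmt(cfg$pathways, hierarchy = cfg$hierarchy)
    }
    restrictToCommonUniverse(net, expr, dis, pw)
  }, error = function(e) fail("inputs", e))
  if (length(res$diseases@sets) == 0)
    fail("inputs", simpleError("no disease set left after restriction"))
  writeEdgeList(res$network, file.path(outDir, "interactome.tsv"),
                config = cfg)
  stage("inputs", file.path(outDir, "interactome.tsv"))

  ## 2: normalization
  norm <- tryCatch(normalizeExpression(res$expression),
                   error = function(e) fail("normalize", e))
  normTab <- data.frame(gene = rownames(norm),
                        SummarizedExperiment::assay(norm, "e"),
                        check.names = FALSE)
  writeResultTable(normTab, file.path(outDir, "normalized.tsv"), cfg)
  stage("normalize", file.path(outDir, "normalized.tsv"))

  ## 3: specificity calls
  calls <- tryCatch(callSpecificGenes(norm, k = cfg$k),
                    error = function(e) fail("specificity", e))
  callTab <- do.call(rbind, lapply(names(calls@calls), function(ct)
    if (length(calls@calls[[ct]]))
      data.frame(cell_type = ct, gene = calls@calls[[ct]],
                 stringsAsFactors = FALSE) else NULL))
  if (is.null(callTab))
    callTab <- data.frame(cell_type = character(), gene = character())
  writeResultTable(callTab, file.path(outDir, "specificity_calls.tsv"),
                   cfg)
  stage("specificity", file.path(outDir, "specificity_calls.tsv"))

  ## 4: cell networks
  cellnets <- tryCatch({
    cts <- names(calls@calls)
    cn <- lapply(cts, function(ct)
      suppressWarnings(induceCellNetwork(
        res$network, intersect(calls@calls[[ct]], genes(res$network)),
        cellType = ct)))
    Filter(function(x) nodeCount(x) > 0, cn)
  }, error = function(e) fail("networks", e))
  netDir <- file.path(outDir, "cell_networks")
  dir.create(netDir, showWarnings = FALSE)
  netFiles <- vapply(cellnets, function(cn) {
    f <- file.path(netDir, paste0(gsub("[^A-Za-z0-9_.-]", "_",
                                       cn@cellType), ".tsv"))
    writeEdgeList(cn, f, config = cfg)
    f
  }, character(1))
  stage("networks", netFiles)

  ## 5: disease-gene enrichment
  enrich <- tryCatch(
    diseaseGeneEnrichment(cellnets, res$diseases, res$universe),
    error = function(e) fail("enrichment", e))
  writeResultTable(enrich, file.path(outDir, "enrichment.tsv"), cfg)
  stage("enrichment", file.path(outDir, "enrichment.tsv"))

  ## 6: pathway catalog filtering
  filtered <- tryCatch({
    pcat <- res$pathways
    ## optional exclusion of pathways by name pattern (e.g. disease-
    ## named signalling pathways); no curated list ships
    if (!is.null(cfg$excludePathwayPatterns)) {
      hit <- Reduce(`|`, lapply(cfg$excludePathwayPatterns, function(p)
        grepl(p, names(pcat@sets)) | grepl(p, pcat@description)))
      if (any(hit))
        pcat <- new("PathwayCatalog", sets = pcat@sets[!hit],
                    description = pcat@description[!hit],
                    depth = pcat@depth[!hit])
    }
    if (isTRUE(cfg$useHierarchy) && !all(is.na(pcat@depth)))
      pcat <- selectDepth(pcat, cfg$depth)
    filterRedundantPathways(pcat, cfg$overlapThreshold)
  }, error = function(e) fail("pathways", e))
  writeGmt(filtered, file.path(outDir, "pathways_filtered.gmt"))
  writeResultTable(filtered@removalLog,
                   file.path(outDir, "pathways_removed.tsv"), cfg)
  stage("pathways", file.path(outDir, c("pathways_filtered.gmt",
                                        "pathways_removed.tsv")))

  ## 7: propagation scores + top-scoring sets
  scored <- tryCatch({
    lapply(cellnets, function(cn) {
      if (nodeCount(cn) < 2) return(NULL)
      g <- genes(cn)
      ds <- names(res$diseases@sets)[vapply(res$diseases@sets,
        function(s) length(intersect(s, g)) > 0, logical(1))]
      if (length(ds) == 0) return(NULL)
      gsvs <- lapply(stats::setNames(ds, ds), function(d)
        standardizeScores(propagateScores(
          cn, res$diseases@sets[[d]], disease = d,
          repetitions = cfg$repetitions, iterations = cfg$iterations,
          damping = cfg$damping, method = cfg$method)))
      list(cellnet = cn, gsvs = gsvs,
           tops = lapply(gsvs, selectTopScoring, zCutoff = cfg$zCutoff))
    })
  }, error = function(e) fail("propagation", e))
  scored <- Filter(Negate(is.null), scored)
  scoreTab <- do.call(rbind, lapply(scored, function(sc)
    do.call(rbind, lapply(sc$gsvs, function(v)
      data.frame(cell_type = v@cellType, disease = v@disease,
                 gene = names(scores(v)), raw_score = unname(scores(v)),
                 z = unname(zscores(v)),
                 in_S = names(scores(v)) %in%
                   topGenes(sc$tops[[v@disease]]),
                 stringsAsFactors = FALSE)))))
  if (is.null(scoreTab))
    scoreTab <- data.frame(cell_type = character())
  writeResultTable(scoreTab, file.path(outDir, "scores.tsv"), cfg)
  stage("propagation", file.path(outDir, "scores.tsv"))

  ## 8: multimorbidity scores + permutation tests
  msTab <- tryCatch(
    multimorbidityTable(cellnets, res$diseases, nPerm = cfg$nPerm,
                        seed = .stageSeed(cfg$seed, 8L),
                        zCutoff = cfg$zCutoff,
                        repetitions = cfg$repetitions,
                        iterations = cfg$iterations,
                        damping = cfg$damping, method = cfg$method),
    error = function(e) fail("multimorbidity", e))
  writeResultTable(msTab, file.path(outDir, "ms.tsv"), cfg)
  stage("multimorbidity", file.path(outDir, "ms.tsv"))

  ## 9: perturbation scores + mechanisms
  psTab <- tryCatch(
    perturbationTable(cellnets, filtered, res$diseases,
                      nPerm = cfg$nPerm,
                      seed = .stageSeed(cfg$seed, 9L),
                      variant = cfg$psVariant, zCutoff = cfg$zCutoff,
                      repetitions = cfg$repetitions,
                      iterations = cfg$iterations,
                      damping = cfg$damping, method = cfg$method),
    error = function(e) fail("perturbation", e))
  mech <- if (is.null(psTab)) NULL else callMechanisms(psTab, cfg$alpha)
  if (!is.null(psTab))
    writeResultTable(psTab, file.path(outDir, "ps.tsv"), cfg)
  if (!is.null(mech))
    writeResultTable(mech, file.path(outDir, "mechanisms.tsv"), cfg)
  stage("perturbation",
        Filter(file.exists, file.path(outDir, c("ps.tsv",
                                                "mechanisms.tsv"))))

  ## 10: candidate genes
  candTab <- tryCatch(
    candidateGeneTable(cellnets, res$diseases, zCutoff = cfg$zCutoff,
                       repetitions = cfg$repetitions,
                       iterations = cfg$iterations,
                       damping = cfg$damping, method = cfg$method),
    error = function(e) fail("candidates", e))
  if (!is.null(candTab))
    writeResultTable(candTab, file.path(outDir, "candidates.tsv"), cfg)
  stage("candidates",
        Filter(file.exists, file.path(outDir, "candidates.tsv")))

  manifest <- do.call(rbind, manifest)
  manifest$config_hash <- configHash(cfg)
  write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(outDir = outDir, config = cfg, manifest = manifest,
                 universe = res$universe, cellnets = cellnets,
                 enrichment = enrich, filteredPathways = filtered,
                 scores = scored, ms = msTab, ps = psTab,
                 mechanisms = mech, candidates = candTab))
}
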