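#' Generate a synthetic interactome
#'
#' Emulates the scale-free-ish topology of curated interactomes.  Under
#' the preferential-attachment model each new gene attaches to
#' `meanDegree / 2` existing genes with probability proportional to
#' degree, giving a connected simple graph with a heavy-tailed degree
#' distribution.  The configuration model draws a power-law-ish degree
#' sequence, simplifies the realized multigraph, and connects stray
#' components with single bridging edges.
#'
#' @param nGenes number of genes (>= 10).
#' @param meanDegree target mean degree (default 10; must be <
#'   `nGenes`).
#' @param model `"preferential-attachment"` (default) or
#'   `"configuration"`.
#' @param seed RNG seed (mandatory: generation is fully reproducible).
#' @return an [InteractionNetwork-class] with genes named
#'   `G0001, G0002, ...`.
#' @export
generateInteractome <- function(nGenes = 500L, meanDegree = 10,
                                model = c("preferential-attachment",
                                          "configuration"),
                                seed) {
  model <- match.arg(model)
  if (missing(seed)) stop("an RNG seed is mandatory")
  if (nGenes < 10) stop("nGenes must be >= 10")
  if (meanDegree >= nGenes)
    stop("infeasible degree sequence: meanDegree must be < nGenes")
  set.seed(seed)
  if (model == "preferential-attachment") {
    m <- max(1L, round(meanDegree / 2))
    g <- igraph::sample_pa(nGenes, m = m, directed = FALSE)
    g <- igraph::simplify(g)
  } else {
    degs <- pmin(nGenes - 1L,
                 pmax(1L, round(stats::rlnorm(
                   nGenes, log(meanDegree) - 0.5, 1))))
    if (sum(degs) %% 2 == 1) degs[1] <- degs[1] + 1L
    g <- igraph::sample_degseq(degs, method = "configuration")
    g <- igraph::simplify(g)
    comp <- igraph::components(g)
    while (comp$no > 1) {
      ## bridge the first two components
      v1 <- which(comp$membership == 1)[1]
      v2 <- which(comp$membership == 2)[1]
      g <- igraph::add_edges(g, c(v1, v2))
      comp <- igraph::components(g)
    }
  }
  igraph::V(g)$name <- sprintf("G%04d", seq_len(nGenes))
  net <- new("InteractionNetwork", graph = g)
  validObject(net)
  net
}

#' Generate a synthetic gene x cell-type expression matrix
#'
#' Per-gene log-normal baseline levels with multiplicative cross-cell-
#' type variation, plus planted cell-type-specific (gene, cell) shifts.
#' The baseline variation follows a scaled arcsine (beta(1/2, 1/2))
#' distribution — a bimodal, bounded, on/off-like profile typical of a
#' broad cross-tissue compendium — under which the 1.5 x IQR rule calls
#' about 5% of unplanted pairs.  Planted pairs are shifted upward by
#' `specificityEffect` multiples of the gene's noise scale; at the
#' default effect size essentially all planted pairs pass the rule.
#'
#' @param net [InteractionNetwork-class] supplying the gene universe.
#' @param cellTypes character vector of cell-type labels (optionally
#'   `"tissue|cell_type"`).
#' @param fracSpecific fraction of genes planted as specific per cell
#'   type, used when `specificSets` is `NULL` (default 0.05).
#' @param specificSets optional named list (cell type -> genes) of
#'   planted specific genes, overriding random sampling.
#' @param specificityEffect planted shift in multiples of the noise
#'   scale (default 6).
#' @param noiseScale half-range of the multiplicative cross-cell-type
#'   variation (default 0.3).
#' @param seed RNG seed (mandatory).
#' @return list with `expression` (SummarizedExperiment, assay
#'   `"exprs"`) and `specificSets` (the planted ground truth).
#' @export
generateExpression <- function(net, cellTypes = paste0("CT", 1:8),
                               fracSpecific = 0.05, specificSets = NULL,
                               specificityEffect = 6, noiseScale = 0.3,
                               seed) {
  if (missing(seed)) stop("an RNG seed is mandatory")
  stopifnot(is(net, "InteractionNetwork"),
            fracSpecific > 0, fracSpecific < 1)
  set.seed(seed)
  gs <- genes(net)
  nG <- length(gs); nC <- length(cellTypes)
  if (is.null(specificSets)) {
    nSpec <- max(1L, round(fracSpecific * nG))
    specificSets <- .sampleSpecificSets(gs, cellTypes, nSpec)
  } else {
    stopifnot(all(names(specificSets) %in% cellTypes),
              all(unlist(specificSets) %in% gs))
    missing <- setdiff(cellTypes, names(specificSets))
    specificSets[missing] <- list(character(0))
    specificSets <- specificSets[cellTypes]
  }
  baseline <- stats::rlnorm(nG, meanlog = 3, sdlog = 0.5)
  eta <- matrix(2 * stats::rbeta(nG * nC, 0.5, 0.5) - 1, nG, nC)
  E <- baseline * (1 + noiseScale * eta)
  dimnames(E) <- list(gs, cellTypes)
  for (ct in cellTypes) {
    idx <- match(specificSets[[ct]], gs)
    if (length(idx))
      E[idx, ct] <- E[idx, ct] +
        baseline[idx] * noiseScale * specificityEffect
  }
  list(expression = makeExpressionSE(E), specificSets = specificSets)
}

## internal: sample per-cell-type specific gene sets such that no gene
## is planted in more than `maxPerGene` cell types.  With quartile-based
## specificity calling, a gene shifted in three or more of eight cell
## types contaminates its own IQR and ceases to look specific anywhere;
## capping the multiplicity keeps planted calls recoverable, and matches
## the biology of marker genes being specific to one or two cell types.
.sampleSpecificSets <- function(genes, cellTypes, nPerCellType,
                                exclude = character(),
                                maxPerGene = 2L) {
  count <- stats::setNames(integer(length(genes)), genes)
  count[exclude] <- maxPerGene  # never picked
  out <- list()
  for (ct in cellTypes) {
    pool <- names(count)[count < maxPerGene]
    pick <- sample(pool, min(nPerCellType, length(pool)))
    count[pick] <- count[pick] + 1L
    out[[ct]] <- pick
  }
  out
}

## internal: grow a connected gene set of a given size from an anchor,
## sampling uniformly from the current neighbourhood frontier and
## avoiding `excluded` genes.  Returns NULL when growth stalls.
.growModule <- function(g, size, anchor, excluded = character()) {
  current <- unique(anchor)
  while (length(current) < size) {
    nb <- igraph::adjacent_vertices(g, current)
    frontier <- setdiff(
      unique(unlist(lapply(nb, names), use.names = FALSE)),
      c(current, excluded))
    if (length(frontier) == 0) return(NULL)
    pick <- frontier[sample.int(length(frontier), 1L)]
    current <- c(current, pick)
  }
  current
}

#' Generate disease modules as connected subgraphs
#'
#' Each disease's associated genes form a connected subgraph grown from
#' a random anchor, emulating the observation that disease genes form
#' connected communities in the interactome.  Pairwise overlap between
#' modules is controlled by a shared connected core:
#' `round(pairwiseOverlap * moduleSize)` genes common to all diseases,
#' so that the Sorensen-Dice overlap between any two modules is
#' approximately `pairwiseOverlap` (0 = disjoint, 1 = identical).
#'
#' @param net [InteractionNetwork-class].
#' @param nDiseases number of diseases (default 3, labelled
#'   `D1, D2, ...`).
#' @param moduleSize genes per disease module (>= 3; default 12).
#' @param pairwiseOverlap target Dice overlap between modules in
#'   \[0, 1\] (default 0.3).
#' @param seed RNG seed (mandatory).
#' @return list with `diseases` (a [DiseaseGeneSets-class]) and
#'   `modules` (ground truth: the planted gene sets plus the shared
#'   core).
#' @export
generateDiseaseModules <- function(net, nDiseases = 3L, moduleSize = 12L,
                                   pairwiseOverlap = 0.3, seed) {
  if (missing(seed)) stop("an RNG seed is mandatory")
  stopifnot(is(net, "InteractionNetwork"), moduleSize >= 3,
            pairwiseOverlap >= 0, pairwiseOverlap <= 1)
  g <- net@graph
  gs <- genes(net)
  if (moduleSize * nDiseases > length(gs))
    stop("modules larger than the graph")
  set.seed(seed)
  coreSize <- round(pairwiseOverlap * moduleSize)
  for (attempt in 1:50) {
    core <- if (coreSize > 0)
      .growModule(g, coreSize, sample(gs, 1)) else character(0)
    if (coreSize > 0 && is.null(core)) next
    modules <- list()
    claimed <- character(0)  # disease-exclusive genes
    ok <- TRUE
    for (d in seq_len(nDiseases)) {
      if (coreSize >= moduleSize) {
        modules[[d]] <- core[seq_len(moduleSize)]
        next
      }
      grown <- NULL
      for (sub in 1:25) {
        anchor <- if (length(core)) core else {
          free <- setdiff(gs, claimed)
          free[sample.int(length(free), 1L)]
        }
        grown <- .growModule(g, moduleSize, anchor, excluded = claimed)
        if (!is.null(grown)) break
      }
      if (is.null(grown)) { ok <- FALSE; break }
      modules[[d]] <- grown
      claimed <- c(claimed, setdiff(grown, core))
    }
    if (ok) break
    modules <- NULL
  }
  if (is.null(modules)) stop("could not grow connected disease modules")
  names(modules) <- paste0("D", seq_len(nDiseases))
  sets <- lapply(modules, sort)
  dis <- new("DiseaseGeneSets", sets = sets,
             evidence = stats::setNames(rep("all", nDiseases),
                                        names(sets)))
  list(diseases = dis,
       modules = list(sets = modules, core = core,
                      pairwiseOverlap = pairwiseOverlap))
}

#' Generate a synthetic pathway catalog
#'
#' Background pathways are random gene sets; planted pathways are drawn
#' inside specified disease modules (so they can be recovered as
#' perturbed mechanisms); redundant pairs are constructed with
#' Sorensen-Dice overlap > 0.5 to exercise the redundancy filter.
#' Background depths cycle over 1, 2, 3; planted pathways and redundant
#' copies are placed at depth 3 (the analysis depth).
#'
#' @param net [InteractionNetwork-class].
#' @param nPathways number of background pathways (default 20).
#' @param sizeRange integer range of background pathway sizes (default
#'   c(8, 25)).
#' @param plantedInModules optional named list of gene sets (e.g.
#'   disease modules or their shared core); one pathway is planted
#'   inside each.
#' @param redundancyPairs number of redundant near-copies to add
#'   (default 2).
#' @param seed RNG seed (mandatory).
#' @return list with `pathways` (a [PathwayCatalog-class]) and `truth`
#'   (planted pathway ids and redundant pair ids).
#' @export
generatePathways <- function(net, nPathways = 20L, sizeRange = c(8L, 25L),
                             plantedInModules = NULL,
                             redundancyPairs = 2L, seed) {
  if (missing(seed)) stop("an RNG seed is mandatory")
  stopifnot(is(net, "InteractionNetwork"))
  set.seed(seed)
  gs <- genes(net)
  sets <- list(); depth <- integer(); descr <- character()
  for (i in seq_len(nPathways)) {
    id <- sprintf("BG%03d", i)
    sz <- sample(seq(sizeRange[1], sizeRange[2]), 1)
    sets[[id]] <- sort(sample(gs, sz))
    depth[id] <- ((i - 1L) %% 3L) + 1L
    descr[id] <- sprintf("background pathway %d", i)
  }
  planted <- character(0)
  if (!is.null(plantedInModules)) {
    for (mi in seq_along(plantedInModules)) {
      id <- sprintf("PL%03d", mi)
      mod <- plantedInModules[[mi]]
      sz <- min(length(mod), max(sizeRange[1], round(length(mod) * 0.8)))
      sets[[id]] <- sort(sample(mod, sz))
      depth[id] <- 3L
      descr[id] <- sprintf("planted pathway in module %s",
                           names(plantedInModules)[mi] %||% mi)
      planted <- c(planted, id)
    }
  }
  redundant <- list()
  if (redundancyPairs > 0) {
    basis <- sample(names(sets)[startsWith(names(sets), "BG")],
                    min(redundancyPairs, nPathways))
    for (ri in seq_along(basis)) {
      id <- sprintf("RD%03d", ri)
      base <- sets[[basis[ri]]]
      ## strict subset of ~80% of the genes: Dice = 2*0.8/(1.8) ~ 0.89
      sub <- sort(sample(base, max(2L, round(length(base) * 0.8))))
      sets[[id]] <- sub
      depth[id] <- depth[[basis[ri]]]
      descr[id] <- sprintf("redundant copy of %s", basis[ri])
      redundant[[ri]] <- c(kept = basis[ri], removed = id)
    }
  }
  cat <- new("PathwayCatalog", sets = sets, description = descr,
             depth = depth)
  list(pathways = cat,
       truth = list(planted = planted, redundantPairs = redundant))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default synthetic-scenario configuration
#'
#' The generator's default conditions: a 500-gene preferential-
#' attachment interactome of mean degree 10; 8 cell types of which 2
#' are planted as multimorbid; 3 diseases with connected 15-gene
#' modules at pairwise Dice overlap 0.3; 20 background pathways plus
#' one pathway planted in the modules' shared core and 2 redundant
#' pairs.  `diseaseModel = "random"` switches to a null scenario whose
#' seeds are random draws from the network (no planted modules, no
#' planted multimorbidity).
#'
#' @param ... overrides of individual fields.
#' @return named list of configuration values.
#' @export
scenarioConfig <- function(...) {
  cfg <- list(
    nGenes = 500L, meanDegree = 10, model = "preferential-attachment",
    nCellTypes = 8L, nMultimorbid = 2L, fracSpecific = 0.25,
    specificityEffect = 6, noiseScale = 0.3,
    nDiseases = 3L, moduleSize = 12L, pairwiseOverlap = 0.3,
    diseaseModel = "module",
    nPathways = 20L, sizeRange = c(8L, 25L), redundancyPairs = 2L,
    zCutoff = 2.0, repetitions = 3L, iterations = 2L, damping = 0.25,
    k = 1.5, nPerm = 1000L, alpha = 0.05, psVariant = "printed")
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Generate a full synthetic scenario with planted ground truth
#'
#' Composes the interactome, expression, disease-module and pathway
#' generators into one seeded scenario.  In the default (`"module"`)
#' disease model, the disease modules overlap the planted specific-gene
#' sets of `nMultimorbid` designated cell types only, which makes those
#' cell types — and only those — carry the planted multimorbidity
#' signal; one pathway is planted inside the modules' shared core as
#' the recoverable mechanism.  In the `"random"` (null) model the
#' disease seeds are uniform draws from the interactome: no planted
#' specificity overlap, no planted multimorbidity, no planted pathways.
#'
#' @param config list from [scenarioConfig()] (or overrides for it).
#' @param seed RNG seed (mandatory; scenario regeneration from the same
#'   seed is bit-identical).
#' @param outDir optional directory: when given, all standard-format
#'   files (`interactome.tsv`, `expr.tsv`, `disease_genes.tsv`,
#'   `pathways.gmt`, `hierarchy.tsv`) plus `truth.json` are written
#'   there.
#' @return a [SyntheticScenario-class].
#' @export
generateScenario <- function(config = scenarioConfig(), seed,
                             outDir = NULL) {
  if (missing(seed)) stop("an RNG seed is mandatory")
  cfg <- scenarioConfig(config)
  net <- generateInteractome(cfg$nGenes, cfg$meanDegree, cfg$model,
                             seed = seed)
  gs <- genes(net)
  cellTypes <- paste0("CT", seq_len(cfg$nCellTypes))
  if (cfg$diseaseModel == "module") {
    dm <- generateDiseaseModules(net, cfg$nDiseases, cfg$moduleSize,
                                 cfg$pairwiseOverlap, seed = seed + 1L)
    multimorbid <- cellTypes[seq_len(cfg$nMultimorbid)]
    moduleGenes <- unique(unlist(dm$modules$sets, use.names = FALSE))
    set.seed(seed + 2L)
    nSpec <- max(1L, round(cfg$fracSpecific * cfg$nGenes))
    ## module genes are specific exactly in the multimorbid cell types;
    ## the remaining specific genes are sampled with a cap of two cell
    ## types per gene so the IQR rule can recover them
    fill <- .sampleSpecificSets(gs, cellTypes,
                                max(0L, nSpec - length(moduleGenes)),
                                exclude = moduleGenes)
    specificSets <- lapply(stats::setNames(cellTypes, cellTypes),
                           function(ct) {
      if (ct %in% multimorbid) unique(c(moduleGenes, fill[[ct]]))
      else fill[[ct]]
    })
    planted <- if (length(dm$modules$core) >= 3)
      list(core = dm$modules$core) else
      list(module1 = dm$modules$sets[[1]])
    pw <- generatePathways(net, cfg$nPathways, cfg$sizeRange,
                           plantedInModules = planted,
                           redundancyPairs = cfg$redundancyPairs,
                           seed = seed + 3L)
    truth <- list(specificSets = NULL, modules = dm$modules,
                  multimorbidCellTypes = multimorbid,
                  plantedPathways = pw$truth$planted,
                  redundantPairs = pw$truth$redundantPairs,
                  effect = list(specificityEffect = cfg$specificityEffect,
                                pairwiseOverlap = cfg$pairwiseOverlap))
    diseasesObj <- dm$diseases
  } else if (cfg$diseaseModel == "random") {
    set.seed(seed + 1L)
    sets <- lapply(stats::setNames(
      paste0("D", seq_len(cfg$nDiseases)),
      paste0("D", seq_len(cfg$nDiseases))),
      function(d) sort(sample(gs, cfg$moduleSize)))
    diseasesObj <- new("DiseaseGeneSets", sets = sets,
                       evidence = stats::setNames(
                         rep("all", cfg$nDiseases), names(sets)))
    set.seed(seed + 2L)
    specificSets <- NULL
    pw <- generatePathways(net, cfg$nPathways, cfg$sizeRange,
                           plantedInModules = NULL,
                           redundancyPairs = cfg$redundancyPairs,
                           seed = seed + 3L)
    truth <- list(specificSets = NULL, modules = NULL,
                  multimorbidCellTypes = character(0),
                  plantedPathways = character(0),
                  redundantPairs = pw$truth$redundantPairs,
                  effect = list(specificityEffect = cfg$specificityEffect,
                                pairwiseOverlap = 0))
  } else stop("unknown diseaseModel: ", cfg$diseaseModel)
  ex <- generateExpression(net, cellTypes, cfg$fracSpecific,
                           specificSets = specificSets,
                           specificityEffect = cfg$specificityEffect,
                           noiseScale = cfg$noiseScale, seed = seed + 4L)
  truth$specificSets <- ex$specificSets
  scen <- new("SyntheticScenario", seed = as.integer(seed),
              network = net, expression = ex$expression,
              diseases = diseasesObj, pathways = pw$pathways,
              truth = truth, config = cfg)
  if (!is.null(outDir)) writeScenario(scen, outDir)
  scen
}

#' Write a synthetic scenario to standard-format files
#'
#' @param scenario [SyntheticScenario-class].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeScenario <- function(scenario, outDir) {
  stopifnot(is(scenario, "SyntheticScenario"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeEdgeList(scenario@network, file.path(outDir, "interactome.tsv"),
                provenance = FALSE)
  E <- SummarizedExperiment::assay(scenario@expression, "exprs")
  expTab <- data.frame(gene = rownames(E), E, check.names = FALSE,
                       stringsAsFactors = FALSE)
  write.table(expTab, file.path(outDir, "expr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dg <- do.call(rbind, lapply(names(scenario@diseases@sets), function(d)
    data.frame(gene = scenario@diseases@sets[[d]], disease = d,
               evidence = "curated", stringsAsFactors = FALSE)))
  write.table(dg, file.path(outDir, "disease_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeGmt(scenario@pathways, file.path(outDir, "pathways.gmt"))
  h <- data.frame(pathway = names(scenario@pathways@sets),
                  parent = NA_character_,
                  depth = scenario@pathways@depth,
                  stringsAsFactors = FALSE)
  write.table(h, file.path(outDir, "hierarchy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = scenario@seed,
         truth = rapply(scenario@truth, unclass, how = "replace"),
         config = scenario@config),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(outDir)
}
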