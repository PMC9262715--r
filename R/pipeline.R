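#' Run configuration
#'
#' Bundles one or more section generator configs with the analysis
#' parameters of every stage and a single global seed. The global seed
#' deterministically spawns per-stage seeds (stage-name hashed) so stages
#' can be rerun independently; identical configurations produce
#' byte-identical outputs.
#'
#' @param sections named list of [TissueConfig] objects (names become
#'   section tags in the outputs).
#' @param outDir output directory (created if needed).
#' @param seed global integer seed.
#' @param contactScale centroid contact scale, default 1.1.
#' @param binSizeUm permutation bin size, default 100.
#' @param nPermutations permutations per test, default 1000.
#' @param nBins laminar depth bins, default 50.
#' @param ligrecPairs ligand-receptor pair table, default
#'   [demoLigRecPairs()].
#' @param taxonomy a [Taxonomy].
#' @return a list of class `"cortexprox_run_config"`.
#' @export
runConfig <- function(sections, outDir, seed = 1L, contactScale = 1.1,
                      binSizeUm = 100, nPermutations = 1000, nBins = 50,
                      ligrecPairs = demoLigRecPairs(),
                      taxonomy = humanTaxonomy()) {
  stopifnot(is.list(sections), length(sections) >= 1,
            !is.null(names(sections)))
  structure(list(sections = sections, outDir = outDir,
                 seed = as.integer(seed), contactScale = contactScale,
                 binSizeUm = binSizeUm,
                 nPermutations = as.integer(nPermutations), nBins = nBins,
                 ligrecPairs = ligrecPairs, taxonomy = taxonomy),
            class = "cortexprox_run_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) each configured section and executes the
#' composition, laminar, proximity and interaction stages, writing one TSV
#' per result table plus a JSON manifest recording the package version,
#' seeds and every analysis parameter. Any stage failure aborts with the
#' stage and section named.
#'
#' Output files (per section, prefixed with the section name):
#' `cells.csv`, `composition.tsv`, `laminar.tsv`, `enrichment.tsv`,
#' `nn_test.tsv`, `vessels.tsv`, `multiway.tsv`, `ligrec.tsv`,
#' `depth_contact.tsv`, and a shared `manifest.json`.
#'
#' @param config a [runConfig()] object.
#' @return invisibly, a named list of per-section result lists.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "cortexprox_run_config"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  stage <- function(name, section, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for section '", section, "': ",
           conditionMessage(e), call. = FALSE))
  }
  wtsv <- function(df, path) fwrite(df, path, sep = "\t", na = "NA")
  for (nm in names(config$sections)) {
    cfg <- config$sections[[nm]]
    pre <- file.path(config$outDir, nm)
    tis <- stage("generate", nm,
                 generateTissue(cfg, config$taxonomy,
                                seed = stageSeed(config$seed,
                                                 paste0("generate_", nm))))
    cells <- tis$cells
    writeCells(cells, paste0(pre, "_cells.csv"))
    comp <- stage("composition", nm, {
      lapply(c("class", "subclass"), function(lv)
        cellComposition(cells, lv, taxonomy = config$taxonomy))
    })
    compTab <- do.call(rbind, lapply(comp, function(cr)
      cbind(level = cr@level, compositionTable(cr),
            glia_to_neuron = gliaToNeuron(cr), exc_to_inh = excToInh(cr))))
    wtsv(compTab, paste0(pre, "_composition.tsv"))
    lam <- stage("laminar", nm, depthProfiles(cells, nBins = config$nBins))
    wtsv(profileTable(lam), paste0(pre, "_laminar.tsv"))
    graph <- stage("contact_graph", nm,
                   buildContactGraph(cells, scale = config$contactScale))
    scheme <- permutationScheme(
      binSizeUm = config$binSizeUm, nPermutations = config$nPermutations,
      seed = stageSeed(config$seed, paste0("proximity_", nm)))
    enr <- stage("pairwise_enrichment", nm,
                 pairwiseEnrichment(cells, graph, scheme))
    wtsv(enr, paste0(pre, "_enrichment.tsv"))
    nn <- stage("nn_test", nm, nnDistanceTest(cells))
    wtsv(nn, paste0(pre, "_nn_test.tsv"))
    ves <- stage("vessels", nm, detectVessels(cells, graph))
    wtsv(ves@summary, paste0(pre, "_vessels.tsv"))
    mw <- stage("multiway", nm,
                multiwayContactTest(cells, graph, scheme = scheme))
    wtsv(mw, paste0(pre, "_multiway.tsv"))
    dc <- stage("depth_contact", nm,
                contactByDepth(cells, graph, scheme = scheme,
                               taxonomy = config$taxonomy))
    wtsv(dc, paste0(pre, "_depth_contact.tsv"))
    lrRes <- stage("ligrec", nm, tryCatch(
      ligrecEnrichment(cells, tis$expression, graph,
                       pairs = config$ligrecPairs, senderType = "MGC",
                       receiverType = "IT", scheme = scheme,
                       taxonomy = config$taxonomy),
      error = function(e) {
        data.frame(ligand = character(0), receptor = character(0),
                   note = conditionMessage(e))
      }))
    wtsv(lrRes, paste0(pre, "_ligrec.tsv"))
    results[[nm]] <- list(cells = cells, composition = comp, laminar = lam,
                          enrichment = enr, nn = nn, vessels = ves,
                          multiway = mw, depth_contact = dc, ligrec = lrRes)
  }
  manifest <- list(
    package = "cortexprox",
    version = as.character(utils::packageVersion("cortexprox")),
    seed = config$seed,
    stage_seeds = setNames(
      lapply(names(config$sections), function(nm)
        list(generate = stageSeed(config$seed, paste0("generate_", nm)),
             proximity = stageSeed(config$seed, paste0("proximity_", nm)))),
      names(config$sections)),
    parameters = list(contact_scale = config$contactScale,
                      bin_size_um = config$binSizeUm,
                      n_permutations = config$nPermutations,
                      n_depth_bins = config$nBins),
    sections = setNames(lapply(config$sections, function(cfg)
      list(species = cfg@species, section_id = cfg@sectionId,
           width_um = cfg@sectionWidthUm, height_um = cfg@sectionHeightUm,
           density = cfg@densityCellsPerMm2, seed = cfg@seed)),
      names(config$sections)))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Bundled human-vs-mouse demo
#'
#' Runs the full pipeline on small synthetic human and/or mouse sections
#' (scaled-down defaults; all study-condition parameters other than the
#' section extent are untouched) and writes all result tables to `outDir`.
#'
#' @param species `"both"` (default), `"human"` or `"mouse"`.
#' @param outDir output directory.
#' @param seed global seed, default 1.
#' @param widthUm demo section width, default 1500 um (a few thousand
#'   cells per section).
#' @param nPermutations permutations per test, default 200 for a quick
#'   demo.
#' @return invisibly, the [runPipeline()] result list.
#' @export
runDemo <- function(species = c("both", "human", "mouse"), outDir,
                    seed = 1L, widthUm = 1500, nPermutations = 200) {
  species <- match.arg(species)
  secs <- list()
  if (species %in% c("both", "human"))
    secs$human <- resizeSection(defaultHumanConfig(seed = seed), widthUm)
  if (species %in% c("both", "mouse"))
    secs$mouse <- resizeSection(defaultMouseConfig(seed = seed),
                                round(widthUm / 3))
  runPipeline(runConfig(secs, outDir, seed = seed,
                        nPermutations = nPermutations))
}
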