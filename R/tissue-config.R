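## Default layer boundaries (relative depth): L1|L2/3|L4|L5|L6|WM.
.LAYER_BOUNDARIES <- c(0.09, 0.35, 0.47, 0.70, 0.88)

## Gene panel shared by the default configs. Marker genes drive cell-type
## structure; the ligand/receptor block supports contact-conditioned
## enrichment; FILLER genes give the matrix realistic bulk.
.genePanel <- function() {
  c("SLC17A7", "GAD1", "GAD2", "SLC32A1",
    "LAMP5", "PVALB", "SST", "VIP", "CUX2", "RORB", "FEZF2", "SYT6",
    "CTGF", "AQP4", "PLP1", "PDGFRA", "CX3CR1", "CLDN5", "PDGFRB",
    "A2M", "LRP1", "NRXN1", "NLGN1", "NRXN3", "NLGN3", "IL34", "CSF1R",
    "APOE", "TREM2", "CX3CL1", "PSAP", "GPR37L1", "SEMA4D", "PLXNB1",
    "EFNB2", "EPHB2", "JAM2", "JAM3",
    sprintf("FILLER%02d", 1:10))
}

.subclassMarker <- c("L2/3 IT" = "CUX2", "L4/5 IT" = "RORB",
                     "L5 ET" = "FEZF2", "L6 CT" = "SYT6", "L6b" = "CTGF",
                     LAMP5 = "LAMP5", PVALB = "PVALB", SST = "SST",
                     VIP = "VIP", ASC = "AQP4", OGC = "PLP1",
                     OPC = "PDGFRA", MGC = "CX3CR1", ENDO = "CLDN5",
                     MURAL = "PDGFRB")

.markerSets <- function(taxonomy) {
  tb <- taxonomyTable(taxonomy)
  sets <- lapply(seq_len(nrow(tb)), function(i) {
    s <- tb$subclass[i]
    base <- switch(tb$class[i],
                   excitatory = "SLC17A7",
                   inhibitory = c("GAD1", "GAD2", "SLC32A1"),
                   `non-neuronal` = character(0))
    ## OPC GAD1 expression is governed by the dedicated latent-subpopulation
    ## model, not the marker machinery.
    unique(c(base, .subclassMarker[s][!is.na(.subclassMarker[s])]))
  })
  names(sets) <- tb$cluster
  sets
}

## Per-subclass depth bands: cluster means are spread uniformly across
## [lo, hi]; sd is shared within the subclass. OGC gets a separate
## white-matter block (last 4 clusters) to emulate WM oligodendrocytes.
.laminarBands <- list(
  "L2/3 IT"    = c(0.13, 0.33, 0.050), "L4/5 IT" = c(0.39, 0.43, 0.030),
  "L5 IT"      = c(0.50, 0.65, 0.070), "L6 IT"   = c(0.72, 0.84, 0.050),
  "L6 IT CAR3" = c(0.78, 0.78, 0.050), "L5 ET"   = c(0.55, 0.62, 0.050),
  "L5/6 NP"    = c(0.68, 0.74, 0.050), "L6 CT"   = c(0.76, 0.85, 0.040),
  "L6b"        = c(0.84, 0.90, 0.050),
  LAMP5 = c(0.08, 0.30, 0.080), VIP = c(0.10, 0.35, 0.100),
  PVALB = c(0.25, 0.75, 0.150), SST = c(0.25, 0.80, 0.150),
  ASC  = c(0.05, 0.95, 0.100), OPC = c(0.20, 0.80, 0.200),
  MGC  = c(0.15, 0.85, 0.200), ENDO = c(0.10, 0.90, 0.150),
  MURAL = c(0.10, 0.90, 0.150))

.laminarDefaults <- function(taxonomy) {
  tb <- taxonomyTable(taxonomy)
  out <- lapply(unique(tb$subclass), function(s) {
    cl <- tb$cluster[tb$subclass == s]
    k <- length(cl)
    if (s == "OGC") {
      ## 12 cortical clusters in deep layers, 4 straddling the WM
      ## boundary (keeps WM oligodendrocyte-enriched without driving the
      ## WM compartment toward hard-core jamming)
      ncx <- k - 4L
      m <- c(seq(0.55, 0.84, length.out = ncx), seq(0.90, 0.96, length.out = 4))
      s2 <- c(rep(0.08, ncx), rep(0.08, 4))
    } else {
      band <- .laminarBands[[s]]
      m <- if (k == 1L) mean(band[1:2]) else seq(band[1], band[2], length.out = k)
      s2 <- rep(band[3], k)
    }
    data.frame(cluster = cl, mean_depth = m, sd_depth = s2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.somaRadiusDefaults <- function(taxonomy) {
  tb <- taxonomyTable(taxonomy)
  sub <- unique(tb[, c("subclass", "class")])
  mean <- ifelse(sub$class == "excitatory", 6,
          ifelse(sub$class == "inhibitory", 5,
          ifelse(sub$subclass %in% c("ENDO", "MURAL"), 4,
          ifelse(sub$subclass == "ASC", 5, 4.5))))
  sd <- ifelse(sub$class == "excitatory", 1,
        ifelse(sub$class == "inhibitory", 1, 0.8))
  data.frame(subclass = sub$subclass, mean = mean, sd = sd,
             stringsAsFactors = FALSE)
}

## Fraction of a cluster's truncated-normal depth mass below the WM
## boundary (its "retention" under white-matter exclusion).
.nonWmRetention <- function(mean, sd, wmBoundary) {
  lo <- pnorm((0 - mean) / sd)
  hi <- pnorm((1 - mean) / sd)
  (pnorm((wmBoundary - mean) / sd) - lo) / (hi - lo)
}

## Expand subclass-level target proportions to cluster-level sampling
## probabilities: split within subclass with mildly uneven deterministic
## weights, then divide by the non-WM retention of each cluster so the
## white-matter-excluded composition recovers the targets, and renormalize.
.clusterSamplingProbs <- function(subclassTargets, taxonomy, laminar,
                                  wmBoundary) {
  tb <- taxonomyTable(taxonomy)
  p <- numeric(nrow(tb))
  names(p) <- tb$cluster
  for (s in names(subclassTargets)) {
    cl <- tb$cluster[tb$subclass == s]
    if (!length(cl)) stop("subclass not in taxonomy: ", s)
    w <- rev(seq_len(length(cl))) + 1          # mildly uneven, deterministic
    p[cl] <- subclassTargets[[s]] * w / sum(w)
  }
  ret <- .nonWmRetention(laminar$mean_depth, laminar$sd_depth, wmBoundary)
  names(ret) <- laminar$cluster
  p <- p / ret[names(p)]
  p / sum(p)
}

#' Construct a tissue configuration
#'
#' Low-level constructor for [TissueConfig]; most users should start from
#' [defaultHumanConfig()] / [defaultMouseConfig()] and adapt with
#' [modifyTissueConfig()] or [resizeSection()].
#'
#' @param sectionWidthUm,sectionHeightUm section extent in micrometres.
#' @param layerBoundaries 5 strictly increasing relative depths in (0, 1].
#' @param densityCellsPerMm2 areal density.
#' @param composition named cluster->probability vector (sums to 1).
#' @param laminarProfiles data.frame `cluster`, `mean_depth`, `sd_depth`.
#' @param hardcoreDistanceUm minimum centroid separation, micrometres.
#' @param somaRadiusUm data.frame `subclass`, `mean`, `sd`.
#' @param satelliteSpecs data.frame of satellite injections (may be empty).
#' @param vesselSpec list (`n_vessels`, `cells_per_vessel`, `step_um`,
#'   `mural_fraction`, `glial_recruit`).
#' @param expressionSpec list (`genes`, `baseline_nb_mean`,
#'   `nb_dispersion`, `marker_sets`, `marker_fold`, `libsize_sdlog`).
#' @param gad1PositiveOpcFraction latent GAD1+ OPC probability.
#' @param ligrecSpec data.frame of contact-conditioned expression boosts.
#' @param species,sectionId tags.
#' @param seed integer RNG seed.
#' @return a validated [TissueConfig].
#' @export
tissueConfig <- function(sectionWidthUm, sectionHeightUm,
                         layerBoundaries = .LAYER_BOUNDARIES,
                         densityCellsPerMm2, composition, laminarProfiles,
                         hardcoreDistanceUm = 8,
                         somaRadiusUm,
                         satelliteSpecs = emptySatelliteSpecs(),
                         vesselSpec = list(n_vessels = 0L,
                                           cells_per_vessel = 0L,
                                           step_um = 8.5, mural_fraction = 0.3,
                                           glial_recruit = numeric(0)),
                         expressionSpec,
                         gad1PositiveOpcFraction = 0,
                         ligrecSpec = emptyLigrecSpec(),
                         species = "human", sectionId = "S1", seed = 1L) {
  new("TissueConfig",
      sectionWidthUm = sectionWidthUm, sectionHeightUm = sectionHeightUm,
      layerBoundaries = layerBoundaries,
      densityCellsPerMm2 = densityCellsPerMm2,
      composition = composition, laminarProfiles = laminarProfiles,
      hardcoreDistanceUm = hardcoreDistanceUm, somaRadiusUm = somaRadiusUm,
      satelliteSpecs = satelliteSpecs, vesselSpec = vesselSpec,
      expressionSpec = expressionSpec,
      gad1PositiveOpcFraction = gad1PositiveOpcFraction,
      ligrecSpec = ligrecSpec, species = species, sectionId = sectionId,
      seed = as.integer(seed))
}

#' @rdname tissueConfig
#' @export
emptySatelliteSpecs <- function() {
  data.frame(focal_subclass = character(0), partner_subclass = character(0),
             fraction = numeric(0), contact_gap_um = numeric(0),
             partners_per_focal = integer(0), stringsAsFactors = FALSE)
}

#' @rdname tissueConfig
#' @export
emptyLigrecSpec <- function() {
  data.frame(ligand = character(0), receptor = character(0),
             sender = character(0), receiver = character(0),
             contact_boost_fold = numeric(0), stringsAsFactors = FALSE)
}

.defaultExpressionSpec <- function(taxonomy) {
  list(genes = .genePanel(), baseline_nb_mean = 0.4, nb_dispersion = 3,
       marker_sets = .markerSets(taxonomy), marker_fold = 25,
       libsize_sdlog = 0.3)
}

#' Default human cortical-section configuration
#'
#' Encodes the headline human composition of the temporal-cortex MERFISH
#' atlas as generator ground truth, on a white-matter-excluded basis:
#' 26% excitatory / 11% inhibitory / 63% non-neuronal cells
#' (glia:neuron = 1.4, E:I = 26/11), IT neurons ~93% of excitatory with IT
#' split 46/18/19/13/4 (L2/3, L4/5, L5, L6, L6 CAR3), non-IT 7%, and
#' inhibitory split 13/26/30/31 (LAMP5/PVALB/SST/VIP). The non-neuronal 63%
#' is partitioned into glia 51.8% (ASC 20, OGC 21, OPC 4.8, MGC 6) and
#' vascular 11.2% (ENDO 8, MURAL 3.2) so that glia:neuron = 1.4. Cluster
#' sampling probabilities are pre-compensated for each cluster's
#' white-matter occupancy (see the methods vignette).
#'
#' Interaction injections (ground truth for the proximity/interaction
#' stages): microglia satellites against IT neurons with a fraction
#' decreasing from L2/3 IT to L6 IT, neuron-oligodendrocyte/OPC multiway
#' satellites (3 partners per focal neuron), intra-subclass SST and PVALB
#' satellites, vessel chains of ENDO/MURAL cells recruiting 2 microglia and
#' 2 oligodendrocytes each, a latent GAD1+ OPC subpopulation of 50%, and an
#' A2M->LRP1 expression boost in contacting microglia->IT pairs.
#'
#' @param sectionWidthUm,sectionHeightUm section extent (defaults give
#'   ~50,000 cells at 2,000 cells/mm^2).
#' @param seed integer RNG seed stored in the config.
#' @param taxonomy a [Taxonomy]; defaults to [humanTaxonomy()].
#' @return a [TissueConfig].
#' @export
defaultHumanConfig <- function(sectionWidthUm = 10000, sectionHeightUm = 2500,
                               seed = 1L, taxonomy = humanTaxonomy()) {
  exc <- 0.26; inh <- 0.11
  itSplit <- c("L2/3 IT" = 0.46, "L4/5 IT" = 0.18, "L5 IT" = 0.19,
               "L6 IT" = 0.13, "L6 IT CAR3" = 0.04)
  nonItSplit <- c("L6 CT" = 0.45, "L6b" = 0.25, "L5/6 NP" = 0.18,
                  "L5 ET" = 0.12)
  inhSplit <- c(LAMP5 = 0.13, PVALB = 0.26, SST = 0.30, VIP = 0.31)
  targets <- c(exc * 0.93 * itSplit, exc * 0.07 * nonItSplit,
               inh * inhSplit,
               c(ASC = 0.20, OGC = 0.21, OPC = 0.048, MGC = 0.06,
                 ENDO = 0.08, MURAL = 0.032))
  laminar <- .laminarDefaults(taxonomy)
  comp <- .clusterSamplingProbs(targets, taxonomy, laminar,
                                .LAYER_BOUNDARIES[5])
  sat <- data.frame(
    focal_subclass  = c("L2/3 IT", "L4/5 IT", "L5 IT", "L6 IT",
                        "L2/3 IT", "L5 IT", "L2/3 IT", "SST", "PVALB"),
    partner_subclass = c("MGC", "MGC", "MGC", "MGC",
                         "OGC", "OGC", "OPC", "SST", "PVALB"),
    fraction = c(0.27, 0.075, 0.045, 0.012, 0.10, 0.08, 0.15, 0.40, 0.35),
    contact_gap_um = 0.5,
    partners_per_focal = c(1L, 1L, 1L, 1L, 3L, 3L, 3L, 1L, 1L),
    stringsAsFactors = FALSE)
  vessel <- list(n_vessels = 150L, cells_per_vessel = 8L, step_um = 8.5,
                 mural_fraction = 0.3,
                 glial_recruit = c(MGC = 2, OGC = 2))
  ligrec <- data.frame(ligand = "A2M", receptor = "LRP1", sender = "MGC",
                       receiver = "IT", contact_boost_fold = 3,
                       stringsAsFactors = FALSE)
  tissueConfig(sectionWidthUm = sectionWidthUm,
               sectionHeightUm = sectionHeightUm,
               densityCellsPerMm2 = 2000,
               composition = comp, laminarProfiles = laminar,
               somaRadiusUm = .somaRadiusDefaults(taxonomy),
               satelliteSpecs = sat, vesselSpec = vessel,
               expressionSpec = .defaultExpressionSpec(taxonomy),
               gad1PositiveOpcFraction = 0.5, ligrecSpec = ligrec,
               species = "human", sectionId = "human_S1", seed = seed)
}

#' Default mouse cortical-section configuration
#'
#' Mouse counterpart constrained by the printed cross-species ratios:
#' glia:neuron = 0.28 (five times lower than the human 1.4), E:I = 6.9
#' (three times the human 2.3), non-IT neurons 29% of excitatory, and cell
#' density three times the human default. Per-subclass splits not printed
#' for mouse are free parameters (documented in the methods vignette):
#' PVALB-shifted inhibitory split (8/40/35/17), IT split 30/28/22/17/3.
#' No interaction injections: mouse sections carry vessels but no glial
#' recruitment, no satellite cells and no ligand-receptor boost, matching
#' the reported absence of these enrichments in mouse.
#'
#' @inheritParams defaultHumanConfig
#' @return a [TissueConfig].
#' @export
defaultMouseConfig <- function(sectionWidthUm = 5000, sectionHeightUm = 2500,
                               seed = 1L, taxonomy = mouseTaxonomy()) {
  ei <- 6.9; gn <- 0.28; vasc <- 0.09
  neurons <- (1 - vasc) / (1 + gn)
  exc <- neurons * ei / (1 + ei)
  inh <- neurons / (1 + ei)
  glia <- gn * neurons
  itSplit <- c("L2/3 IT" = 0.30, "L4/5 IT" = 0.28, "L5 IT" = 0.22,
               "L6 IT" = 0.17, "L6 IT CAR3" = 0.03)
  nonItSplit <- c("L6 CT" = 0.50, "L5 ET" = 0.20, "L5/6 NP" = 0.17,
                  "L6b" = 0.13)
  inhSplit <- c(LAMP5 = 0.08, PVALB = 0.40, SST = 0.35, VIP = 0.17)
  gliaSplit <- c(ASC = 0.427, OGC = 0.377, OPC = 0.090, MGC = 0.106)
  targets <- c(exc * 0.71 * itSplit, exc * 0.29 * nonItSplit,
               inh * inhSplit, glia * gliaSplit,
               c(ENDO = vasc * 0.72, MURAL = vasc * 0.28))
  targets <- targets / sum(targets)
  laminar <- .laminarDefaults(taxonomy)
  comp <- .clusterSamplingProbs(targets, taxonomy, laminar,
                                .LAYER_BOUNDARIES[5])
  vessel <- list(n_vessels = 150L, cells_per_vessel = 8L, step_um = 8.5,
                 mural_fraction = 0.3, glial_recruit = numeric(0))
  tissueConfig(sectionWidthUm = sectionWidthUm,
               sectionHeightUm = sectionHeightUm,
               densityCellsPerMm2 = 6000,
               composition = comp, laminarProfiles = laminar,
               ## three-fold denser tissue cannot honor the human 8 um
               ## centroid floor (laminar density peaks would exceed the
               ## hard-disk jamming limit); mouse packing is tighter
               hardcoreDistanceUm = 5,
               somaRadiusUm = .somaRadiusDefaults(taxonomy),
               vesselSpec = vessel,
               expressionSpec = .defaultExpressionSpec(taxonomy),
               gad1PositiveOpcFraction = 0, species = "mouse",
               sectionId = "mouse_S1", seed = seed)
}

#' Modify or resize a tissue configuration
#'
#' `modifyTissueConfig()` replaces named slots and re-validates;
#' `resizeSection()` changes only the section extent (density and all other
#' study conditions are untouched); `disableInteractions()` removes every
#' interaction injection (satellite specs, vessel chains and glial
#' recruitment, ligand-receptor boosts) so the generated pattern carries no
#' ground-truth cell-cell interaction structure -- the null condition used
#' for permutation-test calibration.
#'
#' @param config a [TissueConfig].
#' @param ... for `modifyTissueConfig()`, `slotName = value` pairs.
#' @return a validated [TissueConfig].
#' @export
modifyTissueConfig <- function(config, ...) {
  args <- list(...)
  for (nm in names(args)) {
    if (!nm %in% slotNames("TissueConfig")) stop("unknown slot: ", nm)
    slot(config, nm) <- if (nm == "seed") as.integer(args[[nm]]) else args[[nm]]
  }
  validObject(config)
  config
}

#' @rdname modifyTissueConfig
#' @param widthUm,heightUm new section extent, micrometres.
#' @export
resizeSection <- function(config, widthUm, heightUm = config@sectionHeightUm) {
  modifyTissueConfig(config, sectionWidthUm = widthUm,
                     sectionHeightUm = heightUm)
}

#' @rdname modifyTissueConfig
#' @export
disableInteractions <- function(config) {
  vs <- config@vesselSpec
  vs$n_vessels <- 0L
  vs$glial_recruit <- numeric(0)
  modifyTissueConfig(config, satelliteSpecs = emptySatelliteSpecs(),
                     vesselSpec = vs, ligrecSpec = emptyLigrecSpec())
}

#' Demo ligand-receptor pair list
#'
#' Ten curated ligand-receptor pairs used in tests and the demo pipeline,
#' including A2M-LRP1 (the pair boosted in contacting microglia-IT neuron
#' pairs by the default human generator). Users supply their own list for
#' real analyses.
#'
#' @return data.frame with columns `ligand`, `receptor`.
#' @export
demoLigRecPairs <- function() {
  data.frame(
    ligand = c("A2M", "NRXN1", "NRXN3", "IL34", "APOE", "CX3CL1", "PSAP",
               "SEMA4D", "EFNB2", "JAM2"),
    receptor = c("LRP1", "NLGN1", "NLGN3", "CSF1R", "TREM2", "CX3CR1",
                 "GPR37L1", "PLXNB1", "EPHB2", "JAM3"),
    stringsAsFactors = FALSE)
}

#' Read / write a tissue configuration
#'
#' Serializes a [TissueConfig] to a versioned YAML document and back.
#' `readTissueConfig()` validates the reconstructed object and rejects
#' unknown schema versions.
#'
#' @param config a [TissueConfig].
#' @param path file path (YAML).
#' @return `readTissueConfig()` returns a [TissueConfig];
#'   `writeTissueConfig()` returns `path` invisibly.
#' @export
writeTissueConfig <- function(config, path) {
  lst <- list(schema_version = 1L)
  for (nm in slotNames("TissueConfig")) {
    v <- slot(config, nm)
    lst[[nm]] <- if (is.data.frame(v)) as.list(v) else v
  }
  ## named numeric vectors survive as maps
  lst$composition <- as.list(config@composition)
  lst$layerBoundaries <- as.numeric(config@layerBoundaries)
  vs <- config@vesselSpec
  vs$glial_recruit <- as.list(vs$glial_recruit)
  lst$vesselSpec <- vs
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname writeTissueConfig
#' @export
readTissueConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  if (is.null(lst$schema_version) || lst$schema_version != 1L)
    stop("unsupported config schema version: ", lst$schema_version)
  asDf <- function(x) as.data.frame(x, stringsAsFactors = FALSE)
  vs <- lst$vesselSpec
  vs$glial_recruit <- unlist(vs$glial_recruit)
  if (is.null(vs$glial_recruit)) vs$glial_recruit <- numeric(0)
  es <- lst$expressionSpec
  es$genes <- as.character(es$genes)
  tissueConfig(sectionWidthUm = lst$sectionWidthUm,
               sectionHeightUm = lst$sectionHeightUm,
               layerBoundaries = as.numeric(lst$layerBoundaries),
               densityCellsPerMm2 = lst$densityCellsPerMm2,
               composition = unlist(lst$composition),
               laminarProfiles = asDf(lst$laminarProfiles),
               hardcoreDistanceUm = lst$hardcoreDistanceUm,
               somaRadiusUm = asDf(lst$somaRadiusUm),
               satelliteSpecs = if (length(lst$satelliteSpecs[[1]]))
                 asDf(lst$satelliteSpecs) else emptySatelliteSpecs(),
               vesselSpec = vs, expressionSpec = es,
               gad1PositiveOpcFraction = lst$gad1PositiveOpcFraction,
               ligrecSpec = if (length(lst$ligrecSpec[[1]]))
                 asDf(lst$ligrecSpec) else emptyLigrecSpec(),
               species = lst$species, sectionId = lst$sectionId,
               seed = lst$seed)
}
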