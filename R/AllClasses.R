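#' @import methods
#' @importFrom stats pnorm qnorm rnorm runif rpois rbinom rnbinom rlnorm
#'   sd quantile wilcox.test p.adjust cor setNames
#' @importClassesFrom Matrix Matrix
NULL

.CELL_COLUMNS <- c("cell_id", "x_um", "y_um", "soma_radius_um", "depth",
                   "layer", "class", "subclass", "cluster", "section_id",
                   "species")

.LAYERS <- c("L1", "L2/3", "L4", "L5", "L6", "WM")

#' Cell-type taxonomy
#'
#' Three-level hierarchy class -> subclass -> cluster with per-subclass flags
#' marking glial (ASC, OGC, OPC, MGC), vascular (ENDO, MURAL) and
#' intratelencephalic (IT) subclasses.
#'
#' @slot table data.frame with columns `cluster`, `subclass`, `class`,
#'   `is_glial`, `is_vascular`, `is_IT`; one row per cluster.
#' @seealso [humanTaxonomy()]
#' @exportClass Taxonomy
setClass("Taxonomy", representation(table = "data.frame"))

setValidity("Taxonomy", function(object) {
  tb <- object@table
  need <- c("cluster", "subclass", "class", "is_glial", "is_vascular", "is_IT")
  if (!all(need %in% names(tb)))
    return(paste("missing columns:", paste(setdiff(need, names(tb)), collapse = ", ")))
  if (anyDuplicated(tb$cluster))
    return("duplicated cluster names")
  if (!all(tb$class %in% c("excitatory", "inhibitory", "non-neuronal")))
    return("class must be excitatory/inhibitory/non-neuronal")
  sub2class <- tapply(tb$class, tb$subclass, function(z) length(unique(z)))
  if (any(sub2class > 1))
    return("a subclass maps to more than one class")
  TRUE
})

#' Per-cell table of a spatial section
#'
#' One record per segmented cell: centroid position (micrometres), soma
#' radius, normalized cortical depth (0 = pial surface), cortical layer and
#' taxonomy labels. Extra columns (e.g. generator provenance flags) are
#' preserved.
#'
#' @slot cells data.frame with at least the columns `cell_id`, `x_um`,
#'   `y_um`, `soma_radius_um`, `depth`, `layer`, `class`, `subclass`,
#'   `cluster`, `section_id`, `species`.
#' @exportClass CellTable
setClass("CellTable", representation(cells = "data.frame"))

setValidity("CellTable", function(object) {
  msg <- .checkCellFrame(object@cells)
  if (is.null(msg)) TRUE else msg
})

# returns NULL if ok, else a message naming the offending field/row
.checkCellFrame <- function(df) {
  miss <- setdiff(.CELL_COLUMNS, names(df))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) return(NULL)
  dup <- df$cell_id[duplicated(df$cell_id)]
  if (length(dup))
    return(paste("duplicated cell_id:", paste(unique(dup), collapse = ", ")))
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad))
    return(paste("non-finite coordinates at rows:", paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!is.finite(df$soma_radius_um) | df$soma_radius_um <= 0)
  if (length(bad))
    return(paste("soma_radius_um must be > 0; offending rows:", paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!is.finite(df$depth) | df$depth < 0)
  if (length(bad))
    return(paste("depth must be finite and >= 0; offending rows:", paste(utils::head(bad, 5), collapse = ", ")))
  NULL
}

#' Sparse cell x gene expression matrix
#'
#' Non-negative integer transcript counts, cells in rows, genes in columns;
#' row names are cell ids matching a [CellTable].
#'
#' @slot counts a `dgCMatrix` of counts with dimnames (cell ids, gene names).
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", representation(counts = "Matrix"))

setValidity("ExpressionMatrix", function(object) {
  m <- object@counts
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m))))
    return("counts must carry cell ids (rownames) and gene names (colnames)")
  v <- m@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    return("counts must be non-negative integers")
  TRUE
})

#' Soma contact / proximity graph
#'
#' Undirected edge list between cells whose somata touch or lie within a
#' small distance, together with the rule that produced it so every edge is
#' re-checkable.
#'
#' @slot edges data.frame with columns `a`, `b` (cell ids, a < b as strings
#'   is not required but pairs are unique and unordered) and
#'   `distance_um` (centroid distance).
#' @slot mode `"centroid"` (edge iff d <= scale * (r_i + r_j)) or
#'   `"boundary"` (edge iff somata dilated by `tol_um` overlap).
#' @slot params named list of the rule parameters used.
#' @slot cellIds character vector of all cell ids the graph was built on.
#' @exportClass ContactGraph
setClass("ContactGraph", representation(edges = "data.frame",
                                        mode = "character",
                                        params = "list",
                                        cellIds = "character"))

setValidity("ContactGraph", function(object) {
  e <- object@edges
  if (!all(c("a", "b", "distance_um") %in% names(e)))
    return("edges must have columns a, b, distance_um")
  if (nrow(e)) {
    if (any(e$a == e$b)) return("self-edges are not allowed")
    key <- paste(pmin(e$a, e$b), pmax(e$a, e$b))
    if (anyDuplicated(key)) return("duplicate unordered pairs")
  }
  if (!object@mode %in% c("centroid", "boundary"))
    return("mode must be 'centroid' or 'boundary'")
  TRUE
})

#' Density-preserving spatial permutation scheme
#'
#' Cells are partitioned into rectangular spatial bins (`binSizeUm` wide,
#' `binHeightUm` tall); label permutations shuffle (subclass, cluster)
#' label pairs among the cells of each bin with positions fixed, so the
#' per-bin count of every cell type is exactly preserved (the "local
#' density" contract) while fine-scale neighbor identity is destroyed.
#' Bins are anisotropic by default (100 x 25 um): cortical tissue is
#' statistically homogeneous laterally but strongly graded along depth, so
#' depth-wise density must be preserved at finer resolution than lateral
#' density for the null to be exchangeable.
#'
#' @slot binSizeUm lateral (x) bin extent, micrometres.
#' @slot binHeightUm depth-wise (y) bin extent, micrometres.
#' @slot nPermutations number of permutations used for null moments.
#' @slot seed integer RNG seed (mandatory for reproducibility).
#' @slot labelLevel `"subclass"` or `"cluster"`.
#' @exportClass PermutationScheme
setClass("PermutationScheme", representation(binSizeUm = "numeric",
                                             binHeightUm = "numeric",
                                             nPermutations = "integer",
                                             seed = "integer",
                                             labelLevel = "character"))

setValidity("PermutationScheme", function(object) {
  if (object@binSizeUm <= 0) return("binSizeUm must be > 0")
  if (object@binHeightUm <= 0) return("binHeightUm must be > 0")
  if (object@nPermutations < 2L) return("nPermutations must be >= 2")
  if (!object@labelLevel %in% c("subclass", "cluster"))
    return("labelLevel must be 'subclass' or 'cluster'")
  TRUE
})

#' Composition result
#'
#' Per-label counts and proportions at one taxonomy level over one
#' denominator population, plus the headline ratios.
#'
#' @slot level `"class"`, `"subclass"` or `"cluster"`.
#' @slot denominator `"all_cells"`, `"neurons"`, `"excitatory"`,
#'   `"inhibitory"` or `"IT"`.
#' @slot excludeWM whether white-matter cells were removed before counting.
#' @slot table data.frame with columns `label`, `count`, `proportion`.
#' @slot nDenominator size of the denominator population.
#' @slot gliaToNeuron glia:neuron ratio of the (optionally WM-excluded)
#'   section; glia = ASC + OGC + OPC + MGC.
#' @slot excToInh excitatory:inhibitory neuron ratio.
#' @exportClass CompositionResult
setClass("CompositionResult", representation(level = "character",
                                             denominator = "character",
                                             excludeWM = "logical",
                                             table = "data.frame",
                                             nDenominator = "integer",
                                             gliaToNeuron = "numeric",
                                             excToInh = "numeric"))

setValidity("CompositionResult", function(object) {
  tb <- object@table
  if (nrow(tb) && abs(sum(tb$proportion) - 1) > 1e-9)
    return("proportions must sum to 1")
  if (nrow(tb) && sum(tb$count) != object@nDenominator)
    return("counts must sum to the denominator size")
  TRUE
})

#' Cortical-depth profile
#'
#' Per-cluster binned depth densities (unit area) and the per-bin
#' excitatory/inhibitory counts, E:I ratio and across-bin standardized E:I
#' z-score.
#'
#' @slot binEdges bin edges, uniform over `[0, maxDepth]`.
#' @slot profiles long data.frame: `cluster`, `bin`, `mid`, `count`,
#'   `density` (density integrates to 1 per cluster).
#' @slot ei data.frame per bin: `bin`, `mid`, `exc`, `inh`, `ratio`,
#'   `log2_ratio`, `z` (mean 0, sd 1 across finite bins).
#' @slot excluded clusters with fewer than `minCells` cells (flagged,
#'   excluded from `profiles`, still counted in `ei`).
#' @slot clusterCounts named integer vector of per-cluster cell counts.
#' @exportClass DepthProfile
setClass("DepthProfile", representation(binEdges = "numeric",
                                        profiles = "data.frame",
                                        ei = "data.frame",
                                        excluded = "character",
                                        clusterCounts = "integer"))

#' Detected blood vessels and glial adjacency
#'
#' Connected components of the contact graph restricted to endothelial and
#' mural cells, with per-vessel counts of adjacent glia.
#'
#' @slot vessels list of character vectors, member cell ids per vessel.
#' @slot adjacency data.frame: `vessel`, `subclass`, `count` (glia of that
#'   subclass contacting any vessel member).
#' @slot summary data.frame: `subclass`, `mean`, `sd` of per-vessel counts.
#' @slot minSize minimum component size used.
#' @exportClass VesselSet
setClass("VesselSet", representation(vessels = "list",
                                     adjacency = "data.frame",
                                     summary = "data.frame",
                                     minSize = "integer"))

#' Synthetic tissue configuration
#'
#' Full parameterization of the synthetic cortical-section generator: flat
#' rectangular geometry with depth = y / section height, laminar layer
#' boundaries, hard-core soma exclusion, per-cluster composition and
#' truncated-Gaussian depth profiles, satellite-cell and vessel-chain
#' injections, and a negative-binomial expression model.
#'
#' @slot sectionWidthUm,sectionHeightUm section extent, micrometres.
#' @slot layerBoundaries strictly increasing relative depths in (0, 1]
#'   separating L1|L2/3|L4|L5|L6|WM; depth >= the last boundary is white
#'   matter.
#' @slot densityCellsPerMm2 areal cell density.
#' @slot composition named numeric, cluster -> sampling probability (sums
#'   to 1).
#' @slot laminarProfiles data.frame: `cluster`, `mean_depth`, `sd_depth` of
#'   a truncated-Gaussian depth distribution on [0, 1].
#' @slot hardcoreDistanceUm minimum centroid separation for free cells.
#' @slot somaRadiusUm data.frame: `subclass`, `mean`, `sd` (truncated
#'   normal, floored at 2 um).
#' @slot satelliteSpecs data.frame: `focal_subclass`, `partner_subclass`,
#'   `fraction` (of partner cells relocated as satellites),
#'   `contact_gap_um`, `partners_per_focal`.
#' @slot vesselSpec list: `n_vessels`, `cells_per_vessel`, `step_um`,
#'   `mural_fraction`, `glial_recruit` (named numeric, glial subclass ->
#'   cells per vessel).
#' @slot expressionSpec list: `genes` (character panel),
#'   `baseline_nb_mean`, `nb_dispersion` (NB size), `marker_sets` (named
#'   list cluster -> gene names), `marker_fold`, `libsize_sdlog`.
#' @slot gad1PositiveOpcFraction probability an OPC belongs to the latent
#'   GAD1-expressing subpopulation.
#' @slot ligrecSpec data.frame: `ligand`, `receptor`, `sender`, `receiver`
#'   (subclass / class / "IT" group names), `contact_boost_fold`.
#' @slot species,sectionId tags copied into the generated table.
#' @slot seed integer RNG seed.
#' @exportClass TissueConfig
setClass("TissueConfig", representation(
  sectionWidthUm = "numeric", sectionHeightUm = "numeric",
  layerBoundaries = "numeric", densityCellsPerMm2 = "numeric",
  composition = "numeric", laminarProfiles = "data.frame",
  hardcoreDistanceUm = "numeric", somaRadiusUm = "data.frame",
  satelliteSpecs = "data.frame", vesselSpec = "list",
  expressionSpec = "list", gad1PositiveOpcFraction = "numeric",
  ligrecSpec = "data.frame", species = "character",
  sectionId = "character", seed = "integer"))

setValidity("TissueConfig", function(object) {
  if (abs(sum(object@composition) - 1) > 1e-9)
    return("composition probabilities must sum to 1")
  b <- object@layerBoundaries
  if (length(b) != 5 || any(diff(b) <= 0) || any(b <= 0) || any(b > 1))
    return("layerBoundaries must be 5 strictly increasing values in (0, 1]")
  if (object@hardcoreDistanceUm <= 0)
    return("hardcoreDistanceUm must be > 0")
  if (any(object@composition < 0))
    return("composition probabilities must be >= 0")
  ss <- object@satelliteSpecs
  if (nrow(ss) && (any(ss$fraction < 0) || any(ss$fraction > 1)))
    return("satellite fractions must lie in [0, 1]")
  f <- object@gad1PositiveOpcFraction
  if (f < 0 || f > 1) return("gad1PositiveOpcFraction must lie in [0, 1]")
  miss <- setdiff(object@laminarProfiles$cluster, names(object@composition))
  if (!setequal(names(object@composition), object@laminarProfiles$cluster))
    return("laminarProfiles and composition must cover the same clusters")
  TRUE
})
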