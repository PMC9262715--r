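#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @name accessors
NULL

#' @describeIn accessors the per-cell data.frame of a [CellTable].
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @describeIn accessors number of cells.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @describeIn accessors the sparse count matrix of an [ExpressionMatrix].
#' @export
setGeneric("exprCounts", function(x) standardGeneric("exprCounts"))

#' @describeIn accessors the edge data.frame of a [ContactGraph].
#' @export
setGeneric("contactEdges", function(x) standardGeneric("contactEdges"))

#' @describeIn accessors the cluster/subclass/class table of a [Taxonomy].
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @describeIn accessors the label/count/proportion table of a
#'   [CompositionResult].
#' @export
setGeneric("compositionTable", function(x) standardGeneric("compositionTable"))

#' @describeIn accessors glia:neuron ratio of a [CompositionResult].
#' @export
setGeneric("gliaToNeuron", function(x) standardGeneric("gliaToNeuron"))

#' @describeIn accessors excitatory:inhibitory ratio of a
#'   [CompositionResult].
#' @export
setGeneric("excToInh", function(x) standardGeneric("excToInh"))

#' @describeIn accessors long per-cluster depth-density table of a
#'   [DepthProfile].
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @describeIn accessors per-bin E:I table of a [DepthProfile].
#' @export
setGeneric("eiTable", function(x) standardGeneric("eiTable"))

#' @describeIn accessors list of member-id vectors of a [VesselSet].
#' @export
setGeneric("vesselMembers", function(x) standardGeneric("vesselMembers"))

#' @describeIn accessors per-vessel glial adjacency counts of a
#'   [VesselSet].
#' @export
setGeneric("vesselAdjacency", function(x) standardGeneric("vesselAdjacency"))

setMethod("cellData", "CellTable", function(x) x@cells)
setMethod("nCells", "CellTable", function(x) nrow(x@cells))
setMethod("exprCounts", "ExpressionMatrix", function(x) x@counts)
setMethod("nCells", "ExpressionMatrix", function(x) nrow(x@counts))
setMethod("contactEdges", "ContactGraph", function(x) x@edges)
setMethod("taxonomyTable", "Taxonomy", function(x) x@table)
setMethod("compositionTable", "CompositionResult", function(x) x@table)
setMethod("gliaToNeuron", "CompositionResult", function(x) x@gliaToNeuron)
setMethod("excToInh", "CompositionResult", function(x) x@excToInh)
setMethod("profileTable", "DepthProfile", function(x) x@profiles)
setMethod("eiTable", "DepthProfile", function(x) x@ei)
setMethod("vesselMembers", "VesselSet", function(x) x@vessels)
setMethod("vesselAdjacency", "VesselSet", function(x) x@adjacency)

setMethod("show", "Taxonomy", function(object) {
  tb <- object@table
  cls <- table(tb$class)
  cat("Taxonomy:", nrow(tb), "clusters across",
      length(unique(tb$subclass)), "subclasses\n")
  cat("  excitatory:", cls[["excitatory"]],
      " inhibitory:", cls[["inhibitory"]],
      " non-neuronal:", cls[["non-neuronal"]], "\n")
})

setMethod("show", "CellTable", function(object) {
  df <- object@cells
  cat("CellTable:", nrow(df), "cells")
  if (nrow(df)) {
    cat(" (", length(unique(df$subclass)), " subclasses, ",
        length(unique(df$cluster)), " clusters)", sep = "")
    cat("\n  section:", df$section_id[1], " species:", df$species[1], "\n")
  } else cat("\n")
})

setMethod("show", "ExpressionMatrix", function(object) {
  m <- object@counts
  cat("ExpressionMatrix:", nrow(m), "cells x", ncol(m), "genes;",
      length(m@x), "non-zero entries\n")
})

setMethod("show", "ContactGraph", function(object) {
  cat("ContactGraph (", object@mode, " mode): ", nrow(object@edges),
      " edges over ", length(object@cellIds), " cells\n", sep = "")
  cat("  params:", paste(names(object@params),
      unlist(object@params), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PermutationScheme", function(object) {
  cat("PermutationScheme: bin", object@binSizeUm, "um,",
      object@nPermutations, "permutations, level", object@labelLevel,
      ", seed", object@seed, "\n")
})

setMethod("show", "CompositionResult", function(object) {
  cat("CompositionResult: level", object@level, "/ denominator",
      object@denominator,
      if (object@excludeWM) "(WM excluded)" else "(WM included)", "\n")
  cat("  n =", object@nDenominator,
      "; glia:neuron =", round(object@gliaToNeuron, 3),
      "; E:I =", round(object@excToInh, 3), "\n")
  print(utils::head(object@table, 10))
})

setMethod("show", "DepthProfile", function(object) {
  cat("DepthProfile:", length(object@binEdges) - 1, "bins,",
      length(unique(object@profiles$cluster)), "profiled clusters",
      if (length(object@excluded))
        paste0("(", length(object@excluded), " excluded, too few cells)")
      else "", "\n")
})

setMethod("show", "VesselSet", function(object) {
  cat("VesselSet:", length(object@vessels), "vessels (min size",
      object@minSize, ")\n")
  if (nrow(object@summary)) print(object@summary)
})

setMethod("show", "TissueConfig", function(object) {
  cat("TissueConfig [", object@species, "/", object@sectionId, "]\n", sep = "")
  cat("  section:", object@sectionWidthUm, "x", object@sectionHeightUm,
      "um; density:", object@densityCellsPerMm2, "cells/mm^2 (expected n ~",
      round(object@densityCellsPerMm2 * object@sectionWidthUm *
            object@sectionHeightUm / 1e6), ")\n")
  cat("  clusters:", length(object@composition),
      "; hardcore:", object@hardcoreDistanceUm, "um; seed:", object@seed, "\n")
  cat("  injections:", nrow(object@satelliteSpecs), "satellite specs;",
      object@vesselSpec$n_vessels, "vessels;",
      nrow(object@ligrecSpec), "ligand-receptor boosts\n")
})
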