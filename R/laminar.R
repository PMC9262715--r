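#' Assign cortical layers from depth
#'
#' Bins normalized depth into the six laminar compartments L1, L2/3, L4,
#' L5, L6, WM using half-open intervals `[b_k, b_{k+1})`: a depth exactly
#' on a boundary belongs to the deeper layer, and any depth at or beyond
#' the last boundary is white matter.
#'
#' @param cells a [CellTable].
#' @param boundaries 5 strictly increasing boundary depths.
#' @return the [CellTable] with its `layer` column replaced.
#' @export
layerAssign <- function(cells, boundaries = .LAYER_BOUNDARIES) {
  if (any(diff(boundaries) <= 0)) stop("boundaries must be increasing")
  df <- cellData(cells)
  df$layer <- .LAYERS[findInterval(df$depth, boundaries) + 1L]
  new("CellTable", cells = df)
}

#' Cortical-depth profiles and the depth-resolved E:I curve
#'
#' Bins normalized cortical depth uniformly over `[0, maxDepth]` and
#' computes, per cluster, the binned depth density normalized to unit area,
#' and per bin the excitatory and inhibitory neuron counts, their ratio and
#' the across-bin standardized z-score of the log2 E:I curve (the log
#' stabilizes the ratio; bins with no inhibitory cells propagate as
#' missing, never infinity).
#'
#' @param cells a [CellTable] with depth present.
#' @param nBins number of uniform depth bins (>= 2), default 50.
#' @param minCells clusters with fewer cells are flagged and excluded from
#'   per-cluster profiles (still counted in the E:I curve), default 20.
#' @param maxDepth upper edge of the binning range; defaults to the
#'   maximum observed depth.
#' @return a [DepthProfile].
#' @export
depthProfiles <- function(cells, nBins = 50, minCells = 20, maxDepth = NULL) {
  if (nBins < 2) stop("nBins must be >= 2")
  df <- cellData(cells)
  if (nrow(df) == 0L) stop("no cells")
  if (is.null(maxDepth)) maxDepth <- max(df$depth)
  edges <- seq(0, maxDepth, length.out = nBins + 1)
  width <- edges[2] - edges[1]
  bin <- pmin(nBins, pmax(1L, findInterval(df$depth, edges,
                                           rightmost.closed = TRUE)))
  counts <- table(factor(df$cluster), factor(bin, levels = seq_len(nBins)))
  nPer <- rowSums(counts)
  excluded <- names(nPer)[nPer < minCells]
  keep <- setdiff(rownames(counts), excluded)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  profiles <- do.call(rbind, lapply(keep, function(cl) {
    cnt <- as.numeric(counts[cl, ])
    data.frame(cluster = cl, bin = seq_len(nBins), mid = mids, count = cnt,
               density = cnt / (nPer[[cl]] * width),
               stringsAsFactors = FALSE)
  }))
  if (is.null(profiles))
    profiles <- data.frame(cluster = character(0), bin = integer(0),
                           mid = numeric(0), count = numeric(0),
                           density = numeric(0))
  exc <- tabulate(bin[df$class == "excitatory"], nBins)
  inh <- tabulate(bin[df$class == "inhibitory"], nBins)
  ratio <- ifelse(inh > 0, exc / inh, NA_real_)
  lr <- log2(ratio)
  lr[!is.finite(lr)] <- NA
  z <- if (sum(is.finite(lr)) >= 2)
    (lr - mean(lr, na.rm = TRUE)) / sd(lr, na.rm = TRUE)
  else rep(NA_real_, nBins)
  ei <- data.frame(bin = seq_len(nBins), mid = mids, exc = exc, inh = inh,
                   ratio = ratio, log2_ratio = lr, z = z)
  cc <- as.integer(nPer); names(cc) <- names(nPer)
  new("DepthProfile", binEdges = edges, profiles = profiles, ei = ei,
      excluded = excluded, clusterCounts = cc)
}
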