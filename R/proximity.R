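#' Build a soma contact / proximity graph
#'
#' Centroid mode links two cells when their centroid distance is at most
#' `scale * (r_i + r_j)` (soma radii), the operationalization of soma
#' contact or proximity from centroid distances; boundary mode links cells
#' whose somata dilated by `tolUm` overlap (with the default circular soma
#' geometry: distance <= r_i + r_j + 2 * tolUm). Neighbor search uses
#' square-grid bucketing (sub-quadratic) and returns results identical to
#' the all-pairs rule.
#'
#' @param cells a [CellTable] (>= 2 cells; radii required).
#' @param mode `"centroid"` or `"boundary"`.
#' @param scale centroid-mode scale factor on the radius sum, default 1.1.
#' @param tolUm boundary-mode dilation tolerance in micrometres, default 1.
#' @return a [ContactGraph].
#' @examples
#' tis <- generateTissue(resizeSection(defaultHumanConfig(seed = 1), 700, 700))
#' buildContactGraph(tis$cells)
#' @export
buildContactGraph <- function(cells, mode = c("centroid", "boundary"),
                              scale = 1.1, tolUm = 1) {
  mode <- match.arg(mode)
  df <- cellData(cells)
  if (nrow(df) < 2L) stop("need at least 2 cells")
  r <- df$soma_radius_um
  if (anyNA(r)) stop("soma radii are required to build a contact graph")
  cut <- if (mode == "centroid") scale * 2 * max(r) else 2 * max(r) + 2 * tolUm
  pr <- gridNeighborPairs(df$x_um, df$y_um, cut)
  thr <- if (mode == "centroid") scale * (r[pr$a] + r[pr$b])
         else r[pr$a] + r[pr$b] + 2 * tolUm
  keep <- pr$d <= thr
  edges <- data.frame(a = df$cell_id[pr$a[keep]], b = df$cell_id[pr$b[keep]],
                      distance_um = pr$d[keep], stringsAsFactors = FALSE)
  params <- if (mode == "centroid") list(scale = scale) else list(tolUm = tolUm)
  new("ContactGraph", edges = edges, mode = mode, params = params,
      cellIds = df$cell_id)
}

#' Permutation scheme constructor
#'
#' @param binSizeUm lateral bin extent (default 100 um, several soma
#'   diameters: destroys neighbor identity while preserving lateral
#'   density).
#' @param binHeightUm depth-wise bin extent (default 25 um: laminar
#'   density varies on a scale of tens of micrometres, so depth bins must
#'   be finer than lateral bins for the within-bin shuffle to be
#'   exchangeable; set equal to `binSizeUm` for square bins).
#' @param nPermutations number of label permutations (default 1000; a
#'   warning is issued below 100, where inference is unreliable).
#' @param seed mandatory integer seed.
#' @param labelLevel `"subclass"` (default) or `"cluster"`.
#' @return a [PermutationScheme].
#' @export
permutationScheme <- function(binSizeUm = 100, binHeightUm = 25,
                              nPermutations = 1000, seed,
                              labelLevel = "subclass") {
  if (missing(seed)) stop("a seed is mandatory for permutation schemes")
  if (nPermutations < 100)
    warning("fewer than 100 permutations: null moments will be noisy")
  new("PermutationScheme", binSizeUm = binSizeUm,
      binHeightUm = binHeightUm,
      nPermutations = as.integer(nPermutations), seed = as.integer(seed),
      labelLevel = labelLevel)
}

#' Density-preserving label permutation
#'
#' Partitions cells into rectangular spatial bins (`binSizeUm` wide,
#' `binHeightUm` tall) and
#' shuffles the (subclass, cluster) label pairs among the cells of each bin
#' with positions fixed. Per-bin per-type counts are exactly preserved (the
#' local-density contract), so the permutation destroys fine-scale
#' neighbor identity while keeping each type's coarse spatial density; a
#' bin containing a single cell is a fixed point.
#'
#' @param cells a [CellTable].
#' @param scheme a [PermutationScheme]; its seed is used.
#' @return data.frame with permuted `class`, `subclass`, `cluster` columns
#'   (same row order as `cellData(cells)`).
#' @export
permuteLabels <- function(cells, scheme) {
  df <- cellData(cells)
  grp <- spatialBinGroups(df$x_um, df$y_um, scheme@binSizeUm,
                          scheme@binHeightUm)
  set.seed(scheme@seed)
  idx <- shuffleWithinBins(grp, nrow(df))
  df[idx, c("class", "subclass", "cluster"), drop = FALSE]
}

## Shared permutation engine: statFun(idx) must compute the statistic
## vector under labels[idx]; returns observed stats + null matrix
## (nPermutations x length(stat)).
runPermutations <- function(df, scheme, statFun) {
  grp <- spatialBinGroups(df$x_um, df$y_um, scheme@binSizeUm,
                          scheme@binHeightUm)
  n <- nrow(df)
  set.seed(scheme@seed)
  obs <- statFun(seq_len(n))
  null <- matrix(NA_real_, scheme@nPermutations, length(obs))
  for (b in seq_len(scheme@nPermutations))
    null[b, ] <- statFun(shuffleWithinBins(grp, n))
  list(observed = obs, null = null)
}

## Candidate pairs for permutation-side edge re-derivation: all pairs
## within the largest possible contact threshold of the graph's rule.
## Under a label permutation a cell carries its type's soma radius, so
## edges are re-filtered with permuted radii ("re-placing types at fixed
## positions" keeps the radius-dependent contact rule consistent).
.permEdgeCandidates <- function(df, graph) {
  r <- df$soma_radius_um
  if (graph@mode == "centroid") {
    s <- graph@params$scale
    cut <- s * 2 * max(r)
  } else {
    cut <- 2 * max(r) + 2 * graph@params$tolUm
  }
  pr <- gridNeighborPairs(df$x_um, df$y_um, cut)
  list(a = pr$a, b = pr$b, d = pr$d, r = r, mode = graph@mode,
       scale = graph@params$scale, tolUm = graph@params$tolUm)
}

.permEdgesFor <- function(cand, idx) {
  rp <- cand$r[idx]
  thr <- if (cand$mode == "centroid")
    cand$scale * (rp[cand$a] + rp[cand$b])
  else rp[cand$a] + rp[cand$b] + 2 * cand$tolUm
  cand$d <= thr
}

## null moments + upper-tailed normal test + empirical p + BH
.permTestTable <- function(obs, null, minExpected = 5) {
  nullMean <- colMeans(null)
  nullSd <- apply(null, 2, sd)
  z <- ifelse(nullSd > 0, (obs - nullMean) / nullSd, NA_real_)
  p <- pnorm(z, lower.tail = FALSE)
  pEmp <- (1 + colSums(sweep(null, 2, obs, ">="))) / (nrow(null) + 1)
  data.frame(observed = obs, null_mean = nullMean, null_sd = nullSd,
             fold_change = ifelse(nullMean > 0, obs / nullMean, NA_real_),
             z = z, p = p, p_empirical = pEmp,
             degenerate = nullSd == 0,
             low_power = nullMean < minExpected)
}

#' Pairwise soma-contact enrichment
#'
#' For every unordered pair of cell-type labels, compares the observed
#' number of contact-graph edges joining the two types against the null
#' distribution obtained from density-preserving label permutations:
#' relabeling cells at fixed positions is equivalent to re-placing the
#' types, so each permuted label carries its soma radius and contact
#' edges are re-derived under the permuted radii (with a radius-dependent
#' contact rule, freezing the edges would leave large-soma types with
#' structurally more same-type edges than any relabeling could produce,
#' inflating false positives). Reports fold change
#' (observed / null mean), upper-tailed Z-test p-value, the empirical
#' permutation p-value for auditability, and BH-adjusted FDR over all
#' reported pairs of the analysis. Pairs with degenerate null (sd 0) are
#' flagged with undefined p; pairs with null mean below `minExpected` are
#' flagged `low_power`.
#'
#' @param cells a [CellTable].
#' @param graph a [ContactGraph] built on these cells.
#' @param scheme a [PermutationScheme].
#' @param minExpected flag threshold on the null mean, default 5.
#' @return data.frame with one row per label pair (`label_a`, `label_b`,
#'   `observed`, `null_mean`, `null_sd`, `fold_change`, `z`, `p`,
#'   `p_empirical`, `fdr`, flags).
#' @export
pairwiseEnrichment <- function(cells, graph, scheme, minExpected = 5) {
  df <- cellData(cells)
  ed <- contactEdges(graph)
  ia <- match(ed$a, df$cell_id); ib <- match(ed$b, df$cell_id)
  if (anyNA(ia) || anyNA(ib))
    stop("graph references cells absent from the table")
  labs <- df[[scheme@labelLevel]]
  lev <- sort(unique(labs))
  K <- length(lev)
  lab <- match(labs, lev)
  cand <- .permEdgeCandidates(df, graph)
  statFun <- function(idx) {
    lp <- lab[idx]
    keep <- .permEdgesFor(cand, idx)
    tabulate(pairKey(lp[cand$a[keep]], lp[cand$b[keep]], K), K * K)
  }
  res <- runPermutations(df, scheme, statFun)
  ## report every unordered pair of observed labels
  km <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  keys <- (km[, "row"] - 1L) * K + km[, "col"]   # pairKey(i, j), i <= j
  tab <- .permTestTable(res$observed[keys], res$null[, keys, drop = FALSE],
                        minExpected)
  out <- cbind(data.frame(label_a = lev[km[, "row"]],
                          label_b = lev[km[, "col"]],
                          stringsAsFactors = FALSE), tab)
  out$fdr <- bhAdjust(out$p)
  out
}

#' Nearest-neighbor self/other distance test
#'
#' For every cell, computes the distance to its nearest neighbor of the
#' same label ("to self") and of any different label ("to other"); per
#' label, tests whether to-self distances are stochastically smaller than
#' to-other distances (one-sided Wilcoxon rank-sum), the signature of a
#' tendency to form pairs within the same type. Labels with fewer than
#' `minCells` cells are excluded; BH correction is applied across labels.
#'
#' @param cells a [CellTable] (>= 2 cells per tested label).
#' @param level `"subclass"` (default) or `"cluster"`.
#' @param minCells minimum cells per tested label, default 20.
#' @return data.frame per label: `label`, `n`, `median_self`,
#'   `median_other`, `p`, `fdr`; the per-cell distance vectors are
#'   attached as attribute `"distances"` (data.frame `cell_id`, `label`,
#'   `d_self`, `d_other`).
#' @export
nnDistanceTest <- function(cells, level = "subclass", minCells = 20) {
  df <- cellData(cells)
  labs <- df[[level]]
  nn <- .nnSelfOther(df$x_um, df$y_um, labs)
  keepLab <- names(which(table(labs) >= max(2, minCells)))
  res <- do.call(rbind, lapply(keepLab, function(L) {
    sel <- labs == L
    ds <- nn$dSelf[sel]; do <- nn$dOther[sel]
    ok <- is.finite(ds) & is.finite(do)
    if (sum(ok) < 2)
      return(data.frame(label = L, n = sum(sel), median_self = NA_real_,
                        median_other = NA_real_, p = NA_real_))
    p <- wilcox.test(ds[ok], do[ok], alternative = "less",
                     exact = FALSE)$p.value
    data.frame(label = L, n = sum(sel),
               median_self = stats::median(ds[ok]),
               median_other = stats::median(do[ok]), p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(label = character(0), n = integer(0),
                      median_self = numeric(0), median_other = numeric(0),
                      p = numeric(0))
  res$fdr <- bhAdjust(res$p)
  rownames(res) <- NULL
  attr(res, "distances") <- data.frame(cell_id = df$cell_id, label = labs,
                                       d_self = nn$dSelf,
                                       d_other = nn$dOther,
                                       stringsAsFactors = FALSE)
  res
}

## nearest-neighbor distance within one point set: escalating grid radius
## with a brute-force fallback for stragglers.
.nnWithin <- function(xs, ys) {
  m <- length(xs)
  out <- rep(Inf, m)
  if (m < 2L) return(out)
  if (m <= 400L) {
    d2 <- outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2
    diag(d2) <- Inf
    return(sqrt(apply(d2, 1, min)))
  }
  area <- max(1e-9, diff(range(xs)) * diff(range(ys)))
  R <- max(1e-6, 2 / sqrt(m / area))
  maxR <- sqrt(diff(range(xs))^2 + diff(range(ys))^2) + 1
  for (iter in 1:6) {
    pr <- gridNeighborPairs(xs, ys, R)
    if (nrow(pr)) {
      both <- data.table(i = c(pr$a, pr$b), d = c(pr$d, pr$d))
      mn <- both[, list(d = min(d)), by = "i"]
      out[mn$i] <- mn$d
    }
    if (all(is.finite(out)) || R > maxR) break
    R <- R * 2
  }
  for (i in which(!is.finite(out))) {
    d2 <- (xs - xs[i])^2 + (ys - ys[i])^2
    d2[i] <- Inf
    out[i] <- sqrt(min(d2))
  }
  out
}

## nearest same-label ("to self") and different-label ("to other")
## neighbor distances. To-other is resolved on all cells jointly (the
## complement of any label is dense, so a small radius suffices); to-self
## is resolved per label on that label's own points.
.nnSelfOther <- function(x, y, labs) {
  n <- length(x)
  dSelf <- rep(Inf, n); dOther <- rep(Inf, n)
  if (n < 2L) return(list(dSelf = dSelf, dOther = dOther))
  area <- max(1e-9, diff(range(x)) * diff(range(y)))
  R <- max(1e-6, 2 / sqrt(n / area))
  maxR <- sqrt(diff(range(x))^2 + diff(range(y))^2) + 1
  for (iter in 1:6) {
    pr <- gridNeighborPairs(x, y, R)
    if (nrow(pr)) {
      both <- data.table(i = c(pr$a, pr$b), j = c(pr$b, pr$a),
                         d = c(pr$d, pr$d))
      mo <- both[labs[both$i] != labs[both$j], list(d = min(d)), by = "i"]
      dOther[mo$i] <- mo$d
    }
    if (all(is.finite(dOther)) || R > maxR) break
    R <- R * 2
  }
  for (i in which(!is.finite(dOther))) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf
    keep <- labs != labs[i]
    if (any(keep)) dOther[i] <- sqrt(min(d2[keep]))
  }
  for (L in unique(labs)) {
    idx <- which(labs == L)
    if (length(idx) >= 2L) dSelf[idx] <- .nnWithin(x[idx], y[idx])
  }
  list(dSelf = dSelf, dOther = dOther)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment, monotone and capped at 1.
#' NA/NaN inputs yield NA outputs and are excluded from the number of
#' tests.
#'
#' @param p vector of p-values in \\[0, 1\\] (NAs allowed).
#' @return vector of BH-adjusted values, same length and order.
#' @export
bhAdjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
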