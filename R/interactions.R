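#' Detect blood vessels and count adjacent glia
#'
#' Blood vessels are the connected components, with at least `minSize`
#' cells, of the contact graph restricted to endothelial and mural cells
#' (a vascular "structure" rather than an isolated cell). For each vessel
#' the number of glial cells of each subclass in contact with any member
#' is counted, and per-subclass mean and sd across vessels are summarized.
#'
#' @param cells a [CellTable].
#' @param graph a [ContactGraph] built on these cells.
#' @param minSize minimum component size, default 3.
#' @param gliaSubclasses glial subclasses to count, default ASC, OGC, OPC,
#'   MGC.
#' @return a [VesselSet].
#' @export
detectVessels <- function(cells, graph, minSize = 3,
                          gliaSubclasses = c("ASC", "OGC", "OPC", "MGC")) {
  df <- cellData(cells)
  vascIds <- df$cell_id[df$subclass %in% .vascularSubclasses]
  ed <- contactEdges(graph)
  ve <- ed[ed$a %in% vascIds & ed$b %in% vascIds, , drop = FALSE]
  comps <- list()
  if (length(vascIds)) {
    g <- igraph::graph_from_data_frame(ve[, c("a", "b")], directed = FALSE,
                                       vertices = vascIds)
    cm <- igraph::components(g)
    comps <- split(names(cm$membership), cm$membership)
    comps <- unname(comps[lengths(comps) >= minSize])
  }
  adj <- data.frame(vessel = integer(0), subclass = character(0),
                    count = integer(0), stringsAsFactors = FALSE)
  if (length(comps)) {
    vesselOf <- integer(0)
    vesselOf[unlist(comps)] <- rep(seq_along(comps), lengths(comps))
    memb <- setNames(rep(seq_along(comps), lengths(comps)), unlist(comps))
    gliaIds <- df$cell_id[df$subclass %in% gliaSubclasses]
    touch <- rbind(
      data.frame(g = ed$a, m = ed$b, stringsAsFactors = FALSE),
      data.frame(g = ed$b, m = ed$a, stringsAsFactors = FALSE))
    touch <- touch[touch$g %in% gliaIds & touch$m %in% names(memb), ,
                   drop = FALSE]
    touch$vessel <- memb[touch$m]
    touch <- unique(touch[, c("g", "vessel")])
    touch$subclass <- df$subclass[match(touch$g, df$cell_id)]
    grid <- expand.grid(vessel = seq_along(comps),
                        subclass = gliaSubclasses,
                        stringsAsFactors = FALSE)
    cnt <- table(factor(touch$vessel, levels = seq_along(comps)),
                 factor(touch$subclass, levels = gliaSubclasses))
    adj <- data.frame(vessel = grid$vessel, subclass = grid$subclass,
                      count = as.integer(cnt[cbind(as.character(grid$vessel),
                                                   grid$subclass)]),
                      stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, lapply(gliaSubclasses, function(s) {
    v <- adj$count[adj$subclass == s]
    data.frame(subclass = s,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  new("VesselSet", vessels = comps, adjacency = adj, summary = summ,
      minSize = as.integer(minSize))
}

#' Multiway contact test
#'
#' Tests whether single focal cells (by default, all neurons) form
#' contacts with unusually many distinct partner cells of the given
#' subclasses (by default oligodendrocytes and/or OPCs). For each k the
#' statistic is the number of focal cells with at least k distinct
#' partner-type contacts; the null comes from the same density-preserving
#' label permutations as [pairwiseEnrichment()], with upper-tailed Z-test
#' p-values BH-adjusted across the tested k values.
#'
#' @param cells a [CellTable].
#' @param graph a [ContactGraph] built on these cells.
#' @param focalClasses classes defining focal cells, default both neuronal
#'   classes.
#' @param partnerSubclasses partner subclasses (union), default OGC + OPC.
#' @param scheme a [PermutationScheme].
#' @param kMax largest k tested (k = 2..kMax), default 5.
#' @return data.frame per k: `k`, `observed`, null moments, `fold_change`,
#'   `z`, `p`, `p_empirical`, `fdr`.
#' @export
multiwayContactTest <- function(cells, graph,
                                focalClasses = c("excitatory", "inhibitory"),
                                partnerSubclasses = c("OGC", "OPC"),
                                scheme, kMax = 5) {
  df <- cellData(cells)
  ks <- 2:kMax
  cand <- .permEdgeCandidates(df, graph)
  statFun <- function(idx) {
    cls <- df$class[idx]; sub <- df$subclass[idx]
    isF <- cls %in% focalClasses
    isP <- sub %in% partnerSubclasses
    keep <- .permEdgesFor(cand, idx)
    ia <- cand$a[keep]; ib <- cand$b[keep]
    focal <- c(ia[isF[ia] & isP[ib]], ib[isF[ib] & isP[ia]])
    cnt <- tabulate(focal, nrow(df))
    vapply(ks, function(k) sum(cnt >= k), numeric(1))
  }
  res <- runPermutations(df, scheme, statFun)
  tab <- .permTestTable(res$observed, res$null, minExpected = 0)
  out <- cbind(data.frame(k = ks), tab)
  out$low_power <- NULL
  out$fdr <- bhAdjust(out$p)
  out
}

#' GAD1-positive OPC fraction
#'
#' Classifies oligodendrocyte precursor cells as GAD1-positive when their
#' GAD1 transcript count reaches `minCount` (default 1; imaging-based
#' counts are near-binary for low expressors) and returns the positive
#' fraction. When GAD2 / SLC32A1 are present in the panel their near
#' absence in OPCs is verified (mean count reported, warning if > 0.1).
#' Sensitivity of the fraction to `minCount` 1..3 is attached.
#'
#' @param cells a [CellTable] with OPCs present.
#' @param expr an [ExpressionMatrix] with GAD1 in the gene panel.
#' @param minCount detection threshold in transcript counts, default 1.
#' @return list: `fraction`, `n_opc`, `flags` (named logical per OPC),
#'   `sensitivity` (fraction at thresholds 1..3), `gabaergic_controls`
#'   (mean OPC counts of GAD2/SLC32A1 when present).
#' @export
gad1OpcFraction <- function(cells, expr, minCount = 1) {
  df <- cellData(cells)
  m <- exprCounts(expr)
  if (!"GAD1" %in% colnames(m)) stop("gene GAD1 missing from the panel")
  opc <- df$cell_id[df$subclass == "OPC"]
  opc <- intersect(opc, rownames(m))
  if (!length(opc)) stop("no OPC cells present")
  g1 <- m[opc, "GAD1"]
  flags <- setNames(g1 >= minCount, opc)
  sens <- vapply(1:3, function(t) mean(g1 >= t), numeric(1))
  names(sens) <- paste0("min_count_", 1:3)
  ctrl <- numeric(0)
  for (g in intersect(c("GAD2", "SLC32A1"), colnames(m))) {
    ctrl[g] <- mean(m[opc, g])
    if (ctrl[g] > 0.1)
      warning("unexpected OPC expression of ", g,
              " (mean count ", round(ctrl[g], 3), ")")
  }
  list(fraction = mean(flags), n_opc = length(opc), flags = flags,
       sensitivity = sens, gabaergic_controls = ctrl)
}

#' Depth-dependent contact enrichment
#'
#' For an ordered set of focal groups (by convention IT subclasses from
#' superficial to deep, plus inhibitory neurons), compares the observed
#' number of contacts with a partner subclass (default microglia) to the
#' density-preserving permutation null, reporting the distribution of
#' observed/expected ratios across permutations and a monotone-trend
#' summary (Spearman correlation of the median ratio against depth order).
#'
#' @param cells a [CellTable].
#' @param graph a [ContactGraph] built on these cells.
#' @param focalGroups ordered character vector of group names (subclass,
#'   class, `"IT"` or `"neurons"`).
#' @param partnerSubclass single partner subclass, default `"MGC"`.
#' @param scheme a [PermutationScheme].
#' @param taxonomy a [Taxonomy] for group resolution.
#' @return data.frame per focal group (in the given order): `group`,
#'   `order`, `observed`, `null_mean`, `null_sd`, `fold_change`,
#'   `ratio_median`, `ratio_q25`, `ratio_q75`, `z`, `p`, `fdr`; attribute
#'   `"trend_spearman"` holds the Spearman correlation of median ratio vs
#'   order.
#' @export
contactByDepth <- function(cells, graph,
                           focalGroups = c("L2/3 IT", "L4/5 IT", "L5 IT",
                                           "L6 IT", "inhibitory"),
                           partnerSubclass = "MGC", scheme,
                           taxonomy = humanTaxonomy()) {
  df <- cellData(cells)
  groupSubs <- lapply(focalGroups, resolveGroup, taxonomy = taxonomy)
  cand <- .permEdgeCandidates(df, graph)
  statFun <- function(idx) {
    sub <- df$subclass[idx]
    isP <- sub == partnerSubclass
    keep <- .permEdgesFor(cand, idx)
    ia <- cand$a[keep]; ib <- cand$b[keep]
    vapply(groupSubs, function(gs) {
      isF <- sub %in% gs
      sum((isF[ia] & isP[ib]) | (isF[ib] & isP[ia]))
    }, numeric(1))
  }
  res <- runPermutations(df, scheme, statFun)
  tab <- .permTestTable(res$observed, res$null, minExpected = 0)
  ratios <- sweep(1 / pmax(res$null, 0.5), 2, res$observed, "*")
  out <- cbind(data.frame(group = focalGroups,
                          order = seq_along(focalGroups),
                          stringsAsFactors = FALSE), tab)
  out$low_power <- NULL
  out$ratio_median <- apply(ratios, 2, stats::median)
  out$ratio_q25 <- apply(ratios, 2, quantile, 0.25)
  out$ratio_q75 <- apply(ratios, 2, quantile, 0.75)
  out$fdr <- bhAdjust(out$p)
  attr(out, "trend_spearman") <-
    suppressWarnings(cor(out$ratio_median, out$order, method = "spearman"))
  out
}

#' Contact-conditioned ligand-receptor enrichment
#'
#' Scores each directed (ligand, receptor) pair over contacting
#' sender -> receiver cell pairs as the mean of
#' `n_L(sender) * n_R(receiver)` with `n` the library-size-normalized
#' expression, and compares it against `nPermutations` random
#' re-pairings: one null cell is drawn per distinct observed cell, from
#' the depth bin of the cell it replaces (removing laminar confounding),
#' and reused with the observed multiplicity so the null score has the
#' observed score's effective sample size. By default null cells are
#' drawn from all sender/receiver-type cells regardless of contact
#' status (an exchangeability null, calibrated by construction);
#' `nullPool = "noncontacting"` restricts draws to non-contacting cells
#' for a direct contacting-vs-non-interacting contrast at the price of
#' slightly inflated tails. Fold change and an
#' upper-tailed Z are reported per pair; because the mean-of-products
#' score is heavy-tailed, the BH FDR across tested pairs is computed from
#' the empirical permutation p-value (the Z is descriptive).
#' Sender -> receiver and receiver -> sender orientations are separate
#' analyses.
#'
#' @param cells a [CellTable].
#' @param expr an [ExpressionMatrix] on (a superset of) these cells.
#' @param graph a [ContactGraph] built on these cells.
#' @param pairs data.frame with columns `ligand`, `receptor` (see
#'   [demoLigRecPairs()]).
#' @param senderType,receiverType group names (subclass, class, `"IT"`).
#' @param scheme a [PermutationScheme] (its seed and permutation count are
#'   used; spatial bins are not).
#' @param nDepthBins depth bins used to match null senders, default 50
#'   (the laminar-module default).
#' @param minPairs minimum number of contacting sender-receiver pairs,
#'   default 10; fewer is a low-power error.
#' @param minTotalCounts QC floor: cells with fewer total transcript
#'   counts are excluded from scoring and from the null pools (their
#'   normalized expression is numerically unstable), default 15.
#' @param nullPool `"all"` (default, exchangeability null) or
#'   `"noncontacting"` (contacting-vs-non-interacting contrast).
#' @param scale library-size normalization target, default 1000.
#' @param taxonomy a [Taxonomy] for group resolution.
#' @return data.frame per pair: `ligand`, `receptor`, `observed`,
#'   `null_mean`, `null_sd`, `fold_change`, `z`, `p`, `p_empirical`,
#'   `fdr`, `n_contacting`.
#' @export
ligrecEnrichment <- function(cells, expr, graph, pairs = demoLigRecPairs(),
                             senderType, receiverType, scheme,
                             nDepthBins = 50, minPairs = 10,
                             minTotalCounts = 15, scale = 1000,
                             nullPool = c("all", "noncontacting"),
                             taxonomy = humanTaxonomy()) {
  nullPool <- match.arg(nullPool)
  df <- cellData(cells)
  miss <- setdiff(unique(c(pairs$ligand, pairs$receptor)),
                  colnames(exprCounts(expr)))
  if (length(miss))
    stop("genes missing from the panel: ", paste(miss, collapse = ", "))
  nm <- normalizeExpression(expr, scale)
  tot <- Matrix::rowSums(exprCounts(expr))
  nm <- nm[df$cell_id, , drop = FALSE]
  qcOk <- tot[df$cell_id] >= minTotalCounts
  sSub <- resolveGroup(senderType, taxonomy)
  rSub <- resolveGroup(receiverType, taxonomy)
  isS <- df$subclass %in% sSub & qcOk
  isR <- df$subclass %in% rSub & qcOk
  ed <- contactEdges(graph)
  ia <- match(ed$a, df$cell_id); ib <- match(ed$b, df$cell_id)
  sIdx <- c(ia[isS[ia] & isR[ib]], ib[isS[ib] & isR[ia]])
  rIdx <- c(ib[isS[ia] & isR[ib]], ia[isS[ib] & isR[ia]])
  mObs <- length(sIdx)
  if (mObs < minPairs)
    stop("only ", mObs, " contacting sender-receiver pairs (need >= ",
         minPairs, "): analysis is underpowered")
  ## depth bins over the section; null senders/receivers are drawn from
  ## the observed sender's bin among non-contacting cells of each type
  edges <- seq(0, max(df$depth) + 1e-9, length.out = nDepthBins + 1)
  binOf <- pmin(nDepthBins, pmax(1L, findInterval(df$depth, edges,
                                                  rightmost.closed = TRUE)))
  ## exchangeability null (default): pools contain ALL sender/receiver
  ## cells of the right type (contact status ignored), so under
  ## independence of expression and contact the observed pair set is one
  ## draw from the same universe the null samples -- restricting pools to
  ## non-contacting cells makes the test a finite-pool two-sample
  ## comparison and inflates its tails
  if (nullPool == "all") {
    allS <- which(isS); allR <- which(isR)
  } else {
    allS <- setdiff(which(isS), unique(sIdx))
    allR <- setdiff(which(isR), unique(rIdx))
  }
  if (!length(allS) || !length(allR))
    stop("no sender or receiver cells for the null")
  poolS <- split(allS, binOf[allS])
  poolR <- split(allR, binOf[allR])
  nearestPool <- function(pool, b) {
    avail <- as.integer(names(pool))
    pool[[as.character(avail[which.min(abs(avail - b))])]]
  }
  L <- as.matrix(nm[, unique(pairs$ligand), drop = FALSE])
  R <- as.matrix(nm[, unique(pairs$receptor), drop = FALSE])
  scorePairs <- function(si, ri) {
    vapply(seq_len(nrow(pairs)), function(k)
      mean(L[si, pairs$ligand[k]] * R[ri, pairs$receptor[k]]), numeric(1))
  }
  obs <- scorePairs(sIdx, rIdx)
  ## null re-pairings preserve the observed duplication structure: one
  ## null cell is drawn per distinct observed cell (depth-bin matched)
  ## and reused with the same multiplicity, so the null score has the
  ## same effective sample size as the observed score
  uS <- unique(sIdx); uR <- unique(rIdx)
  sPos <- match(sIdx, uS); rPos <- match(rIdx, uR)
  drawLike <- function(cellsIdx, pool) {
    out <- integer(length(cellsIdx))
    bins <- binOf[cellsIdx]
    for (bb in unique(bins)) {
      w <- which(bins == bb)
      pp <- nearestPool(pool, bb)
      out[w] <- pp[sample.int(length(pp), length(w), replace = TRUE)]
    }
    out
  }
  set.seed(scheme@seed)
  B <- scheme@nPermutations
  null <- matrix(NA_real_, B, nrow(pairs))
  for (b in seq_len(B)) {
    su <- drawLike(uS, poolS)
    ru <- drawLike(uR, poolR)
    null[b, ] <- scorePairs(su[sPos], ru[rPos])
  }
  tab <- .permTestTable(obs, null, minExpected = 0)
  out <- cbind(pairs[, c("ligand", "receptor")], tab)
  out$low_power <- NULL
  out$n_contacting <- mObs
  ## the mean-of-products score is heavy-tailed, so the FDR is computed
  ## from the empirical permutation p; the upper-tailed Z is kept as a
  ## descriptive effect summary
  out$fdr <- bhAdjust(out$p_empirical)
  rownames(out) <- NULL
  out
}
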