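test_that("vessel detection: empty, hand-built, and oracle equivalence", {
  # no vascular cells -> empty set
  ct0 <- makeCells(x = 1:5 * 30, y = rep(0, 5), subclass = "ASC")
  v0 <- detectVessels(ct0, buildContactGraph(ct0))
  expect_length(vesselMembers(v0), 0)
  # chain of 5 ENDO at contact spacing plus 2 touching microglia
  ct <- makeCells(x = c(0, 8, 16, 24, 32, 0, 32, 200),
                  y = c(0, 0, 0, 0, 0, 8, 8, 200),
                  subclass = c(rep("ENDO", 5), "MGC", "MGC", "MGC"),
                  radius = 4)
  g <- buildContactGraph(ct)
  vs <- detectVessels(ct, g, minSize = 3)
  expect_length(vesselMembers(vs), 1)
  adj <- vesselAdjacency(vs)
  expect_equal(adj$count[adj$subclass == "MGC"], 2)
  expect_equal(vs@summary$mean[vs@summary$subclass == "MGC"], 2)
  # isolated vascular cells below minSize are not vessels
  ct2 <- makeCells(x = c(0, 100, 200), y = rep(0, 3), subclass = "ENDO")
  expect_length(vesselMembers(detectVessels(ct2, buildContactGraph(ct2))), 0)
})

test_that("vessel components equal brute-force union-find on real sections", {
  tis <- demoHumanTissue()
  g <- demoHumanGraph()
  vs <- detectVessels(tis$cells, g, minSize = 3)
  df <- cellData(tis$cells)
  vasc <- df$cell_id[df$subclass %in% c("ENDO", "MURAL")]
  ed <- contactEdges(g)
  ve <- ed[ed$a %in% vasc & ed$b %in% vasc, ]
  comps <- bruteComponents(vasc, ve$a, ve$b)
  comps <- comps[lengths(comps) >= 3]
  expect_equal(sort(vapply(vesselMembers(vs),
                           function(v) paste(sort(v), collapse = "|"),
                           character(1))),
               sort(vapply(comps,
                           function(v) paste(sort(v), collapse = "|"),
                           character(1))))
})

test_that("multiway observed counts match hand construction and tail identity", {
  # one neuron touching exactly 3 OGC; everything else isolated
  ct <- makeCells(x = c(0, 10, -10, 0, 300, 400),
                  y = c(0, 0, 0, 10, 300, 400),
                  subclass = c("L5 IT", "OGC", "OGC", "OGC", "SST", "OGC"),
                  radius = 5)
  g <- buildContactGraph(ct)
  sch <- suppressWarnings(permutationScheme(nPermutations = 50, seed = 2))
  mw <- multiwayContactTest(ct, g, scheme = sch, kMax = 4)
  expect_equal(mw$observed, c(1, 1, 0))
  # no partner cells -> all-zero observed
  ct2 <- makeCells(x = 1:4 * 9, y = rep(0, 4), subclass = "L5 IT")
  mw2 <- multiwayContactTest(ct2, buildContactGraph(ct2), scheme = sch,
                             kMax = 3)
  expect_equal(mw2$observed, c(0, 0))
  # tail identity on a real section: observed(k) equals the histogram
  # tail of per-focal distinct partner counts, recomputed independently
  tis <- demoHumanTissue()
  gH <- demoHumanGraph()
  schH <- permutationScheme(nPermutations = 100, seed = 3)
  mwH <- multiwayContactTest(tis$cells, gH, scheme = schH, kMax = 5)
  df <- cellData(tis$cells)
  ed <- contactEdges(gH)
  isN <- setNames(df$class %in% c("excitatory", "inhibitory"), df$cell_id)
  isP <- setNames(df$subclass %in% c("OGC", "OPC"), df$cell_id)
  focal <- c(ed$a[isN[ed$a] & isP[ed$b]], ed$b[isN[ed$b] & isP[ed$a]])
  cnt <- table(focal)
  expect_equal(mwH$observed,
               vapply(2:5, function(k) sum(cnt >= k), numeric(1)))
  expect_true(all(diff(mwH$observed) <= 0))
})

test_that("GAD1+ OPC classification matches hand counts", {
  ct <- makeCells(x = 1:4 * 30, y = rep(0, 4), subclass = "OPC")
  counts <- Matrix::Matrix(matrix(c(0, 0, 3, 5), 4, 1,
                                  dimnames = list(cellData(ct)$cell_id,
                                                  "GAD1")), sparse = TRUE)
  expr <- new("ExpressionMatrix",
              counts = methods::as(counts, "CsparseMatrix"))
  res <- gad1OpcFraction(ct, expr, minCount = 1)
  expect_equal(res$fraction, 0.5)
  expect_equal(res$n_opc, 4)
  expect_equal(unname(res$sensitivity), c(0.5, 0.5, 0.5))
  zero <- expr
  zero@counts[] <- 0
  expect_equal(gad1OpcFraction(ct, zero)$fraction, 0)
  noGene <- new("ExpressionMatrix", counts = methods::as(
    Matrix::Matrix(counts, dimnames = list(rownames(counts), "OTHER")),
    "CsparseMatrix"))
  expect_error(gad1OpcFraction(ct, noGene), "GAD1")
  expect_true(all(diff(gad1OpcFraction(ct, expr)$sensitivity) <= 0))
})

test_that("depth-contact ratios are near one under random labels", {
  set.seed(12)
  n <- 4000
  ct <- makeCells(x = runif(n, 0, 2000), y = runif(n, 0, 1000),
                  subclass = sample(c(itSubclasses[1:4], "SST", "MGC"),
                                    n, TRUE),
                  depth = runif(n))
  g <- buildContactGraph(ct)
  sch <- permutationScheme(nPermutations = 200, seed = 13)
  dc <- contactByDepth(ct, g, scheme = sch)
  expect_true(all(abs(dc$fold_change - 1) < 0.35))
  expect_true(all(dc$fdr > 0.01))
})

test_that("depth-contact expected frequency matches exhaustive enumeration", {
  xs <- c(0, 9, 20, 29, 40, 49)
  labs <- c("L2/3 IT", "MGC", "SST", "MGC", "L2/3 IT", "SST")
  ct <- makeCells(x = xs, y = rep(0, 6), subclass = labs, radius = 5)
  g <- buildContactGraph(ct)
  sch <- permutationScheme(binSizeUm = 1000, binHeightUm = 1000,
                           nPermutations = 3000, seed = 21)
  dc <- contactByDepth(ct, g, focalGroups = "L2/3 IT", scheme = sch)
  df <- cellData(ct)
  ed <- bruteForceEdges(df)
  ia <- match(ed$a, df$cell_id); ib <- match(ed$b, df$cell_id)
  stats <- vapply(allPermutations(1:6), function(idx) {
    lp <- labs[idx]
    sum((lp[ia] == "L2/3 IT" & lp[ib] == "MGC") |
        (lp[ib] == "L2/3 IT" & lp[ia] == "MGC"))
  }, numeric(1))
  tol <- 3 * sd(stats) / sqrt(sch@nPermutations)
  expect_lt(abs(dc$null_mean - mean(stats)), tol + 1e-12)
})

test_that("ligand-receptor toy example matches hand arithmetic", {
  # two contacting sender-receiver pairs with normalized L=2, R=3; all
  # non-contacting pool cells sit at L=1, R=1 (scale 10)
  xs <- c(0, 10, 60, 70, 200, 220, 240, 260, 300, 320, 340, 360)
  sub <- c("MGC", "L2/3 IT", "MGC", "L2/3 IT",
           rep("MGC", 4), rep("L2/3 IT", 4))
  ct <- makeCells(x = xs, y = rep(0, 12), subclass = sub, radius = 5,
                  depth = rep(0.5, 12))
  ids <- cellData(ct)$cell_id
  cnt <- matrix(0, 12, 3, dimnames = list(ids, c("LIG", "REC", "PAD")))
  cnt[, "PAD"] <- 10
  cnt[sub == "MGC", "LIG"] <- 1; cnt[sub == "L2/3 IT", "REC"] <- 1
  cnt[c(1, 3), "LIG"] <- 2; cnt[c(2, 4), "REC"] <- 3
  cnt[, "PAD"] <- 10 - cnt[, "LIG"] - cnt[, "REC"]   # totals all 10
  expr <- new("ExpressionMatrix",
              counts = methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                   "CsparseMatrix"))
  g <- buildContactGraph(ct)
  expect_equal(nrow(contactEdges(g)), 2)
  sch <- suppressWarnings(permutationScheme(nPermutations = 50, seed = 3))
  res <- ligrecEnrichment(ct, expr, g,
                          pairs = data.frame(ligand = "LIG",
                                             receptor = "REC"),
                          senderType = "MGC", receiverType = "L2/3 IT",
                          scheme = sch, nDepthBins = 1, minPairs = 2,
                          minTotalCounts = 0, scale = 10,
                          nullPool = "noncontacting")
  expect_equal(res$observed, 6)
  expect_equal(res$null_mean, 1)
  expect_equal(res$fold_change, 6)
  # low-power guard
  expect_error(ligrecEnrichment(ct, expr, g,
                                pairs = data.frame(ligand = "LIG",
                                                   receptor = "REC"),
                                senderType = "MGC",
                                receiverType = "L2/3 IT", scheme = sch,
                                nDepthBins = 1, minPairs = 10),
               "underpowered")
})

test_that("ligrec fold is invariant to global library rescaling", {
  tis <- demoHumanTissue()
  g <- demoHumanGraph()
  sch <- permutationScheme(nPermutations = 100, seed = 17)
  base <- ligrecEnrichment(tis$cells, tis$expression, g,
                           senderType = "MGC", receiverType = "IT",
                           scheme = sch)
  scaled <- new("ExpressionMatrix", counts = exprCounts(tis$expression) * 3)
  res2 <- ligrecEnrichment(tis$cells, scaled, g, senderType = "MGC",
                           receiverType = "IT", scheme = sch,
                           minTotalCounts = 45)
  expect_equal(res2$fold_change, base$fold_change, tolerance = 1e-9)
  expect_equal(res2$observed, base$observed, tolerance = 1e-9)
})
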