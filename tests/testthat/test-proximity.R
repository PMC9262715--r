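test_that("centroid and boundary contact rules match their definitions", {
  ct <- makeCells(x = c(0, 10.5), y = c(0, 0), subclass = c("SST", "VIP"),
                  radius = 5)
  g <- buildContactGraph(ct, scale = 1.1)
  expect_equal(nrow(contactEdges(g)), 1)   # threshold 11.0
  far <- makeCells(x = c(0, 100), y = c(0, 0), subclass = c("SST", "VIP"),
                   radius = 5)
  expect_equal(nrow(contactEdges(buildContactGraph(far))), 0)
  # boundary mode: dilated somata overlap iff d <= r_i + r_j + 2 tol
  bd <- makeCells(x = c(0, 11.5), y = c(0, 0), subclass = c("SST", "VIP"),
                  radius = 5)
  expect_equal(nrow(contactEdges(buildContactGraph(bd, mode = "boundary",
                                                   tolUm = 1))), 1)
  expect_equal(nrow(contactEdges(buildContactGraph(bd, mode = "boundary",
                                                   tolUm = 0.5))), 0)
})

test_that("grid-bucketed edge search equals the all-pairs oracle (500 cells)", {
  set.seed(7)
  n <- 500
  df <- cellData(makeCells(x = runif(n, 0, 400), y = runif(n, 0, 400),
                           subclass = sample(c("SST", "ASC", "OGC"), n, TRUE),
                           radius = runif(n, 3, 8)))
  ct <- new("CellTable", cells = df)
  for (mode in c("centroid", "boundary")) {
    got <- contactEdges(buildContactGraph(ct, mode = mode))
    want <- bruteForceEdges(df, mode = mode)
    expect_setequal(edgeKey(got$a, got$b), edgeKey(want$a, want$b))
    ord <- match(edgeKey(got$a, got$b), edgeKey(want$a, want$b))
    expect_equal(got$distance_um, want$d[ord], tolerance = 1e-9)
  }
})

test_that("label permutation preserves per-bin multisets and fixed points", {
  tis <- smallHumanTissue()
  df <- cellData(tis$cells)
  sch <- permutationScheme(binSizeUm = 100, binHeightUm = 25,
                           nPermutations = 100, seed = 5)
  perm <- permuteLabels(tis$cells, sch)
  # global conservation
  expect_equal(table(perm$subclass), table(df$subclass))
  expect_equal(table(perm$cluster), table(df$cluster))
  # per-bin multiset conservation, and joint (subclass, cluster) pairing
  bin <- paste(floor(df$x_um / 100), floor(df$y_um / 25))
  for (b in unique(bin)) {
    sel <- bin == b
    expect_equal(sort(perm$cluster[sel]), sort(df$cluster[sel]))
  }
  expect_equal(perm$subclass,
               taxonomyTable(humanTaxonomy())$subclass[
                 match(perm$cluster, taxonomyTable(humanTaxonomy())$cluster)])
  # a single-cell bin is a fixed point
  lone <- makeCells(x = c(1, 500), y = c(1, 500),
                    subclass = c("SST", "VIP"))
  p2 <- permuteLabels(lone, sch)
  expect_equal(p2$subclass, c("SST", "VIP"))
})

test_that("permutation null moments match exhaustive enumeration (6 cells)", {
  xs <- c(0, 8, 16, 30, 38, 46)
  ys <- c(0, 5, 0, 4, 0, 5)
  labs <- c("SST", "SST", "SST", "VIP", "VIP", "VIP")
  ct <- makeCells(x = xs, y = ys, subclass = labs, radius = 5)
  g <- buildContactGraph(ct)
  expect_gt(nrow(contactEdges(g)), 2)
  sch <- permutationScheme(binSizeUm = 1000, binHeightUm = 1000,
                           nPermutations = 4000, seed = 42)
  enr <- pairwiseEnrichment(ct, g, sch, minExpected = 0)
  # exhaustive oracle over all 720 label arrangements
  df <- cellData(ct)
  ed <- bruteForceEdges(df)
  ia <- match(ed$a, df$cell_id); ib <- match(ed$b, df$cell_id)
  lab <- match(labs, sort(unique(labs)))
  stats <- sapply(allPermutations(1:6), function(idx) {
    lp <- lab[idx]
    c(ss = sum(lp[ia] == 1 & lp[ib] == 1),
      sv = sum(lp[ia] != lp[ib]),
      vv = sum(lp[ia] == 2 & lp[ib] == 2))
  })
  want <- data.frame(key = c("SST~SST", "SST~VIP", "VIP~VIP"),
                     mean = apply(stats, 1, mean), sd = apply(stats, 1, sd))
  got <- enr[, c("label_a", "label_b", "null_mean", "null_sd", "observed")]
  B <- sch@nPermutations
  for (k in seq_len(nrow(want))) {
    row <- got[paste(got$label_a, got$label_b, sep = "~") == want$key[k], ]
    tolMean <- 3 * want$sd[k] / sqrt(B)
    expect_lt(abs(row$null_mean - want$mean[k]), tolMean + 1e-12)
    tolSd <- 3 * want$sd[k] / sqrt(2 * (B - 1))
    expect_lt(abs(row$null_sd - want$sd[k]), tolSd + 0.02)
  }
  # observed counts equal direct edge-label counts
  expect_equal(got$observed[paste(got$label_a, got$label_b, sep = "~") ==
                            "SST~SST"], sum(lab[ia] == 1 & lab[ib] == 1))
})

test_that("enrichment is deterministic and invariant to cell renaming", {
  tis <- smallHumanTissue()
  g <- buildContactGraph(tis$cells)
  sch <- permutationScheme(nPermutations = 120, seed = 9)
  a <- pairwiseEnrichment(tis$cells, g, sch)
  b <- pairwiseEnrichment(tis$cells, g, sch)
  expect_identical(a, b)
  df <- cellData(tis$cells)
  df$cell_id <- paste0("zz_", df$cell_id)
  ren <- new("CellTable", cells = df)
  g2 <- buildContactGraph(ren)
  c2 <- pairwiseEnrichment(ren, g2, sch)
  expect_equal(a[, -(1:2)], c2[, -(1:2)])
  expect_equal(a$label_a, c2$label_a)
})

test_that("BH adjustment matches the hand step-up formula", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  # NA excluded from the number of tests
  got <- bhAdjust(c(0.01, NA, 0.04))
  expect_equal(got, c(0.02, NA, 0.04))
  # generic hand check: step-up min_{j>=i} m p_(j) / j, capped at 1
  set.seed(8)
  p <- runif(20)^2
  o <- order(p); m <- 20
  hand <- numeric(m)
  hand[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(bhAdjust(p), pmin(1, hand))
  expect_true(all(bhAdjust(p) >= p))
})

test_that("nearest-neighbor distances match hand geometry and brute force", {
  ct <- makeCells(x = c(0, 1, 2, 10, 11, 12), y = rep(0, 6),
                  subclass = rep(c("SST", "VIP"), each = 3), radius = 0.4)
  res <- nnDistanceTest(ct, minCells = 2)
  d <- attr(res, "distances")
  expect_equal(d$d_self, rep(1, 6))
  expect_equal(d$d_other, c(10, 9, 8, 8, 9, 10))
  # brute-force equivalence on random cells
  set.seed(10)
  n <- 300
  ct2 <- makeCells(x = runif(n, 0, 200), y = runif(n, 0, 200),
                   subclass = sample(c("SST", "ASC", "OGC"), n, TRUE))
  df <- cellData(ct2)
  got <- cortexprox:::.nnSelfOther(df$x_um, df$y_um, df$subclass)
  for (i in seq_len(n)) {
    d2 <- (df$x_um - df$x_um[i])^2 + (df$y_um - df$y_um[i])^2
    d2[i] <- Inf
    same <- df$subclass == df$subclass[i]
    expect_equal(got$dSelf[i], sqrt(min(d2[same])), tolerance = 1e-9)
    expect_equal(got$dOther[i], sqrt(min(d2[!same])), tolerance = 1e-9)
  }
})

test_that("self/other test is near-uniform under a symmetric null", {
  set.seed(11)
  ps <- replicate(12, {
    n <- 200
    ct <- makeCells(x = runif(n, 0, 500), y = runif(n, 0, 500),
                    subclass = sample(rep(c("SST", "VIP"), n / 2)))
    res <- nnDistanceTest(ct, minCells = 2)
    res$p
  })
  ps <- as.numeric(ps)
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_gt(min(ps), 1e-4)
})
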