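test_that("layer assignment uses half-open bins with the deeper-layer tie rule", {
  b <- c(0.09, 0.35, 0.47, 0.70, 0.88)
  depths <- c(0, 0.05, 0.09, 0.34, 0.35, 0.5, 0.7, 0.87, 0.88, 0.95, 1.2)
  ct <- makeCells(x = seq_along(depths) * 30, y = rep(0, length(depths)),
                  subclass = "ASC", depth = depths)
  out <- cellData(layerAssign(ct, b))$layer
  expect_equal(out, c("L1", "L1", "L2/3", "L2/3", "L4", "L5", "L6", "L6",
                      "WM", "WM", "WM"))
  # brute-force interval search agrees on random depths
  set.seed(2)
  d <- runif(500, 0, 1.1)
  ct2 <- makeCells(x = seq_along(d), y = rep(0, 500), subclass = "ASC",
                   depth = d)
  got <- cellData(layerAssign(ct2, b))$layer
  layers <- c("L1", "L2/3", "L4", "L5", "L6", "WM")
  want <- vapply(d, function(z) layers[sum(z >= b) + 1], character(1))
  expect_equal(got, want)
  expect_error(layerAssign(ct, rev(b)), "increasing")
})

test_that("uniform depths give a flat profile within Poisson error", {
  set.seed(4)
  n <- 6000
  ct <- makeCells(x = runif(n, 0, 3000), y = runif(n, 0, 1000),
                  subclass = "ASC", depth = runif(n))
  dp <- depthProfiles(ct, nBins = 20, minCells = 1, maxDepth = 1)
  cnt <- profileTable(dp)$count
  expect_true(all(abs(cnt - n / 20) <= 3 * sqrt(n / 20)))
  # each profile integrates to one
  width <- diff(dp@binEdges[1:2])
  expect_equal(sum(profileTable(dp)$density) * width, 1, tolerance = 1e-9)
})

test_that("a narrow cluster's profile peaks in the bin holding its mean", {
  set.seed(5)
  d <- pmin(1, pmax(0, rnorm(2000, 0.45, 0.03)))
  ct <- makeCells(x = seq_along(d), y = rep(0, 2000), subclass = "L4/5 IT",
                  depth = d)
  dp <- depthProfiles(ct, nBins = 50, minCells = 1, maxDepth = 1)
  pt <- profileTable(dp)
  mode <- pt$bin[which.max(pt$density)]
  expect_equal(mode, findInterval(0.45, dp@binEdges))
})

test_that("cluster profiles aggregate exactly to the global histogram", {
  tis <- smallHumanTissue()
  dp <- depthProfiles(tis$cells, nBins = 25, minCells = 0)
  pt <- profileTable(dp)
  agg <- tapply(pt$count, pt$bin, sum)
  df <- cellData(tis$cells)
  bin <- pmin(25, pmax(1, findInterval(df$depth, dp@binEdges,
                                       rightmost.closed = TRUE)))
  want <- table(factor(bin, levels = 1:25))
  expect_equal(as.numeric(agg), as.numeric(want))
})

test_that("depth profiles are invariant to cell order and flag small clusters", {
  tis <- smallHumanTissue()
  df <- cellData(tis$cells)
  set.seed(6)
  shuf <- new("CellTable", cells = df[sample.int(nrow(df)), ])
  a <- depthProfiles(tis$cells, nBins = 20, minCells = 20)
  b <- depthProfiles(shuf, nBins = 20, minCells = 20)
  pa <- profileTable(a); pb <- profileTable(b)
  expect_equal(pa[order(pa$cluster, pa$bin), ],
               pb[order(pb$cluster, pb$bin), ], ignore_attr = TRUE)
  small <- names(which(table(df$cluster) < 20))
  expect_setequal(a@excluded, small)
  expect_error(depthProfiles(tis$cells, nBins = 1), "nBins")
})

test_that("E:I curve is standardized and never infinite", {
  tis <- demoHumanTissue()
  dp <- depthProfiles(tis$cells)
  ei <- eiTable(dp)
  expect_true(all(is.na(ei$ratio[ei$inh == 0])))
  z <- ei$z[is.finite(ei$z)]
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  # the dense thin L4/5 IT band is narrower than the L5 IT spread
  df <- cellData(tis$cells)
  expect_lt(sd(df$depth[df$subclass == "L4/5 IT"]),
            sd(df$depth[df$subclass == "L5 IT"]))
})
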