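test_that("hand-counted ratios: 10 EXC, 5 INH, 21 glia, 4 vascular", {
  n <- 40
  ct <- makeCells(x = seq_len(n) * 20, y = rep(50, n),
                  subclass = rep(c("L2/3 IT", "SST", "ASC", "ENDO"),
                                 c(10, 5, 21, 4)))
  cc <- cellComposition(ct, "class")
  expect_equal(gliaToNeuron(cc), 1.4)
  expect_equal(excToInh(cc), 2.0)
  tab <- compositionTable(cc)
  expect_equal(tab$proportion[tab$label == "non-neuronal"], 25 / 40)
  expect_equal(sum(tab$proportion), 1)
  expect_equal(sum(tab$count), cc@nDenominator)
})

test_that("single-class table has proportion one", {
  ct <- makeCells(x = 1:5 * 30, y = rep(0, 5), subclass = "VIP")
  cc <- cellComposition(ct, "class")
  expect_equal(compositionTable(cc)$proportion, 1)
})

test_that("cluster-level composition aggregates exactly to subclass level", {
  tis <- smallHumanTissue()
  ccC <- cellComposition(tis$cells, "cluster")
  ccS <- cellComposition(tis$cells, "subclass")
  tb <- taxonomyTable(humanTaxonomy())
  agg <- tapply(compositionTable(ccC)$count,
                tb$subclass[match(compositionTable(ccC)$label, tb$cluster)],
                sum)
  sc <- compositionTable(ccS)
  expect_equal(as.integer(agg[sc$label]), sc$count)
})

test_that("proportions are invariant under row permutation", {
  tis <- smallHumanTissue()
  df <- cellData(tis$cells)
  set.seed(1)
  shuf <- new("CellTable", cells = df[sample.int(nrow(df)), ])
  a <- compositionTable(cellComposition(tis$cells, "subclass"))
  b <- compositionTable(cellComposition(shuf, "subclass"))
  expect_equal(a, b)
})

test_that("white-matter exclusion and empty denominators behave", {
  ct <- makeCells(x = 1:6 * 30, y = rep(0, 6),
                  subclass = rep(c("L2/3 IT", "OGC"), 3),
                  layer = c("L2/3", "WM", "L2/3", "WM", "L2/3", "WM"))
  cc <- cellComposition(ct, "class")
  expect_equal(cc@nDenominator, 3L)
  ccAll <- cellComposition(ct, "class", excludeWM = FALSE)
  expect_equal(ccAll@nDenominator, 6L)
  expect_error(cellComposition(ct, "class", denominator = "inhibitory"),
               "empty denominator")
  # depth > 1 without layer label is treated as WM with a warning
  df <- cellData(ct); df$layer[2] <- NA; df$depth[2] <- 1.2
  expect_warning(cellComposition(new("CellTable", cells = df), "class"),
                 "treated as WM")
})

test_that("species comparison matches hand arithmetic", {
  h <- makeCells(x = 1:10 * 25, y = rep(0, 10),
                 subclass = rep(c("L2/3 IT", "SST"), c(8, 2)))
  m <- makeCells(x = 1:10 * 25, y = rep(0, 10),
                 subclass = rep(c("L2/3 IT", "SST"), c(5, 5)))
  ch <- cellComposition(h, "subclass")
  cm <- cellComposition(m, "subclass")
  out <- compareSpecies(ch, cm)
  expect_equal(out$ratio[out$label == "L2/3 IT"], 0.8 / 0.5)
  expect_equal(out$ratio[out$label == "SST"], 0.2 / 0.5)
  same <- compareSpecies(ch, ch)
  expect_true(all(same$ratio == 1))
  expect_equal(attr(same, "glia_to_neuron_ratio"), NA_real_)  # no glia
  # zero mouse proportion -> undefined, never infinity
  m2 <- makeCells(x = 1:4 * 25, y = rep(0, 4), subclass = "L2/3 IT")
  out2 <- compareSpecies(ch, cellComposition(m2, "subclass"))
  expect_true(is.na(out2$ratio[out2$label == "SST"]))
  expect_error(compareSpecies(ch, cellComposition(m, "class")),
               "level and denominator")
})
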