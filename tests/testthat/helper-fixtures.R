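# Shared fixtures and independent oracles. Generated tissues are memoised
# so several test files can reuse the same sections.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# mid-sized human section with all interaction injections (~20k cells)
demoHumanTissue <- function() memo("human20k", {
  generateTissue(resizeSection(defaultHumanConfig(seed = 3), 4000, 2500))
})

# mouse section, no injections beyond vessels (~15k cells)
demoMouseTissue <- function() memo("mouse15k", {
  generateTissue(resizeSection(defaultMouseConfig(seed = 3), 1000, 2500))
})

# small human section for quick structural tests (~1.3k cells)
smallHumanTissue <- function() memo("human1k", {
  generateTissue(resizeSection(defaultHumanConfig(seed = 1), 800, 800))
})

demoHumanGraph <- function() memo("humanGraph", {
  buildContactGraph(demoHumanTissue()$cells)
})

# hand-built cell table with sensible defaults for unspecified columns
makeCells <- function(x, y, subclass, cluster = subclass,
                      class = NULL, radius = 5, depth = NULL,
                      layer = NULL) {
  n <- length(x)
  tax <- taxonomyTable(humanTaxonomy())
  if (is.null(class)) {
    class <- tax$class[match(subclass, tax$subclass)]
    class[is.na(class)] <- "non-neuronal"
  }
  if (is.null(depth)) depth <- rep(0.5, n)
  if (is.null(layer)) layer <- rep("L5", n)
  df <- data.frame(cell_id = sprintf("c%03d", seq_len(n)), x_um = x,
                   y_um = y, soma_radius_um = rep(radius, length.out = n),
                   depth = depth, layer = layer, class = class,
                   subclass = subclass, cluster = cluster,
                   section_id = "test", species = "human",
                   stringsAsFactors = FALSE)
  new("CellTable", cells = df)
}

# O(n^2) all-pairs contact oracle
bruteForceEdges <- function(df, mode = "centroid", scale = 1.1, tolUm = 1) {
  n <- nrow(df)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((df$x_um[i] - df$x_um[j])^2 + (df$y_um[i] - df$y_um[j])^2)
    thr <- if (mode == "centroid")
      scale * (df$soma_radius_um[i] + df$soma_radius_um[j])
    else df$soma_radius_um[i] + df$soma_radius_um[j] + 2 * tolUm
    if (d <= thr)
      out[[length(out) + 1]] <- data.frame(a = df$cell_id[i],
                                           b = df$cell_id[j], d = d)
  }
  if (!length(out)) return(data.frame(a = character(0), b = character(0),
                                      d = numeric(0)))
  do.call(rbind, out)
}

edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# all permutations of a vector (for exhaustive enumeration oracles)
allPermutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in allPermutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# closed-form mean of a normal truncated to [lo, hi]
truncNormMean <- function(m, s, lo = 0, hi = 1) {
  a <- (lo - m) / s; b <- (hi - m) / s
  m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# brute-force union-find connected components over an edge list
bruteComponents <- function(nodes, ea, eb) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(ea)) {
    ra <- find(ea[k]); rb <- find(eb[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  unname(split(nodes, roots))
}

itSubclasses <- c("L2/3 IT", "L4/5 IT", "L5 IT", "L6 IT", "L6 IT CAR3")
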