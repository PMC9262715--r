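#' @importFrom data.table data.table setkey rbindlist fwrite fread :=
#'   setDF setnames
NULL

.datatable.aware <- TRUE

utils::globalVariables(c("gx", "gy", "a", "b", "d2", "i.b", "x.a", ".N",
                         "..keep"))

# Truncated-normal draws on [lo, hi] by inverse-CDF; vectorized over all
# arguments.
rtruncNorm <- function(n, mean, sd, lo = 0, hi = 1) {
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  u <- runif(n, plo, phi)
  pmin(hi, pmax(lo, qnorm(u) * sd + mean))
}

# Candidate neighbor pairs within `cutoff` via square-grid bucketing and a
# 9-offset data.table self-join. Returns a data.table (a, b, d) with a < b
# (integer row indices) and d <= cutoff; each unordered pair appears once.
gridNeighborPairs <- function(x, y, cutoff) {
  n <- length(x)
  if (n < 2L)
    return(data.table(a = integer(0), b = integer(0), d = numeric(0)))
  dt <- data.table(a = seq_len(n),
                   gx = as.integer(floor(x / cutoff)),
                   gy = as.integer(floor(y / cutoff)))
  setkey(dt, gx, gy)
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  out <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    q <- data.table(b = dt$a,
                    gx = dt$gx + offs$dx[k],
                    gy = dt$gy + offs$dy[k])
    m <- dt[q, on = c("gx", "gy"), nomatch = NULL, allow.cartesian = TRUE]
    out[[k]] <- m[m$a < m$b, c("a", "b")]
  }
  pr <- rbindlist(out)
  if (!nrow(pr))
    return(data.table(a = integer(0), b = integer(0), d = numeric(0)))
  d2 <- (x[pr$a] - x[pr$b])^2 + (y[pr$a] - y[pr$b])^2
  keep <- d2 <= cutoff^2
  data.table(a = pr$a[keep], b = pr$b[keep], d = sqrt(d2[keep]))
}

# Rectangular spatial bins (binW wide, binH tall): list of integer index
# vectors.
spatialBinGroups <- function(x, y, binW, binH = binW) {
  key <- paste(floor(x / binW), floor(y / binH))
  unname(split(seq_along(x), key))
}

# One within-bin shuffle: returns idx such that newLabels = labels[idx];
# per-bin label multisets are exactly preserved.
shuffleWithinBins <- function(groups, n) {
  idx <- integer(n)
  for (g in groups) {
    idx[g] <- if (length(g) > 1L) g[sample.int(length(g))] else g
  }
  idx
}

# Unordered pair key for integer label codes in 1..K.
pairKey <- function(la, lb, K) {
  (pmin(la, lb) - 1L) * K + pmax(la, lb)
}

# Deterministic per-stage seed spawned from a global seed.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Resolve a cell-group name against a taxonomy: a class name, "IT",
# "neurons", or a subclass name -> character vector of subclasses.
resolveGroup <- function(name, taxonomy) {
  tb <- taxonomyTable(taxonomy)
  if (name %in% tb$subclass) return(name)
  if (name == "IT") return(unique(tb$subclass[tb$is_IT]))
  if (name == "neurons")
    return(unique(tb$subclass[tb$class %in% c("excitatory", "inhibitory")]))
  if (name %in% tb$class) return(unique(tb$subclass[tb$class == name]))
  stop("unknown cell group: ", name)
}

.gliaSubclasses <- c("ASC", "OGC", "OPC", "MGC")
.vascularSubclasses <- c("ENDO", "MURAL")
.itSubclasses <- c("L2/3 IT", "L4/5 IT", "L5 IT", "L6 IT", "L6 IT CAR3")
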