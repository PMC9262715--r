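## Occupancy grid for hard-core dart throwing: cell-list with linked
## chains, grid side = hardcore distance so only the 3x3 neighborhood needs
## checking. Plain environment for speed.
.makeGrid <- function(W, H, h, capacity) {
  e <- new.env(parent = emptyenv())
  e$ngx <- max(1L, as.integer(ceiling(W / h)) + 2L)
  e$ngy <- max(1L, as.integer(ceiling(H / h)) + 2L)
  e$head <- matrix(0L, e$ngx, e$ngy)
  e$nxt <- integer(capacity)
  e$px <- numeric(capacity)
  e$py <- numeric(capacity)
  e$h2 <- h * h
  e$h <- h
  e
}

.gridCellOf <- function(e, x, y) {
  c(min(e$ngx, max(1L, as.integer(x %/% e$h) + 1L)),
    min(e$ngy, max(1L, as.integer(y %/% e$h) + 1L)))
}

.gridInsert <- function(e, i, x, y) {
  g <- .gridCellOf(e, x, y)
  e$px[i] <- x; e$py[i] <- y
  e$nxt[i] <- e$head[g[1], g[2]]
  e$head[g[1], g[2]] <- i
}

## TRUE if any stored point (not in `excl`) lies within the hardcore
## distance of (x, y).
.gridConflict <- function(e, x, y, excl = integer(0)) {
  g <- .gridCellOf(e, x, y)
  for (dx in -1:1) {
    cx <- g[1] + dx
    if (cx < 1L || cx > e$ngx) next
    for (dy in -1:1) {
      cy <- g[2] + dy
      if (cy < 1L || cy > e$ngy) next
      j <- e$head[cx, cy]
      while (j > 0L) {
        if (!(j %in% excl)) {
          ddx <- e$px[j] - x; ddy <- e$py[j] - y
          if (ddx * ddx + ddy * ddy < e$h2) return(TRUE)
        }
        j <- e$nxt[j]
      }
    }
  }
  FALSE
}

#' Generate a synthetic cortical section
#'
#' Simulates a spatial cell table and a sparse expression matrix with known
#' ground truth. Cells are drawn from the configured cluster composition
#' (Poisson total count = density x area), given truncated-Gaussian depths
#' per cluster, and placed by dart throwing under a hard-core minimum
#' centroid separation. On top of this base pattern the generator injects:
#' satellite cells relocated to exact soma-contact distance
#' (r_i + r_j + gap) from focal partners, blood-vessel-like self-avoiding
#' chains of endothelial/mural cells with optional perivascular glial
#' recruitment, a latent GAD1-positive OPC subpopulation (GAD2/SLC32A1 are
#' silenced in all OPCs), and contact-conditioned ligand-receptor
#' expression boosts. Expression counts are negative-binomial with
#' marker-gene folds and per-cell lognormal library-size factors.
#'
#' Relocated cells are flagged in the output (`placement` column:
#' `"free"`, `"satellite"`, `"vessel"`, `"perivascular"`; plus
#' `satellite_of` and `vessel_id`); only free cells are subject to the
#' hard-core rule.
#'
#' @param config a [TissueConfig].
#' @param taxonomy a [Taxonomy] resolving every configured cluster.
#' @param seed RNG seed; defaults to the seed stored in `config`.
#' @return list with elements `cells` (a [CellTable]) and `expression`
#'   (an [ExpressionMatrix]).
#' @examples
#' cfg <- resizeSection(defaultHumanConfig(seed = 1), 600, 600)
#' tis <- generateTissue(cfg)
#' tis$cells
#' @export
generateTissue <- function(config, taxonomy = humanTaxonomy(),
                           seed = config@seed) {
  validObject(config)
  tb <- taxonomyTable(taxonomy)
  miss <- setdiff(names(config@composition), tb$cluster)
  if (length(miss))
    stop("composition references clusters absent from the taxonomy: ",
         paste(utils::head(miss, 5), collapse = ", "))
  set.seed(seed)
  W <- config@sectionWidthUm; H <- config@sectionHeightUm
  genes <- config@expressionSpec$genes
  n <- rpois(1, config@densityCellsPerMm2 * W * H / 1e6)
  if (n == 0L) return(.emptyTissue(config, genes))

  comp <- config@composition
  cl <- sample(names(comp), n, replace = TRUE, prob = comp)
  row <- match(cl, tb$cluster)
  sub <- tb$subclass[row]
  cls <- tb$class[row]

  lam <- config@laminarProfiles
  lrow <- match(cl, lam$cluster)
  dmean <- lam$mean_depth[lrow]; dsd <- lam$sd_depth[lrow]
  plo <- pnorm((0 - dmean) / dsd); phi <- pnorm((1 - dmean) / dsd)
  depth0 <- pmin(1, pmax(0, qnorm(runif(n, plo, phi)) * dsd + dmean))

  sr <- config@somaRadiusUm
  srow <- match(sub, sr$subclass)
  if (anyNA(srow))
    stop("no soma radius configured for subclass: ",
         paste(unique(sub[is.na(srow)]), collapse = ", "))
  radius <- pmax(2, rnorm(n, sr$mean[srow], sr$sd[srow]))

  wmB <- config@layerBoundaries[5]
  placement <- rep("free", n)
  satelliteOf <- rep(NA_integer_, n)
  vesselId <- rep(NA_integer_, n)
  groupFocal <- integer(0)   # parallel vectors: satellite index / focal index
  groupSat <- integer(0)
  groupRank <- integer(0)    # sibling rank within the focal's group
  groupGap <- numeric(0)
  groupSize <- integer(0)

  ## --- role selection (before placement) -------------------------------
  vs <- config@vesselSpec
  nv <- as.integer(vs$n_vessels)
  vesselMembersIdx <- list()
  if (nv > 0L && vs$cells_per_vessel > 0L) {
    cpv <- as.integer(vs$cells_per_vessel)
    poolE <- which(sub == "ENDO" & depth0 < wmB)
    poolM <- which(sub == "MURAL" & depth0 < wmB)
    nMur <- round(vs$mural_fraction * cpv)
    needM <- nMur * nv; needE <- (cpv - nMur) * nv
    if (needM > length(poolM)) needM <- length(poolM)
    if (needE > length(poolE)) needE <- length(poolE)
    nv <- max(0L, min(nv, as.integer((needM + needE) %/% cpv)))
    if (nv > 0L) {
      pickM <- sample(poolM, min(needM, nMur * nv))
      pickE <- sample(poolE, min(needE, (cpv - nMur) * nv))
      members <- c(pickM, pickE)
      placement[members] <- "vessel"
      ## interleave so each vessel gets its mural share
      vesselMembersIdx <- vector("list", nv)
      for (v in seq_len(nv)) {
        mm <- pickM[seq_len(nMur) + (v - 1L) * nMur]
        ee <- pickE[seq_len(cpv - nMur) + (v - 1L) * (cpv - nMur)]
        vesselMembersIdx[[v]] <- c(mm, ee)[!is.na(c(mm, ee))]
        vesselId[vesselMembersIdx[[v]]] <- v
      }
    }
  }
  recruit <- vs$glial_recruit
  recruitIdx <- list()
  if (nv > 0L && length(recruit)) {
    for (g in names(recruit)) {
      cnt <- as.integer(recruit[[g]])
      if (cnt <= 0L) next
      pool <- which(sub == g & depth0 < wmB & placement == "free")
      take <- sample(pool, min(length(pool), cnt * nv))
      placement[take] <- "perivascular"
      recruitIdx[[g]] <- take
    }
  }

  ss <- config@satelliteSpecs
  if (nrow(ss)) {
    for (k in seq_len(nrow(ss))) {
      partnerAll <- which(sub == ss$partner_subclass[k])
      pool <- partnerAll[depth0[partnerAll] < wmB &
                         placement[partnerAll] == "free"]
      nSat <- min(length(pool), round(ss$fraction[k] * length(partnerAll)))
      if (nSat == 0L) next
      sat <- sample(pool, nSat)
      ppf <- max(1L, as.integer(ss$partners_per_focal[k]))
      focalPool <- which(sub == ss$focal_subclass[k] & depth0 < wmB &
                         placement == "free" & is.na(satelliteOf))
      focalPool <- setdiff(focalPool, sat)
      nFocal <- ceiling(nSat / ppf)
      if (length(focalPool) < nFocal) {
        nFocal <- length(focalPool)
        nSat <- min(nSat, nFocal * ppf)
        if (nFocal == 0L) next
        sat <- sat[seq_len(nSat)]
      }
      focals <- sample(focalPool, nFocal)
      assign <- rep(focals, each = ppf)[seq_len(nSat)]
      rank <- rep(seq_len(ppf), times = nFocal)[seq_len(nSat)]
      placement[sat] <- "satellite"
      satelliteOf[sat] <- assign
      groupFocal <- c(groupFocal, assign)
      groupSat <- c(groupSat, sat)
      groupRank <- c(groupRank, rank)
      groupGap <- c(groupGap, rep(ss$contact_gap_um[k], nSat))
      groupSize <- c(groupSize, rep(ppf, nSat))
    }
  }

  ## --- placement -------------------------------------------------------
  h <- config@hardcoreDistanceUm
  x <- numeric(n); y <- numeric(n)
  grid <- .makeGrid(W, H, h, n)
  freeIdx <- which(placement == "free")
  budget <- 100 * length(freeIdx)
  attempts <- 0L
  ## depth is drawn once per cell and kept on rejection (only x is
  ## re-sampled), so the realized depth marginal of every cluster is
  ## exactly its configured truncated normal.
  for (i in freeIdx) {
    cy <- depth0[i] * H
    repeat {
      attempts <- attempts + 1L
      if (attempts > budget)
        stop(sprintf(paste0(
          "hard-core packing unsatisfiable: density %g cells/mm^2 cannot be ",
          "placed with hardcore distance %g um (rejection budget exceeded)"),
          config@densityCellsPerMm2, h))
      cx <- runif(1, 0, W)
      if (!.gridConflict(grid, cx, cy)) {
        x[i] <- cx; y[i] <- cy
        .gridInsert(grid, i, cx, cy)
        break
      }
    }
  }

  ## vessel chains: persistent-direction self-avoiding walks confined to
  ## the cortical ribbon; members relocated onto chain points.
  if (length(vesselMembersIdx)) {
    yMax <- wmB * H * 0.99
    for (v in seq_along(vesselMembersIdx)) {
      mem <- sample(vesselMembersIdx[[v]])   # shuffle ENDO/MURAL order
      px <- runif(1, 2 * h, W - 2 * h)
      py <- runif(1, 0.05 * H, yMax)
      th <- runif(1, 0, 2 * pi)
      chainX <- numeric(length(mem)); chainY <- numeric(length(mem))
      chainX[1] <- px; chainY[1] <- py
      for (s in seq_along(mem)[-1]) {
        ok <- FALSE
        for (try in 1:20) {
          th2 <- th + rnorm(1, 0, 0.35)
          nx <- chainX[s - 1] + vs$step_um * cos(th2)
          ny <- chainY[s - 1] + vs$step_um * sin(th2)
          if (nx < 1 || nx > W - 1 || ny < 1 || ny > yMax) next
          if (s > 2) {
            dd <- (chainX[1:(s - 2)] - nx)^2 + (chainY[1:(s - 2)] - ny)^2
            if (min(dd) < (0.9 * vs$step_um)^2) next
          }
          ok <- TRUE; th <- th2; break
        }
        if (!ok) { th <- th + pi / 2
          nx <- min(W - 1, max(1, chainX[s - 1] + vs$step_um * cos(th)))
          ny <- min(yMax, max(1, chainY[s - 1] + vs$step_um * sin(th)))
        }
        chainX[s] <- nx; chainY[s] <- ny
      }
      x[mem] <- chainX; y[mem] <- chainY
      for (ii in mem) .gridInsert(grid, ii, x[ii], y[ii])
    }
    ## perivascular glia: contact distance from a random chain member
    for (g in names(recruitIdx)) {
      for (i in recruitIdx[[g]]) {
        v <- sample.int(length(vesselMembersIdx), 1)
        host <- sample(vesselMembersIdx[[v]], 1)
        d <- radius[i] + radius[host] + 0.5
        pos <- .placeAround(grid, x[host], y[host], d, W, H,
                            excl = vesselMembersIdx[[v]])
        x[i] <- pos[1]; y[i] <- pos[2]
        vesselId[i] <- v
        .gridInsert(grid, i, pos[1], pos[2])
      }
    }
  }

  ## satellites: exact contact distance from their focal partner; siblings
  ## of one focal are spread over angles so multiway groups do not collide.
  if (length(groupSat)) {
    baseAngle <- runif(length(groupSat), 0, 2 * pi)
    for (q in seq_along(groupSat)) {
      i <- groupSat[q]; f <- groupFocal[q]
      d <- radius[i] + radius[f] + groupGap[q]
      th0 <- baseAngle[q] + 2 * pi * (groupRank[q] - 1) / groupSize[q]
      sibs <- groupSat[groupFocal == f]
      pos <- .placeAround(grid, x[f], y[f], d, W, H,
                          excl = c(f, sibs), th0 = th0)
      x[i] <- pos[1]; y[i] <- pos[2]
      .gridInsert(grid, i, pos[1], pos[2])
    }
  }

  depth <- y / H
  layer <- .LAYERS[findInterval(depth, config@layerBoundaries) + 1L]
  ids <- sprintf("%s_c%06d", config@sectionId, seq_len(n))
  df <- data.frame(cell_id = ids, x_um = x, y_um = y,
                   soma_radius_um = radius, depth = depth, layer = layer,
                   class = cls, subclass = sub, cluster = cl,
                   section_id = config@sectionId, species = config@species,
                   placement = placement,
                   satellite_of = ifelse(is.na(satelliteOf), NA_character_,
                                         ids[satelliteOf]),
                   vessel_id = vesselId,
                   stringsAsFactors = FALSE)
  cells <- new("CellTable", cells = df)

  expr <- .generateExpression(config, taxonomy, df)
  list(cells = cells, expression = expr)
}

## place a point at exact distance d from (cx, cy), trying rotated angles
## to satisfy the hardcore rule against non-exempt cells; falls back to the
## first in-bounds angle.
.placeAround <- function(grid, cx, cy, d, W, H, excl, th0 = NULL) {
  if (is.null(th0)) th0 <- runif(1, 0, 2 * pi)
  fallback <- NULL
  for (t in 0:19) {
    th <- th0 + t * 2.399963  # golden-angle sweep
    nx <- cx + d * cos(th); ny <- cy + d * sin(th)
    if (nx < 0 || nx > W || ny < 0 || ny > H) next
    if (is.null(fallback)) fallback <- c(nx, ny)
    if (!.gridConflict(grid, nx, ny, excl = excl)) return(c(nx, ny))
  }
  if (is.null(fallback))
    fallback <- c(min(W, max(0, cx + d)), min(H, max(0, cy)))
  fallback
}

.emptyTissue <- function(config, genes) {
  df <- data.frame(cell_id = character(0), x_um = numeric(0),
                   y_um = numeric(0), soma_radius_um = numeric(0),
                   depth = numeric(0), layer = character(0),
                   class = character(0), subclass = character(0),
                   cluster = character(0), section_id = character(0),
                   species = character(0), placement = character(0),
                   satellite_of = character(0), vessel_id = integer(0),
                   stringsAsFactors = FALSE)
  m <- Matrix::Matrix(0, 0, length(genes), sparse = TRUE,
                      dimnames = list(character(0), genes))
  list(cells = new("CellTable", cells = df),
       expression = new("ExpressionMatrix",
                        counts = methods::as(m, "CsparseMatrix")))
}

## Negative-binomial expression with marker folds, library-size factors,
## the GAD1+ OPC latent subpopulation and contact-conditioned
## ligand-receptor boosts. Consumes RNG state after placement.
.generateExpression <- function(config, taxonomy, df) {
  es <- config@expressionSpec
  genes <- es$genes
  n <- nrow(df); G <- length(genes)
  libfac <- rlnorm(n, 0, es$libsize_sdlog)
  mu <- matrix(es$baseline_nb_mean, n, G) * libfac
  colnames(mu) <- genes
  ## marker folds per cluster
  ms <- es$marker_sets
  for (clu in intersect(unique(df$cluster), names(ms))) {
    gset <- intersect(ms[[clu]], genes)
    if (!length(gset)) next
    rows <- which(df$cluster == clu)
    mu[rows, gset] <- mu[rows, gset] * es$marker_fold
  }
  ## GAD1+ OPC model: GAD2 and SLC32A1 silent in all OPCs; GAD1 expressed
  ## from the marker model in a latent Bernoulli subset, silent otherwise.
  opc <- which(df$subclass == "OPC")
  if (length(opc)) {
    for (g in intersect(c("GAD2", "SLC32A1"), genes)) mu[opc, g] <- 0
    if ("GAD1" %in% genes) {
      pos <- opc[as.logical(rbinom(length(opc), 1,
                                   config@gad1PositiveOpcFraction))]
      mu[opc, "GAD1"] <- 0
      mu[pos, "GAD1"] <- es$baseline_nb_mean * libfac[pos] * es$marker_fold
    }
  }
  ## contact-conditioned ligand-receptor boosts
  lr <- config@ligrecSpec
  if (nrow(lr) && n > 1L) {
    cut <- 1.1 * 2 * max(df$soma_radius_um)
    pr <- gridNeighborPairs(df$x_um, df$y_um, cut)
    keep <- pr$d <= 1.1 * (df$soma_radius_um[pr$a] + df$soma_radius_um[pr$b])
    pr <- pr[keep, ]
    for (k in seq_len(nrow(lr))) {
      sSub <- resolveGroup(lr$sender[k], taxonomy)
      rSub <- resolveGroup(lr$receiver[k], taxonomy)
      isS <- df$subclass %in% sSub; isR <- df$subclass %in% rSub
      hit <- (isS[pr$a] & isR[pr$b]) | (isS[pr$b] & isR[pr$a])
      sCells <- unique(c(pr$a[hit & isS[pr$a]], pr$b[hit & isS[pr$b]]))
      rCells <- unique(c(pr$a[hit & isR[pr$a]], pr$b[hit & isR[pr$b]]))
      if (lr$ligand[k] %in% genes && length(sCells))
        mu[sCells, lr$ligand[k]] <- mu[sCells, lr$ligand[k]] *
          lr$contact_boost_fold[k]
      if (lr$receptor[k] %in% genes && length(rCells))
        mu[rCells, lr$receptor[k]] <- mu[rCells, lr$receptor[k]] *
          lr$contact_boost_fold[k]
    }
  }
  counts <- matrix(rnbinom(n * G, size = es$nb_dispersion, mu = mu), n, G,
                   dimnames = list(df$cell_id, genes))
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  new("ExpressionMatrix", counts = m)
}
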