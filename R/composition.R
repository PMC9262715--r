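#' Cell-type composition
#'
#' Counts and proportions of cell-type labels at one taxonomy level over a
#' chosen denominator population, together with the two headline ratios of
#' cortical cytoarchitecture: glia:neuron (glia = astrocytes +
#' oligodendrocytes + OPCs + microglia; endothelial/mural cells are
#' non-neuronal but not glia) and excitatory:inhibitory. White-matter cells
#' are excluded by default, matching how cortical compositions are
#' conventionally reported; cells with depth > 1 but no layer label are
#' treated as white matter with a warning.
#'
#' @param cells a [CellTable].
#' @param level `"class"`, `"subclass"` or `"cluster"`.
#' @param denominator population the proportions are relative to:
#'   `"all_cells"`, `"neurons"`, `"excitatory"`, `"inhibitory"` or `"IT"`.
#' @param excludeWM drop `layer == "WM"` cells before counting (default
#'   TRUE).
#' @param taxonomy a [Taxonomy] (used to resolve IT subclasses).
#' @return a [CompositionResult].
#' @examples
#' tis <- generateTissue(resizeSection(defaultHumanConfig(seed = 1), 800, 800))
#' cellComposition(tis$cells, "class")
#' @export
cellComposition <- function(cells, level = c("class", "subclass", "cluster"),
                            denominator = c("all_cells", "neurons",
                                            "excitatory", "inhibitory", "IT"),
                            excludeWM = TRUE, taxonomy = humanTaxonomy()) {
  level <- match.arg(level)
  denominator <- match.arg(denominator)
  df <- cellData(cells)
  if (excludeWM && nrow(df)) {
    unlabeled <- (is.na(df$layer) | df$layer == "") & df$depth > 1
    if (any(unlabeled)) {
      warning(sum(unlabeled),
              " cells with depth > 1 and no layer label treated as WM")
      df$layer[unlabeled] <- "WM"
    }
    df <- df[df$layer != "WM", , drop = FALSE]
  }
  keep <- switch(denominator,
    all_cells = rep(TRUE, nrow(df)),
    neurons = df$class %in% c("excitatory", "inhibitory"),
    excitatory = df$class == "excitatory",
    inhibitory = df$class == "inhibitory",
    IT = df$subclass %in% resolveGroup("IT", taxonomy))
  dd <- df[keep, , drop = FALSE]
  if (nrow(dd) == 0L)
    stop("empty denominator population: ", denominator)
  lab <- dd[[level]]
  tab <- table(lab)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    proportion = as.numeric(tab) / nrow(dd),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count), ]
  rownames(out) <- NULL
  nGlia <- sum(df$subclass %in% .gliaSubclasses)
  nNeu <- sum(df$class %in% c("excitatory", "inhibitory"))
  nExc <- sum(df$class == "excitatory")
  nInh <- sum(df$class == "inhibitory")
  new("CompositionResult", level = level, denominator = denominator,
      excludeWM = excludeWM, table = out, nDenominator = nrow(dd),
      gliaToNeuron = if (nNeu > 0) nGlia / nNeu else NA_real_,
      excToInh = if (nInh > 0) nExc / nInh else NA_real_)
}

#' Compare compositions between species
#'
#' Per-label human/mouse proportion ratios plus the ratio-of-ratios for the
#' glia:neuron and E:I headline statistics. Labels with zero mouse
#' proportion get an undefined (NA) ratio, never infinity.
#'
#' @param human,mouse [CompositionResult] objects at the same level and
#'   denominator.
#' @return data.frame (`label`, `human`, `mouse`, `ratio`) with attributes
#'   `glia_to_neuron_ratio` and `exc_to_inh_ratio` (human / mouse).
#' @export
compareSpecies <- function(human, mouse) {
  if (human@level != mouse@level || human@denominator != mouse@denominator)
    stop("compositions must share level and denominator")
  ht <- compositionTable(human); mt <- compositionTable(mouse)
  labels <- sort(union(ht$label, mt$label))
  hp <- ht$proportion[match(labels, ht$label)]; hp[is.na(hp)] <- 0
  mp <- mt$proportion[match(labels, mt$label)]; mp[is.na(mp)] <- 0
  out <- data.frame(label = labels, human = hp, mouse = mp,
                    ratio = ifelse(mp > 0, hp / mp, NA_real_),
                    stringsAsFactors = FALSE)
  gn <- if (is.finite(mouse@gliaToNeuron) && mouse@gliaToNeuron > 0)
    human@gliaToNeuron / mouse@gliaToNeuron else NA_real_
  ei <- if (is.finite(mouse@excToInh) && mouse@excToInh > 0)
    human@excToInh / mouse@excToInh else NA_real_
  attr(out, "glia_to_neuron_ratio") <- gn
  attr(out, "exc_to_inh_ratio") <- ei
  out
}
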