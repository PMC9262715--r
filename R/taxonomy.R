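#' Packaged cortical cell-type taxonomy
#'
#' Builds the packaged three-level taxonomy used throughout the package:
#' 125 clusters (29 excitatory, 39 inhibitory, 57 non-neuronal) organized
#' into the canonical cortical subclasses. Excitatory subclasses: L2/3 IT,
#' L4/5 IT, L5 IT, L6 IT, L6 IT CAR3, L5 ET, L5/6 NP, L6 CT, L6b.
#' Inhibitory subclasses: LAMP5, PVALB, SST, VIP. Non-neuronal subclasses:
#' ASC (astrocytes), OGC (oligodendrocytes), OPC (oligodendrocyte
#' precursors), MGC (microglia), ENDO (endothelial), MURAL (mural).
#'
#' `mouseTaxonomy()` returns the same subclass structure (cross-species
#' comparisons in this package are made at the subclass level, where the
#' taxonomies correspond one-to-one).
#'
#' @return a [Taxonomy] object.
#' @examples
#' tax <- humanTaxonomy()
#' table(taxonomyTable(tax)$class)
#' @export
humanTaxonomy <- function() {
  exc <- c("L2/3 IT" = 6, "L4/5 IT" = 3, "L5 IT" = 4, "L6 IT" = 4,
           "L6 IT CAR3" = 1, "L5 ET" = 2, "L5/6 NP" = 2, "L6 CT" = 4,
           "L6b" = 3)
  inh <- c(LAMP5 = 8, PVALB = 10, SST = 13, VIP = 8)
  non <- c(ASC = 11, OGC = 16, OPC = 6, MGC = 10, ENDO = 8, MURAL = 6)
  build <- function(counts, cls) {
    do.call(rbind, lapply(names(counts), function(s) {
      k <- counts[[s]]
      data.frame(cluster = if (k == 1L) s else
                   paste(s, tolower(as.character(utils::as.roman(seq_len(k))))),
                 subclass = s, class = cls, stringsAsFactors = FALSE)
    }))
  }
  tb <- rbind(build(exc, "excitatory"), build(inh, "inhibitory"),
              build(non, "non-neuronal"))
  tb$is_glial <- tb$subclass %in% .gliaSubclasses
  tb$is_vascular <- tb$subclass %in% .vascularSubclasses
  tb$is_IT <- tb$subclass %in% .itSubclasses
  rownames(tb) <- NULL
  new("Taxonomy", table = tb)
}

#' @rdname humanTaxonomy
#' @export
mouseTaxonomy <- function() humanTaxonomy()
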