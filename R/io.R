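#' Read and write cell tables
#'
#' Cell tables are stored as UTF-8 comma-separated CSV with a header row
#' and '.' decimals; the write -> read round trip is lossless (numeric
#' columns are written at full precision). Readers validate rather than
#' coerce: missing columns, duplicated ids, non-positive radii and
#' non-finite coordinates are rejected with a message naming the offending
#' field/rows.
#'
#' @param path CSV file path.
#' @param table a [CellTable].
#' @return `readCells()` returns a [CellTable]; `writeCells()` returns
#'   `path` invisibly.
#' @export
readCells <- function(path) {
  df <- as.data.frame(fread(path, sep = ",", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = "NA"))
  if ("cell_id" %in% names(df)) df$cell_id <- as.character(df$cell_id)
  for (col in c("layer", "class", "subclass", "cluster", "section_id",
                "species", "placement", "satellite_of"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  msg <- .checkCellFrame(df)
  if (!is.null(msg)) stop("invalid cell table '", path, "': ", msg)
  new("CellTable", cells = df)
}

#' @rdname readCells
#' @export
writeCells <- function(table, path) {
  stopifnot(is(table, "CellTable"))
  fwrite(cellData(table), path, sep = ",", na = "NA", quote = "auto")
  invisible(path)
}

#' Read and write expression matrices
#'
#' Sparse cell x gene counts are stored as MatrixMarket (`.mtx`) with two
#' TSV sidecars next to the matrix file: `<stem>_genes.tsv` (one gene name
#' per line) and `<stem>_cells.tsv` (one cell id per line). Dimension
#' mismatches and negative or non-integer entries are rejected.
#'
#' @param path path to the `.mtx` file.
#' @param expr an [ExpressionMatrix].
#' @return `readExpression()` returns an [ExpressionMatrix];
#'   `writeExpression()` returns `path` invisibly.
#' @export
readExpression <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  m <- Matrix::readMM(path)
  genes <- readLines(paste0(stem, "_genes.tsv"))
  cellIds <- readLines(paste0(stem, "_cells.tsv"))
  if (length(cellIds) != nrow(m) || length(genes) != ncol(m))
    stop("expression sidecars do not match matrix dimensions: matrix is ",
         nrow(m), " x ", ncol(m), ", sidecars give ", length(cellIds),
         " cells and ", length(genes), " genes")
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x))))
    stop("expression matrix contains negative or non-integer counts")
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(cellIds, genes)
  new("ExpressionMatrix", counts = m)
}

#' @rdname readExpression
#' @export
writeExpression <- function(expr, path) {
  stopifnot(is(expr, "ExpressionMatrix"))
  stem <- sub("\\.mtx$", "", path)
  m <- exprCounts(expr)
  Matrix::writeMM(m, path)
  writeLines(colnames(m), paste0(stem, "_genes.tsv"))
  writeLines(rownames(m), paste0(stem, "_cells.tsv"))
  invisible(path)
}

#' Library-size normalization
#'
#' Scales every cell (row) to a fixed total (`scale` counts per cell);
#' cells with zero total counts stay all-zero and are flagged in the
#' `"zero_cells"` attribute of the result.
#'
#' @param expr an [ExpressionMatrix].
#' @param scale target row total (counts-per-`scale`), default 1000.
#' @return a sparse normalized matrix (same dimnames) with attribute
#'   `zero_cells` listing all-zero cell ids.
#' @export
normalizeExpression <- function(expr, scale = 1000) {
  m <- exprCounts(expr)
  if (nrow(m) == 0L) stop("empty expression matrix")
  rs <- Matrix::rowSums(m)
  zero <- rownames(m)[rs == 0]
  f <- ifelse(rs > 0, scale / rs, 0)
  out <- Matrix::Diagonal(x = f) %*% m
  dimnames(out) <- dimnames(m)
  out <- methods::as(out, "CsparseMatrix")
  attr(out, "zero_cells") <- zero
  out
}

#' Write nucleus outlines as GeoJSON
#'
#' Writes one polygon feature per cell. Without measured nucleus polygons
#' the soma circle is polygonized with `nVertices` vertices (the package's
#' default geometry).
#'
#' @param table a [CellTable].
#' @param path output file.
#' @param nVertices vertices per circle polygon.
#' @return `path`, invisibly.
#' @export
writeNucleiGeoJSON <- function(table, path, nVertices = 24) {
  df <- cellData(table)
  th <- seq(0, 2 * pi, length.out = nVertices + 1)
  feats <- lapply(seq_len(nrow(df)), function(i) {
    ring <- cbind(df$x_um[i] + df$soma_radius_um[i] * cos(th),
                  df$y_um[i] + df$soma_radius_um[i] * sin(th))
    list(type = "Feature",
         properties = list(cell_id = df$cell_id[i],
                           subclass = df$subclass[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                            function(j) ring[j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
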