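#' Expression matrix container
#'
#' Holds a genes x cells expression matrix together with gene and cell
#' identifiers, a per-cell metadata table and a layer tag distinguishing raw
#' counts from normalized values. This is the central data model every
#' pipeline stage consumes.
#'
#' @param values numeric matrix or \code{Matrix} sparse matrix, genes in rows,
#'   cells in columns. The counts layer must be non-negative.
#' @param gene_ids character vector of unique gene identifiers (row names).
#'   Identifiers are treated as opaque strings; symbol/Ensembl mapping is the
#'   caller's responsibility.
#' @param cell_ids character vector of unique cell identifiers (column names).
#' @param cell_meta data.frame of per-cell metadata, one row per cell in
#'   \code{cell_ids} order. A \code{sample_id} column is required by the
#'   meta-cell stage; a group column (e.g. a toxicity grade) is optional.
#' @param layer_tag either \code{"counts"} or \code{"normalized"}.
#'
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values}, \code{gene_ids}, \code{cell_ids}, \code{cell_meta},
#'   \code{layer_tag}.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              cell_meta = NULL,
                              layer_tag = c("counts", "normalized")) {
  layer_tag <- match.arg(layer_tag)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (or set dimnames on 'values')")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids))
    stop("row count (", nrow(values), ") does not match number of gene_ids (",
         length(gene_ids), ")")
  if (ncol(values) != length(cell_ids))
    stop("column count (", ncol(values), ") does not match number of cell_ids (",
         length(cell_ids), ")")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (layer_tag == "counts" && length(values) && min(values) < 0)
    stop("counts layer must be non-negative")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (is.null(cell_meta$cell_id)) cell_meta$cell_id <- cell_ids
    if (nrow(cell_meta) != length(cell_ids) ||
        !all(cell_meta$cell_id == cell_ids))
      stop("cell_meta must have one row per cell, in cell_ids order")
  }
  rownames(values) <- gene_ids
  colnames(values) <- cell_ids
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta, layer_tag = layer_tag),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", length(x$gene_ids), "genes x",
      length(x$cell_ids), "cells; layer =", x$layer_tag, "\n")
  extra <- setdiff(names(x$cell_meta), "cell_id")
  if (length(extra)) cat("cell_meta columns:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read a 10x-style Matrix Market triplet into an ExpressionMatrix
#'
#' Reads a sparse counts matrix in Matrix Market coordinate format together
#' with companion gene and barcode lists (one identifier per line; extra
#' tab-separated columns, as in 10x \code{genes.tsv}, are ignored beyond the
#' first). Indices are 1-based on disk as usual for the MTX dialect.
#'
#' @param matrix_path path to the \code{.mtx} triplet file.
#' @param genes_path path to the gene identifier file (rows).
#' @param barcodes_path path to the cell barcode file (columns).
#' @param cell_meta optional per-cell metadata data.frame (see
#'   \code{\link{expression_matrix}}).
#' @return An \code{ExpressionMatrix} with \code{layer_tag = "counts"}.
#' @export
read_matrix_market <- function(matrix_path, genes_path, barcodes_path,
                               cell_meta = NULL) {
  for (p in c(matrix_path, genes_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")[[1]]
  cells <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")[[1]]
  if (nrow(m) != length(genes))
    stop("dimension mismatch: ", matrix_path, " declares ", nrow(m),
         " rows but ", genes_path, " lists ", length(genes), " genes")
  if (ncol(m) != length(cells))
    stop("dimension mismatch: ", matrix_path, " declares ", ncol(m),
         " columns but ", barcodes_path, " lists ", length(cells), " barcodes")
  expression_matrix(methods::as(m, "CsparseMatrix"), genes, cells,
                    cell_meta = cell_meta, layer_tag = "counts")
}

#' Write an ExpressionMatrix as Matrix Market triplet plus identifier files
#'
#' @param X an \code{ExpressionMatrix}.
#' @param matrix_path,genes_path,barcodes_path output paths.
#' @param meta_path optional path for the cell metadata TSV (written with a
#'   header when given).
#' @return Invisibly, the matrix path.
#' @export
write_matrix_market <- function(X, matrix_path, genes_path, barcodes_path,
                                meta_path = NULL) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  Matrix::writeMM(methods::as(Matrix::Matrix(X$values, sparse = TRUE),
                              "generalMatrix"), matrix_path)
  writeLines(X$gene_ids, genes_path)
  writeLines(X$cell_ids, barcodes_path)
  if (!is.null(meta_path))
    utils::write.table(X$cell_meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(matrix_path)
}

#' Read a cell metadata table (TSV with header)
#'
#' @param path TSV file with a header line; must contain a \code{cell_id}
#'   column.
#' @return data.frame keyed by \code{cell_id}.
#' @export
read_cell_meta <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (is.null(tab$cell_id)) stop("cell metadata must contain a cell_id column")
  tab
}

#' Read a GMT gene-set collection
#'
#' Tab-separated GMT: one set per line as \code{name<TAB>description<TAB>gene...}.
#' The per-set description is discarded; duplicate genes within a set are
#' removed (first occurrence kept). Order of sets follows the file.
#'
#' @param path GMT file path.
#' @return A \code{GeneSetCollection}: list with \code{sets} (named list of
#'   character vectors) and \code{source_tag} (the file path).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": expected >= 3 tab-separated ",
           "fields, got ", length(f))
    nm[i] <- f[1]
    sets[[i]] <- unique(f[-(1:2)])
  }
  names(sets) <- nm
  structure(list(sets = sets, source_tag = path), class = "GeneSetCollection")
}

#' Library-size normalize a counts matrix
#'
#' Per cell, counts are divided by the cell total, multiplied by
#' \code{scale}, and transformed with \code{log(1 + x)} in base
#' \code{log_base}. All-zero cells remain all-zero. Re-application is refused
#' via the layer tag.
#'
#' @param X \code{ExpressionMatrix} with \code{layer_tag = "counts"}.
#' @param scale library-size target (default 1e4).
#' @param log_base logarithm base; default \code{exp(1)} (natural log).
#' @return An \code{ExpressionMatrix} with \code{layer_tag = "normalized"}.
#' @export
normalize_cells <- function(X, scale = 1e4, log_base = exp(1)) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  if (X$layer_tag != "counts")
    stop("normalize_cells expects a counts layer; got '", X$layer_tag, "'")
  totals <- Matrix::colSums(X$values)
  fac <- ifelse(totals > 0, scale / totals, 0)
  v <- X$values %*% Matrix::Diagonal(x = fac)
  if (methods::is(v, "sparseMatrix")) {
    v <- methods::as(v, "CsparseMatrix")
    v@x <- log1p(v@x) / log(log_base)
  } else {
    v <- log1p(as.matrix(v)) / log(log_base)
  }
  expression_matrix(v, X$gene_ids, X$cell_ids, X$cell_meta,
                    layer_tag = "normalized")
}

#' Basic quality-control filter
#'
#' Configurable thresholds for minimum detected genes per cell and maximum
#' mitochondrial fraction. Defaults are permissive (no filtering).
#'
#' @param X \code{ExpressionMatrix} (counts).
#' @param min_genes_per_cell keep cells with at least this many detected
#'   (count > 0) genes.
#' @param max_mito_fraction keep cells whose summed counts over
#'   \code{mito_genes} divided by total counts do not exceed this fraction.
#' @param mito_genes gene identifiers counted as mitochondrial.
#' @return Filtered \code{ExpressionMatrix}.
#' @export
qc_filter <- function(X, min_genes_per_cell = 0, max_mito_fraction = 1,
                      mito_genes = character()) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  detected <- Matrix::colSums(X$values > 0)
  keep <- detected >= min_genes_per_cell
  if (length(mito_genes) && max_mito_fraction < 1) {
    mg <- intersect(mito_genes, X$gene_ids)
    tot <- Matrix::colSums(X$values)
    mito <- if (length(mg)) Matrix::colSums(X$values[mg, , drop = FALSE]) else 0
    frac <- ifelse(tot > 0, mito / tot, 0)
    keep <- keep & frac <= max_mito_fraction
  }
  subset_cells(X, X$cell_ids[keep])
}

#' Subset an ExpressionMatrix by cell identifiers
#'
#' @param X \code{ExpressionMatrix}.
#' @param cells character vector of cell identifiers to keep (order kept).
#' @return \code{ExpressionMatrix} restricted to \code{cells}.
#' @export
subset_cells <- function(X, cells) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  idx <- match(cells, X$cell_ids)
  if (anyNA(idx)) stop("unknown cell identifiers in subset")
  expression_matrix(X$values[, idx, drop = FALSE], X$gene_ids, cells,
                    X$cell_meta[idx, , drop = FALSE], layer_tag = X$layer_tag)
}
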