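#' Prepare gene profiles for SOM training
#'
#' Each gene's expression profile over the meta-cells is centered to zero
#' mean, the differential-expression convention of the portraits: values
#' express over-/under-expression relative to the gene's average. Genes
#' constant across meta-cells (including all-zero genes) are retained with
#' an all-zero profile.
#'
#' @param M \code{MetaCellSet}.
#' @return numeric matrix, genes x meta-cells, rows centered.
#' @export
prepare_gene_profiles <- function(M) {
  stopifnot(inherits(M, "MetaCellSet"))
  p <- t(M$centroids)                      # genes x meta-cells
  p - rowMeans(p)
}

.grid_coords <- function(rows, cols) {
  ## unit u (1-based) sits at 0-based (row, col) in row-major order
  cbind(row = (seq_len(rows * cols) - 1) %/% cols,
        col = (seq_len(rows * cols) - 1) %% cols)
}

## squared Euclidean distances between rows of a and rows of b
.cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

.best_matching_unit <- function(profiles, weights) {
  max.col(-.cross_dist2(profiles, weights), ties.method = "first")
}

#' Train a rectangular self-organizing map on gene profiles
#'
#' Batch SOM: each epoch all genes are assigned to their best-matching unit
#' (BMU, minimum Euclidean distance), then every unit's weight vector is
#' replaced by the neighborhood-weighted mean of the gene profiles, with a
#' Gaussian kernel over planar grid distance whose width anneals from
#' \code{sigma_start} to \code{sigma_end}. Weights are initialized
#' linearly along the first two principal components of the profiles
#' (deterministic), with a seeded random fallback for degenerate input.
#' After the annealed epochs, updates continue at \code{sigma_end} until
#' the assignment reaches a fixed point, so every gene maps to its true
#' BMU of the final weights and the final weights reflect exactly those
#' assignments.
#'
#' @param profiles genes x meta-cells matrix from
#'   \code{\link{prepare_gene_profiles}}; values must be finite.
#' @param rows,cols grid shape (default 40 x 40 = 1,600 meta-genes).
#' @param epochs training epochs (default 100).
#' @param sigma_start,sigma_end neighborhood width schedule in grid units;
#'   defaults \code{cols / 2} and 0.5.
#' @param init \code{"linear"} (principal-component plane) or
#'   \code{"random"} (seeded sample of gene profiles).
#' @param anneal \code{"geometric"} (default) or \code{"linear"} decay of
#'   the neighborhood width; the linear schedule spends more epochs at
#'   intermediate widths.
#' @param max_converge after the annealed epochs, batch updates continue
#'   at \code{sigma_end} until the gene assignment is a fixed point (at
#'   most this many extra iterations), so the stored weights are
#'   consistent with the final gene-to-unit map.
#' @param seed integer seed (used by the random fallback/initialization).
#' @return A \code{SOMModel}: list with \code{grid_rows}, \code{grid_cols},
#'   \code{weights} (units x meta-cells, row-major unit order),
#'   \code{gene_to_unit} (named integer, 1-based unit index),
#'   \code{training_log} (per-epoch mean quantization error, i.e. mean
#'   Euclidean BMU distance), \code{grid} (0-based unit coordinates).
#' @export
train_som <- function(profiles, rows = 40, cols = 40, epochs = 100,
                      sigma_start = cols / 2, sigma_end = 0.5,
                      init = c("linear", "random"),
                      anneal = c("geometric", "linear"),
                      max_converge = 30, seed = 1) {
  init <- match.arg(init)
  anneal <- match.arg(anneal)
  profiles <- as.matrix(profiles)
  if (any(!is.finite(profiles))) stop("profiles contain non-finite values")
  n_units <- rows * cols
  if (n_units < 4) stop("grid must have at least 4 units")
  if (nrow(profiles) < n_units / 10)
    warning("fewer than rows*cols/10 genes; the map will be sparsely populated")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("gene%d", seq_len(nrow(profiles)))

  grid <- .grid_coords(rows, cols)
  grid_d2 <- .cross_dist2(grid, grid)

  weights <- .init_weights(profiles, grid, init, seed)

  update_weights <- function(weights, bmu, sigma) {
    h <- exp(-grid_d2 / (2 * sigma^2))     # units x units kernel
    ## counts of genes per BMU, then neighborhood-weighted profile means
    counts <- tabulate(bmu, nbins = n_units)
    sums <- matrix(0, n_units, ncol(profiles))
    sums[sort(unique(bmu)), ] <- rowsum(profiles, bmu)
    num <- h %*% sums
    den <- as.vector(h %*% counts)
    upd <- den > 1e-12
    weights[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    weights
  }

  qe <- numeric(0)
  for (e in seq_len(epochs)) {
    d2 <- .cross_dist2(profiles, weights)
    bmu <- max.col(-d2, ties.method = "first")
    qe[e] <- mean(sqrt(d2[cbind(seq_len(nrow(profiles)), bmu)]))
    frac <- if (epochs == 1) 1 else (e - 1) / (epochs - 1)
    sigma <- if (anneal == "geometric")
      sigma_start * (sigma_end / sigma_start)^frac
    else sigma_start + (sigma_end - sigma_start) * frac
    weights <- update_weights(weights, bmu, sigma)
  }
  ## convergence phase at the final neighborhood width: iterate batch
  ## updates until the gene assignment is a fixed point, so the final
  ## weights are consistent with the final gene -> unit map
  final <- .best_matching_unit(profiles, weights)
  for (e in seq_len(max_converge)) {
    prev <- final
    weights <- update_weights(weights, final, sigma_end)
    d2 <- .cross_dist2(profiles, weights)
    final <- max.col(-d2, ties.method = "first")
    qe[length(qe) + 1] <- mean(sqrt(d2[cbind(seq_len(nrow(profiles)), final)]))
    if (identical(prev, final)) break
  }
  structure(list(grid_rows = rows, grid_cols = cols, weights = weights,
                 gene_to_unit = stats::setNames(final, rownames(profiles)),
                 training_log = qe, grid = grid),
            class = "SOMModel")
}

.init_weights <- function(profiles, grid, init, seed) {
  n_units <- nrow(grid)
  m <- ncol(profiles)
  center <- colMeans(profiles)
  if (init == "linear" && nrow(profiles) >= 3) {
    pc <- tryCatch({
      x <- sweep(profiles, 2, center, "-")
      ev <- eigen(crossprod(x) / max(1, nrow(x) - 1), symmetric = TRUE)
      list(v = ev$vectors[, 1:2, drop = FALSE],
           sd = sqrt(pmax(ev$values[1:2], 0)))
    }, error = function(e) NULL)
    if (!is.null(pc) && all(pc$sd > 0)) {
      ## span [-2, 2] standard deviations across each grid axis
      s1 <- (grid[, "col"] / max(1, max(grid[, "col"])) - 0.5) * 4 * pc$sd[1]
      s2 <- (grid[, "row"] / max(1, max(grid[, "row"])) - 0.5) * 4 * pc$sd[2]
      w <- outer(s1, pc$v[, 1]) + outer(s2, pc$v[, 2])
      return(sweep(w, 2, center, "+"))
    }
  }
  set.seed(as.integer(seed))
  profiles[sample(nrow(profiles), n_units, replace = TRUE), , drop = FALSE]
}

#' @export
print.SOMModel <- function(x, ...) {
  cat("SOMModel:", x$grid_rows, "x", x$grid_cols, "grid,",
      length(x$gene_to_unit), "genes over", ncol(x$weights), "meta-cells;",
      "final quantization error", signif(utils::tail(x$training_log, 1), 4), "\n")
  invisible(x)
}

#' Grid positions of genes
#'
#' Maps trained genes to their 0-based (row, col) grid coordinates. Genes
#' absent from the model are reported in the \code{missing} attribute, not
#' an error.
#'
#' @param model \code{SOMModel}.
#' @param gene_list gene identifiers.
#' @return data.frame with columns \code{gene}, \code{unit}, \code{row},
#'   \code{col}; attribute \code{missing} lists unknown genes.
#' @export
project_genes <- function(model, gene_list) {
  stopifnot(inherits(model, "SOMModel"))
  known <- intersect(gene_list, names(model$gene_to_unit))
  u <- model$gene_to_unit[known]
  out <- data.frame(gene = known, unit = unname(u),
                    row = model$grid[u, "row"], col = model$grid[u, "col"],
                    stringsAsFactors = FALSE)
  attr(out, "missing") <- setdiff(gene_list, known)
  out
}

#' Serialize a SOMModel to a directory of TSVs
#'
#' Writes \code{weights.tsv} (units x meta-cells), \code{gene_to_unit.tsv}
#' and \code{training_log.tsv}.
#'
#' @param model \code{SOMModel}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_som <- function(model, dir) {
  stopifnot(inherits(model, "SOMModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(model$weights, file.path(dir, "weights.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(data.frame(gene = names(model$gene_to_unit),
                                unit = unname(model$gene_to_unit)),
                     file.path(dir, "gene_to_unit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(epoch = seq_along(model$training_log),
                                quantization_error = model$training_log),
                     file.path(dir, "training_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
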