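## PCA scores via eigen-decomposition on the smaller side of the centered
## matrix; avoids a full SVD of a large cells x genes array.
.pca_scores <- function(x, rank) {
  x <- as.matrix(x)
  x <- sweep(x, 2, colMeans(x), "-")
  rank <- min(rank, dim(x) - c(1, 0))
  if (ncol(x) <= nrow(x)) {
    ev <- eigen(crossprod(x), symmetric = TRUE)
    k <- min(rank, sum(ev$values > 1e-10))
    x %*% ev$vectors[, seq_len(max(k, 1)), drop = FALSE]
  } else {
    ev <- eigen(tcrossprod(x), symmetric = TRUE)
    k <- min(rank, sum(ev$values > 1e-10))
    ev$vectors[, seq_len(max(k, 1)), drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[seq_len(max(k, 1))], 0)), max(k, 1))
  }
}

#' Base clustering of cells
#'
#' Unsupervised partition of the cells used as the first of the three
#' downsampling steps: k-means on the top principal components of the
#' normalized expression. Any externally computed partition (e.g. a graph
#' clustering) can be injected into \code{\link{build_metacells}} instead.
#'
#' @param X normalized \code{ExpressionMatrix}.
#' @param k number of clusters.
#' @param n_pcs principal components used (default 30).
#' @param seed integer seed; labels are deterministic for a fixed seed.
#' @return integer vector of cluster labels named by cell identifier.
#' @export
base_cluster <- function(X, k, n_pcs = 30, seed = 1) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  n <- length(X$cell_ids)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")")
  if (k == 1) return(stats::setNames(rep(1L, n), X$cell_ids))
  scores <- .pca_scores(Matrix::t(X$values), n_pcs)
  set.seed(as.integer(seed))
  km <- stats::kmeans(scores, centers = k, nstart = 5, iter.max = 50)
  stats::setNames(as.integer(km$cluster), X$cell_ids)
}

#' Build meta-cells by sample-wise refinement clustering
#'
#' Steps two and three of the downsampling: each base cluster is divided
#' into sample-specific sub-clusters, and each (cluster, sample) cell set is
#' subdivided by a refinement k-means with
#' \code{k = max(1, round(n / cells_per_metacell))}. Each refinement
#' centroid — the mean normalized expression of its member cells — becomes a
#' meta-cell, a proxy for all single cells of the sub-cluster. A meta-cell
#' therefore contains cells of exactly one sample, and the overall reduction
#' factor is approximately \code{cells_per_metacell}.
#'
#' @param X normalized \code{ExpressionMatrix}; \code{cell_meta$sample_id}
#'   is required.
#' @param base_labels labels from \code{\link{base_cluster}} (or any total
#'   partition over the cells, named or in cell order).
#' @param cells_per_metacell target meta-cell size (default 100).
#' @param n_pcs principal components used in the refinement k-means.
#' @param seed integer seed.
#' @return A \code{MetaCellSet}: list with \code{centroids} (meta-cells x
#'   genes), \code{assignment} (cell -> meta-cell index, named integer),
#'   \code{provenance} (data.frame: meta_cell, base_cluster, sample_id,
#'   refinement_cluster), \code{sizes}.
#' @export
build_metacells <- function(X, base_labels, cells_per_metacell = 100,
                            n_pcs = 10, seed = 1) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  n <- length(X$cell_ids)
  if (length(base_labels) != n)
    stop("base_labels must label every cell")
  if (!is.null(names(base_labels)))
    base_labels <- base_labels[X$cell_ids]
  sample_id <- X$cell_meta$sample_id
  if (is.null(sample_id) || anyNA(sample_id))
    stop("cell_meta must supply a sample_id for every cell")

  set.seed(as.integer(seed))
  dense <- as.matrix(Matrix::t(X$values))   # cells x genes
  assignment <- integer(n)
  centroids <- list(); prov <- list(); sizes <- integer()
  mc <- 0L
  for (cl in sort(unique(base_labels))) {
    for (s in sort(unique(sample_id[base_labels == cl]))) {
      idx <- which(base_labels == cl & sample_id == s)
      k <- max(1L, as.integer(round(length(idx) / cells_per_metacell)))
      k <- min(k, length(idx))
      sub <- if (k == 1) {
        rep(1L, length(idx))
      } else if (k == length(idx)) {
        seq_along(idx)                  # one meta-cell per cell
      } else {
        scores <- .pca_scores(dense[idx, , drop = FALSE], n_pcs)
        as.integer(stats::kmeans(scores, centers = k, nstart = 3,
                                 iter.max = 50)$cluster)
      }
      for (r in seq_len(k)) {
        mc <- mc + 1L
        member <- idx[sub == r]
        assignment[member] <- mc
        centroids[[mc]] <- colMeans(dense[member, , drop = FALSE])
        sizes[mc] <- length(member)
        prov[[mc]] <- data.frame(meta_cell = mc, base_cluster = cl,
                                 sample_id = s, refinement_cluster = r)
      }
    }
  }
  centroids <- do.call(rbind, centroids)
  rownames(centroids) <- sprintf("mc%04d", seq_len(mc))
  colnames(centroids) <- X$gene_ids
  structure(list(centroids = centroids,
                 assignment = stats::setNames(assignment, X$cell_ids),
                 provenance = do.call(rbind, prov),
                 sizes = sizes),
            class = "MetaCellSet")
}

#' @export
print.MetaCellSet <- function(x, ...) {
  cat("MetaCellSet:", nrow(x$centroids), "meta-cells over",
      length(x$assignment), "cells (",
      round(length(x$assignment) / nrow(x$centroids), 1), "cells/meta-cell )\n")
  invisible(x)
}

#' Serialize a MetaCellSet to TSV files
#'
#' @param M \code{MetaCellSet}.
#' @param centroid_path dense TSV of centroids (meta-cells in rows).
#' @param assignment_path TSV of cell_id, meta_cell.
#' @return Invisibly, \code{centroid_path}.
#' @export
write_metacells <- function(M, centroid_path, assignment_path) {
  stopifnot(inherits(M, "MetaCellSet"))
  utils::write.table(M$centroids, centroid_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(data.frame(cell_id = names(M$assignment),
                                meta_cell = unname(M$assignment)),
                     assignment_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(centroid_path)
}
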