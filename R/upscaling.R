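#' Fit the meta-gene upscaler
#'
#' Transfer learning from meta-cell to single-cell resolution: for every
#' non-empty grid unit, a regression model is fitted on the meta-cells from
#' the unit's member-gene expression (centered per gene by its meta-cell
#' mean, the same centering as the training profiles) to the unit's weight
#' vector. Units with a single member gene use that gene's centered value
#' directly; units with a constant weight vector use that constant. Empty
#' units inherit the predictor of the nearest non-empty unit by Euclidean
#' grid distance (ties broken by the lower unit index). Applying the fitted
#' upscaler to any cell's gene expression then predicts all meta-gene
#' values without re-running the SOM.
#'
#' @param model \code{SOMModel}.
#' @param M the \code{MetaCellSet} the SOM was trained on.
#' @param method \code{"svr"} (support-vector regression, linear kernel,
#'   eps-regression; default) or \code{"lm"} (least squares), both behind
#'   the same contract.
#' @param cost SVR cost parameter (default 1).
#' @return An \code{Upscaler}: list with \code{predictors} (per unit:
#'   type, genes, fit), \code{source_unit} (unit whose predictor each unit
#'   uses), \code{gene_center} (per-gene centering constants),
#'   \code{grid_rows}, \code{grid_cols}.
#' @export
fit_upscaler <- function(model, M, method = c("svr", "lm"), cost = 1) {
  method <- match.arg(method)
  stopifnot(inherits(model, "SOMModel"), inherits(M, "MetaCellSet"))
  if (ncol(model$weights) != nrow(M$centroids))
    stop("SOM was trained on ", ncol(model$weights),
         " meta-cells but the MetaCellSet has ", nrow(M$centroids))
  n_units <- model$grid_rows * model$grid_cols
  gene_center <- colMeans(M$centroids)             # per-gene mean over meta-cells
  centered <- sweep(M$centroids, 2, gene_center, "-")  # meta-cells x genes

  genes_of_unit <- split(names(model$gene_to_unit),
                         factor(model$gene_to_unit, levels = seq_len(n_units)))
  predictors <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    g <- genes_of_unit[[u]]
    if (!length(g)) next
    y <- model$weights[u, ]
    if (stats::sd(y) < 1e-12) {
      predictors[[u]] <- list(type = "constant", genes = character(),
                              value = mean(y))
    } else if (length(g) == 1) {
      predictors[[u]] <- list(type = "passthrough", genes = g)
    } else {
      xmat <- centered[, g, drop = FALSE]
      keep <- apply(xmat, 2, stats::sd) > 1e-12
      if (any(keep)) { xmat <- xmat[, keep, drop = FALSE]; g <- g[keep] }
      fit <- NULL
      type <- method
      if (method == "svr") {
        ## epsilon-tube scaled to the target spread so that low-variance
        ## meta-genes still produce support vectors
        fit <- tryCatch(
          e1071::svm(x = xmat, y = y, type = "eps-regression",
                     kernel = "linear", cost = cost,
                     epsilon = 0.05, scale = TRUE),
          error = function(e) NULL)
        if (is.null(fit)) type <- "lm"
      }
      if (type == "lm") fit <- stats::lm.fit(cbind(1, xmat), y)
      predictors[[u]] <- list(type = type, genes = g, fit = fit)
    }
  }
  nonempty <- which(!vapply(predictors, is.null, logical(1)))
  if (!length(nonempty)) stop("no unit has a member gene; SOM not trained?")
  source_unit <- integer(n_units)
  d2 <- .cross_dist2(model$grid, model$grid[nonempty, , drop = FALSE])
  for (u in seq_len(n_units)) {
    if (u %in% nonempty) { source_unit[u] <- u; next }
    best <- min(d2[u, ])
    source_unit[u] <- nonempty[which(d2[u, ] <= best + 1e-12)[1]]
  }
  structure(list(predictors = predictors, source_unit = source_unit,
                 gene_center = gene_center, method = method,
                 grid_rows = model$grid_rows, grid_cols = model$grid_cols),
            class = "Upscaler")
}

#' Predict meta-gene values for single cells
#'
#' Applies the fitted per-unit predictors to each cell's gene expression
#' (centered with the meta-cell gene means stored in the upscaler). Member
#' genes missing from the matrix are imputed as zero expression with a
#' warning. Feeding a row of the result to \code{\link{portrait_of}} yields
#' the cell's expression portrait.
#'
#' @param up \code{Upscaler}.
#' @param X \code{ExpressionMatrix} (normalized, same gene space as the
#'   training data).
#' @return numeric matrix, cells x units.
#' @export
predict_metagenes <- function(up, X) {
  stopifnot(inherits(up, "Upscaler"), inherits(X, "ExpressionMatrix"))
  n_units <- up$grid_rows * up$grid_cols
  needed <- unique(unlist(lapply(up$predictors,
                                 function(p) if (is.null(p)) NULL else p$genes)))
  missing <- setdiff(needed, X$gene_ids)
  if (length(missing))
    warning(length(missing), " member gene(s) absent from the matrix; ",
            "imputed as zero expression")
  ## cells x genes centered feature matrix over needed genes
  feat <- matrix(0, length(X$cell_ids), length(needed),
                 dimnames = list(X$cell_ids, needed))
  present <- intersect(needed, X$gene_ids)
  feat[, present] <- as.matrix(Matrix::t(X$values[present, , drop = FALSE]))
  feat <- sweep(feat, 2, up$gene_center[needed], "-")

  out <- matrix(0, length(X$cell_ids), n_units,
                dimnames = list(X$cell_ids, NULL))
  cache <- list()
  for (u in seq_len(n_units)) {
    src <- up$source_unit[u]
    key <- as.character(src)
    if (is.null(cache[[key]])) {
      p <- up$predictors[[src]]
      cache[[key]] <- switch(p$type,
        constant = rep(p$value, nrow(feat)),
        passthrough = feat[, p$genes],
        svr = as.numeric(stats::predict(p$fit, feat[, p$genes, drop = FALSE])),
        lm = {
          cf <- p$fit$coefficients
          cf[is.na(cf)] <- 0
          as.numeric(cbind(1, feat[, p$genes, drop = FALSE]) %*% cf)
        })
    }
    out[, u] <- cache[[key]]
  }
  out
}
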