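## connected components on a set of grid units (1-based indices) under
## 8- or 4-neighborhood adjacency; returns an integer component label per unit
.connected_components <- function(units, rows, cols, neighborhood = 8) {
  if (!length(units)) return(integer())
  inset <- logical(rows * cols)
  inset[units] <- TRUE
  comp <- rep(NA_integer_, length(units))
  names(comp) <- as.character(units)
  pos <- cbind(r = (units - 1) %/% cols, c = (units - 1) %% cols)
  offsets <- if (neighborhood == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  lab <- 0L
  for (i in seq_along(units)) {
    if (!is.na(comp[i])) next
    lab <- lab + 1L
    queue <- units[i]
    comp[i] <- lab
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      r <- (u - 1) %/% cols; cc <- (u - 1) %% cols
      nr <- r + offsets$dr; nc <- cc + offsets$dc
      ok <- nr >= 0 & nr < rows & nc >= 0 & nc < cols
      nb <- nr[ok] * cols + nc[ok] + 1
      nb <- nb[inset[nb]]
      j <- match(nb, units)
      new <- j[is.na(comp[j])]
      comp[new] <- lab
      queue <- c(queue, units[new])
    }
  }
  comp
}

## Segmentation of one connected component of selected units into spots of
## correlated meta-genes. Local peaks of the summary over-expression
## landscape S seed the spots; peaks whose weight profiles correlate at
## least `split_correlation` describe the same expression pattern and are
## merged into one seed group. The remaining units are flooded in order of
## decreasing S, each joining the adjacent seed group whose peak profile
## correlates best with its own weight vector, so the cut between two
## adjacent spots falls where the meta-gene profiles change character.
## Deterministic: ties broken by unit index / group id.
.segment_component <- function(units, S, weights, seeds, rows, cols,
                               neighborhood, split_correlation) {
  offsets <- if (neighborhood == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  pos_of_unit <- match(seq_len(rows * cols), units)
  neighbors <- lapply(units, function(u) {
    r <- (u - 1) %/% cols; cc <- (u - 1) %% cols
    nr <- r + offsets$dr; nc <- cc + offsets$dc
    ok <- nr >= 0 & nr < rows & nc >= 0 & nc < cols
    nb <- pos_of_unit[nr[ok] * cols + nc[ok] + 1]
    nb[!is.na(nb)]
  })
  seed_idx <- pos_of_unit[intersect(seeds, units)]
  if (!length(seed_idx)) seed_idx <- order(-S, units)[1]
  seed_idx <- seed_idx[order(-S[seed_idx], units[seed_idx])]
  ## group seeds by weight-profile correlation to the group's first seed
  group_top <- integer(0)
  region <- rep(NA_integer_, length(units))
  for (p in seed_idx) {
    g_hit <- 0L
    for (g in seq_along(group_top)) {
      r <- suppressWarnings(stats::cor(weights[units[p], ],
                                       weights[units[group_top[g]], ]))
      if (!is.na(r) && r >= split_correlation) { g_hit <- g; break }
    }
    if (!g_hit) { group_top <- c(group_top, p); g_hit <- length(group_top) }
    region[p] <- g_hit
  }
  ## flood remaining units in decreasing S, joining the best-correlated
  ## adjacent group; repeat until the component is covered (connectivity
  ## guarantees progress)
  ord <- order(-S, units)
  repeat {
    todo <- ord[is.na(region[ord])]
    if (!length(todo)) break
    progress <- FALSE
    for (i in todo) {
      cand <- unique(region[neighbors[[i]]])
      cand <- cand[!is.na(cand)]
      if (!length(cand)) next
      if (length(cand) == 1) { region[i] <- cand }
      else {
        rr <- vapply(cand, function(g)
          suppressWarnings(stats::cor(weights[units[i], ],
                                      weights[units[group_top[g]], ])),
          numeric(1))
        rr[is.na(rr)] <- -Inf
        region[i] <- cand[order(-rr, cand)][1]
      }
      progress <- TRUE
    }
    if (!progress) { region[is.na(region)] <- 1L; break }
  }
  region
}

#' Extract over-expression spot modules from portraits
#'
#' In every portrait, units whose value reaches \code{threshold_fraction}
#' of that portrait's maximum are selected (a portrait with non-positive
#' maximum contributes nothing). The union of selected units over all
#' portraits is decomposed into connected areas under the chosen adjacency.
#' A spot is a region of correlated meta-genes, so each area is further
#' segmented where the meta-gene profiles change character: the peak unit
#' of every portrait seeds a spot, seeds whose weight profiles correlate
#' at least \code{split_correlation} are treated as one spot, and every
#' remaining unit joins the adjacent seed group with the most similar
#' profile (flooding in order of decreasing summary over-expression, the
#' per-unit maximum of the portrait-normalized values). Adjacent spots
#' driven by distinct expression patterns thereby become distinct modules
#' even when no expression gap separates them.
#' Segments with at least \code{min_units} units become spot modules. A
#' module's genes are the genes mapped to its member units, so each gene
#' belongs to at most one module. Modules are lettered by
#' \code{\link{label_modules}}.
#'
#' @param model \code{SOMModel}.
#' @param portraits list of \code{Portrait} objects over the model's grid;
#'   defaults to \code{\link{metacell_portraits}(model)}.
#' @param threshold_fraction over-expression threshold as fraction of each
#'   portrait's maximum (default 0.90).
#' @param min_units minimum units per module (default 3).
#' @param neighborhood 8 (default) or 4.
#' @param split_correlation two over-expression peaks within one connected
#'   area are treated as the same spot when their meta-gene weight
#'   profiles correlate at least this much (default 0.9); set to a value
#'   > 1 to disable splitting, reducing modules to plain connected
#'   components.
#' @return A \code{SpotModuleMap}: list with \code{modules} (list of
#'   \code{label}, \code{units} (1-based), \code{genes}), \code{overview}
#'   (grid matrix of labels or NA), \code{threshold_fraction},
#'   \code{grid_rows}, \code{grid_cols}.
#' @export
extract_spots <- function(model, portraits = NULL, threshold_fraction = 0.90,
                          min_units = 3, neighborhood = 8,
                          split_correlation = 0.9) {
  stopifnot(inherits(model, "SOMModel"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie strictly between 0 and 1")
  if (is.null(portraits)) portraits <- metacell_portraits(model)
  rows <- model$grid_rows; cols <- model$grid_cols
  S <- rep(0, rows * cols)      # summary: max portrait-normalized value
  seeds <- integer()            # each portrait's peak unit seeds a spot
  for (p in portraits) {
    v <- as.vector(t(unclass(p)))       # row-major unit order
    mx <- max(v)
    if (mx <= 0) next
    S <- pmax(S, v / mx)
    seeds <- c(seeds, which.max(v))
  }
  seeds <- unique(seeds)
  units <- which(S >= threshold_fraction)
  comp <- .connected_components(units, rows, cols, neighborhood)
  modules <- list()
  for (l in seq_len(max(c(comp, 0L)))) {
    cu <- units[comp == l]
    seg <- if (split_correlation <= 1 && length(cu) > 1)
      .segment_component(cu, S[cu], model$weights, seeds, rows, cols,
                         neighborhood, split_correlation)
    else rep(1L, length(cu))
    for (s in unique(seg)) {
      u <- cu[seg == s]
      if (length(u) < min_units) next
      genes <- names(model$gene_to_unit)[model$gene_to_unit %in% u]
      modules[[length(modules) + 1]] <- list(label = "", units = u,
                                             genes = genes)
    }
  }
  map <- structure(list(modules = modules, overview = NULL,
                        threshold_fraction = threshold_fraction,
                        grid_rows = rows, grid_cols = cols),
                   class = "SpotModuleMap")
  label_modules(map)
}

.letter_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

#' Letter the modules of a spot-module map
#'
#' Letters A, B, C, ... are assigned by row-major grid-scan order of the
#' module centroids (mean row, then mean column), extended to AA, AB, ...
#' beyond 26 modules. Deterministic and idempotent: relabeling an already
#' labeled map reproduces the same letters.
#'
#' @param map \code{SpotModuleMap}.
#' @return the map with \code{label}s set and the \code{overview} grid
#'   filled (module letter per unit, NA outside modules).
#' @export
label_modules <- function(map) {
  stopifnot(inherits(map, "SpotModuleMap"))
  if (!length(map$modules)) { map$overview <- matrix(NA_character_,
    map$grid_rows, map$grid_cols); return(map) }
  cen <- t(vapply(map$modules, function(m) {
    r <- (m$units - 1) %/% map$grid_cols
    cc <- (m$units - 1) %% map$grid_cols
    c(mean(r), mean(cc))
  }, numeric(2)))
  ord <- order(cen[, 1], cen[, 2])
  labels <- .letter_labels(length(ord))
  map$modules <- map$modules[ord]
  for (i in seq_along(map$modules)) map$modules[[i]]$label <- labels[i]
  ov <- matrix(NA_character_, map$grid_rows, map$grid_cols)
  for (m in map$modules) {
    r <- (m$units - 1) %/% map$grid_cols + 1
    cc <- (m$units - 1) %% map$grid_cols + 1
    ov[cbind(r, cc)] <- m$label
  }
  map$overview <- ov
  map
}

#' @export
print.SpotModuleMap <- function(x, ...) {
  cat("SpotModuleMap:", length(x$modules), "modules on a", x$grid_rows, "x",
      x$grid_cols, "grid (threshold", x$threshold_fraction, ")\n")
  for (m in x$modules)
    cat(" ", m$label, ":", length(m$units), "units,",
        length(m$genes), "genes\n")
  invisible(x)
}

#' Module gene lists
#'
#' @param map \code{SpotModuleMap}.
#' @return named list, module letter -> gene identifiers.
#' @export
module_genes <- function(map) {
  stopifnot(inherits(map, "SpotModuleMap"))
  stats::setNames(lapply(map$modules, `[[`, "genes"),
                  vapply(map$modules, `[[`, character(1), "label"))
}

#' Per-cell module expression
#'
#' For each cell and module, the mean normalized expression over the
#' module's genes present in the matrix. A module with no gene in the
#' matrix yields an NA column with a warning.
#'
#' @param X \code{ExpressionMatrix}.
#' @param map \code{SpotModuleMap} (or a named list of gene vectors).
#' @return numeric matrix, cells x modules, with cell ids as row names and
#'   module labels as column names.
#' @export
module_expression <- function(X, map) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  sets <- if (inherits(map, "SpotModuleMap")) module_genes(map) else map
  out <- matrix(NA_real_, length(X$cell_ids), length(sets),
                dimnames = list(X$cell_ids, names(sets)))
  for (i in seq_along(sets)) {
    g <- intersect(sets[[i]], X$gene_ids)
    if (!length(g)) {
      warning("module '", names(sets)[i], "' has no gene in the matrix")
      next
    }
    out[, i] <- Matrix::colMeans(X$values[g, , drop = FALSE])
  }
  out
}

#' Gene-set over-representation in spot modules
#'
#' Right-tailed Fisher's exact test per (module, gene set): the 2x2 table
#' counts universe genes by module membership and set membership; the
#' p-value is the hypergeometric upper tail of the overlap. Per module,
#' sets are reported sorted ascending by p.
#'
#' @param map \code{SpotModuleMap}.
#' @param collection \code{GeneSetCollection} from \code{\link{read_gmt}}
#'   (or a named list of gene vectors).
#' @param universe gene identifiers forming the test universe; must contain
#'   every module gene.
#' @param top_n optional: keep only the top-n sets per module.
#' @return data.frame with columns \code{module}, \code{set},
#'   \code{overlap}, \code{module_size}, \code{set_size}, \code{universe},
#'   \code{p_value}.
#' @export
geneset_annotation <- function(map, collection, universe, top_n = Inf) {
  stopifnot(inherits(map, "SpotModuleMap"))
  sets <- if (inherits(collection, "GeneSetCollection")) collection$sets
          else collection
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  mg <- module_genes(map)
  bad <- unlist(lapply(mg, setdiff, universe))
  if (length(bad))
    stop("universe must contain every module gene; missing e.g. ", bad[1])
  res <- list()
  for (mod in names(mg)) {
    k <- length(mg[[mod]])
    for (s in names(sets)) {
      set_u <- intersect(sets[[s]], universe)
      ov <- length(intersect(mg[[mod]], set_u))
      p <- stats::phyper(ov - 1, length(set_u),
                         length(universe) - length(set_u), k,
                         lower.tail = FALSE)
      res[[length(res) + 1]] <- data.frame(
        module = mod, set = s, overlap = ov, module_size = k,
        set_size = length(set_u), universe = length(universe),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$module, out$p_value), ]
  if (is.finite(top_n))
    out <- do.call(rbind, lapply(split(out, out$module), utils::head, top_n))
  rownames(out) <- NULL
  out
}

#' Write a spot-module map to TSV
#'
#' One row per module unit: unit index, 0-based row/col, module label; a
#' second file lists the module gene memberships.
#'
#' @param map \code{SpotModuleMap}.
#' @param units_path,genes_path output TSV paths.
#' @return Invisibly, \code{units_path}.
#' @export
write_module_map <- function(map, units_path, genes_path) {
  stopifnot(inherits(map, "SpotModuleMap"))
  rows <- do.call(rbind, lapply(map$modules, function(m)
    data.frame(unit = m$units,
               row = (m$units - 1) %/% map$grid_cols,
               col = (m$units - 1) %% map$grid_cols,
               label = m$label, stringsAsFactors = FALSE)))
  utils::write.table(rows, units_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- do.call(rbind, lapply(map$modules, function(m)
    if (length(m$genes)) data.frame(label = m$label, gene = m$genes,
                                    stringsAsFactors = FALSE)))
  utils::write.table(g, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(units_path)
}
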