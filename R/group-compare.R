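#' PAT enrichment per group (right-tailed Fisher's exact test)
#'
#' For every PAT and group, the 2x2 table counts cells by group membership
#' and PAT membership; the reported p-value is the hypergeometric upper
#' tail of the in-group overlap (right-tailed Fisher), together with its
#' -log10 transform. No multiple-testing correction is applied by default;
#' Benjamini-Hochberg is available via \code{adjust}.
#'
#' @param assign \code{PATAssignment}.
#' @param group_of_cell per-cell categorical (named by cell_id or in cell
#'   order).
#' @param include_none test the "none" class too (default FALSE).
#' @param adjust if TRUE, add a Benjamini-Hochberg adjusted column.
#' @return data.frame with columns \code{label}, \code{group},
#'   \code{in_group}, \code{pat_total}, \code{group_total}, \code{n},
#'   \code{p_value}, \code{minus_log10_p} (and \code{p_adjusted} when
#'   requested).
#' @export
pat_enrichment <- function(assign, group_of_cell, include_none = FALSE,
                           adjust = FALSE) {
  stopifnot(inherits(assign, "PATAssignment"))
  g <- group_of_cell
  if (!is.null(names(g))) g <- g[assign$cell_id]
  if (length(g) != nrow(assign)) stop("group_of_cell must cover every cell")
  if (anyNA(g)) stop("group_of_cell contains missing values")
  labs <- unique(assign$label)
  if (!include_none) labs <- setdiff(labs, "none")
  groups <- sort(unique(as.character(g)))
  n <- nrow(assign)
  res <- list()
  for (l in labs) {
    in_pat <- assign$label == l
    K <- sum(in_pat)
    for (gr in groups) {
      in_g <- g == gr
      a <- sum(in_pat & in_g)
      p <- stats::phyper(a - 1, K, n - K, sum(in_g), lower.tail = FALSE)
      res[[length(res) + 1]] <- data.frame(
        label = l, group = gr, in_group = a, pat_total = K,
        group_total = sum(in_g), n = n, p_value = p,
        minus_log10_p = -log10(p), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$group, out$p_value), , drop = FALSE]
}

#' Virtual PAT flow between two cell groups
#'
#' Computes per-group PAT frequencies (over classified cells by default,
#' i.e. excluding "none"), takes their differences, and iteratively
#' balances over-represented PATs in group A against the most similar
#' under-represented PATs in group B: the source with the largest
#' remaining surplus is matched to the remaining sink with the smallest
#' Euclidean distance between their mean module-expression vectors, the
#' transferable amount \code{min(surplus, deficit)} becomes an edge, and
#' the iteration continues until surpluses or deficits are exhausted.
#' Distance ties are broken by PAT label order, making the graph
#' deterministic.
#'
#' @param assign \code{PATAssignment}.
#' @param group_of_cell binary per-cell categorical (exactly two groups).
#' @param centroids PAT x module mean-expression matrix
#'   (\code{\link{pat_centroids}}); rows must cover every classified PAT.
#' @param include_none include the "none" class in the frequencies.
#' @return A \code{FlowGraph}: list with \code{edges} (data.frame: source,
#'   sink, flow), \code{residuals} (named numeric, unmatched surplus
#'   (positive) or deficit (negative)), \code{direction_tag} (group A,
#'   group B).
#' @export
pat_flow <- function(assign, group_of_cell, centroids,
                     include_none = FALSE) {
  stopifnot(inherits(assign, "PATAssignment"))
  g <- group_of_cell
  if (!is.null(names(g))) g <- g[assign$cell_id]
  if (length(g) != nrow(assign)) stop("group_of_cell must cover every cell")
  groups <- sort(unique(as.character(g)))
  if (length(groups) != 2)
    stop("pat_flow requires exactly 2 groups; got ", length(groups))
  keep <- if (include_none) rep(TRUE, nrow(assign)) else assign$label != "none"
  lab <- assign$label[keep]; gg <- g[keep]
  labs <- sort(unique(lab))
  freq <- function(gr) {
    tab <- table(factor(lab[gg == gr], levels = labs))
    as.numeric(tab) / max(1, sum(tab))
  }
  delta <- stats::setNames(freq(groups[1]) - freq(groups[2]), labs)
  missing <- setdiff(labs, rownames(centroids))
  if (length(missing))
    stop("centroids missing for PAT(s): ", paste(missing, collapse = ", "))

  surplus <- delta[delta > 0]
  deficit <- -delta[delta < 0]
  edges <- list()
  tol <- 1e-12
  while (length(surplus) && length(deficit) &&
         max(surplus) > tol && max(deficit) > tol) {
    src <- names(surplus)[order(-surplus, names(surplus))][1]
    d <- sqrt(rowSums((centroids[names(deficit), , drop = FALSE] -
                       matrix(centroids[src, ], length(deficit),
                              ncol(centroids), byrow = TRUE))^2))
    snk <- names(deficit)[order(d, names(deficit))][1]
    fl <- min(surplus[src], deficit[snk])
    edges[[length(edges) + 1]] <- data.frame(source = src, sink = snk,
                                             flow = unname(fl),
                                             stringsAsFactors = FALSE)
    surplus[src] <- surplus[src] - fl
    deficit[snk] <- deficit[snk] - fl
    surplus <- surplus[surplus > tol]
    deficit <- deficit[deficit > tol]
  }
  residuals <- c(surplus, -deficit)
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(source = character(), sink = character(),
                           flow = numeric(), stringsAsFactors = FALSE)
  structure(list(edges = edges, residuals = residuals,
                 direction_tag = groups), class = "FlowGraph")
}

#' @export
print.FlowGraph <- function(x, ...) {
  cat("FlowGraph:", nrow(x$edges), "edges,",
      x$direction_tag[1], "->", x$direction_tag[2],
      "; total flow", signif(sum(x$edges$flow), 4), "\n")
  invisible(x)
}

#' Write a flow graph as a TSV edge list and a Sankey-style JSON
#'
#' @param graph \code{FlowGraph}.
#' @param tsv_path edge-list TSV path.
#' @param json_path optional Sankey JSON path (nodes + links).
#' @return Invisibly, \code{tsv_path}.
#' @export
write_flow_graph <- function(graph, tsv_path, json_path = NULL) {
  stopifnot(inherits(graph, "FlowGraph"))
  utils::write.table(graph$edges, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    nodes <- unique(c(graph$edges$source, graph$edges$sink))
    links <- graph$edges
    links$source <- match(links$source, nodes) - 1
    links$sink <- match(links$sink, nodes) - 1
    names(links) <- c("source", "target", "value")
    jsonlite::write_json(list(nodes = lapply(nodes, function(n) list(name = n)),
                              links = links,
                              direction = graph$direction_tag),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
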