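#' Activation thresholds for module activation patterns
#'
#' Thresholds are expressed in units of sigma, the standard deviation of the
#' pooled, per-module-centered module-expression values over all cells: a
#' module is activated at minor level in a cell when its centered value
#' exceeds \code{minor_sigma} x sigma (default 0.5), at major level beyond
#' \code{major_sigma} x sigma (default 1.0). PATs carried by fewer than
#' \code{rare_fraction} of all cells (default 0.5\%) are rejected.
#'
#' @param major_sigma,minor_sigma,rare_fraction numeric thresholds.
#' @param pooled_sigma if \code{FALSE}, use a per-module standard deviation
#'   instead of the pooled one.
#' @return An \code{ActivationThresholds} object.
#' @export
activation_thresholds <- function(major_sigma = 1.0, minor_sigma = 0.5,
                                  rare_fraction = 0.005,
                                  pooled_sigma = TRUE) {
  if (!(0 < minor_sigma && minor_sigma < major_sigma))
    stop("0 < minor_sigma < major_sigma required")
  if (rare_fraction < 0 || rare_fraction >= 1)
    stop("rare_fraction must lie in [0, 1)")
  structure(list(major_sigma = major_sigma, minor_sigma = minor_sigma,
                 rare_fraction = rare_fraction, pooled_sigma = pooled_sigma),
            class = "ActivationThresholds")
}

#' Per-cell module activation levels
#'
#' Each module column of the module-expression matrix is centered across
#' cells; sigma is the standard deviation of the pooled centered matrix
#' (one value over all modules x cells; a per-module sigma is available via
#' the thresholds object). Activation levels are the centered values in
#' sigma units.
#'
#' @param E cells x modules module-expression matrix
#'   (\code{\link{module_expression}}).
#' @param thresholds \code{ActivationThresholds}.
#' @return list with \code{levels} (cells x modules, sigma units) and
#'   \code{sigma}.
#' @export
call_activation <- function(E, thresholds = activation_thresholds()) {
  E <- as.matrix(E)
  if (any(!is.finite(E))) stop("module expression must be finite")
  centered <- sweep(E, 2, colMeans(E), "-")
  if (thresholds$pooled_sigma) {
    sigma <- stats::sd(as.vector(centered))
    if (!is.finite(sigma) || sigma <= 0)
      stop("degenerate module expression: pooled standard deviation is zero")
    levels <- centered / sigma
  } else {
    sigma <- apply(centered, 2, stats::sd)
    if (any(sigma <= 0)) stop("degenerate module expression: a module has ",
                              "zero standard deviation")
    levels <- sweep(centered, 2, sigma, "/")
  }
  list(levels = levels, sigma = sigma)
}

#' Assign module activation patterns (PATs)
#'
#' A cell's activated set is the modules whose level exceeds
#' \code{minor_sigma}. The cell is a major PAT when all activated modules
#' also exceed \code{major_sigma} (uppercase letters), a minor PAT when at
#' least one falls below (lowercase letters), and "none" when the set is
#' empty. Within a label, letters are ordered by descending overall
#' activation frequency of the modules across all cells (the first letters
#' refer to the more abundant modules), recomputed from the data unless a
#' fixed order is supplied.
#'
#' @param levels result of \code{\link{call_activation}} (or a plain cells
#'   x modules matrix already in sigma units).
#' @param thresholds \code{ActivationThresholds}.
#' @param module_order optional character vector of module letters, most
#'   abundant first; default: by activation frequency at the minor level.
#' @return A \code{PATAssignment}: data.frame with columns \code{cell_id},
#'   \code{label}, \code{tier} ("major"/"minor"/"none"); attributes
#'   \code{module_order} and \code{activated} (logical cells x modules at
#'   the minor level).
#' @export
assign_pats <- function(levels, thresholds = activation_thresholds(),
                        module_order = NULL) {
  L <- if (is.list(levels) && !is.data.frame(levels)) levels$levels else levels
  L <- as.matrix(L)
  mods <- colnames(L)
  if (is.null(mods)) stop("module-expression matrix must have column names")
  act_minor <- L > thresholds$minor_sigma
  act_major <- L > thresholds$major_sigma
  if (is.null(module_order)) {
    freq <- colSums(act_minor)
    module_order <- mods[order(-freq, mods)]
  }
  n <- nrow(L)
  label <- character(n); tier <- character(n)
  ord <- match(module_order, mods)
  for (i in seq_len(n)) {
    a <- which(act_minor[i, ])
    if (!length(a)) { label[i] <- "none"; tier[i] <- "none"; next }
    major <- all(act_major[i, a])
    letters_i <- module_order[module_order %in% mods[a]]
    tier[i] <- if (major) "major" else "minor"
    label[i] <- paste(if (major) letters_i else tolower(letters_i),
                      collapse = " ")
  }
  out <- data.frame(cell_id = rownames(L) %||% sprintf("cell%d", seq_len(n)),
                    label = label, tier = tier, stringsAsFactors = FALSE)
  attr(out, "module_order") <- module_order
  attr(out, "activated") <- act_minor
  class(out) <- c("PATAssignment", "data.frame")
  out
}

#' Reject rare PATs
#'
#' Every distinct label (major and minor labels counted separately) carried
#' by strictly fewer than \code{rare_fraction} of all cells is dissolved;
#' its cells are re-labeled "none". Surviving labels are unchanged.
#'
#' @param assign \code{PATAssignment}.
#' @param rare_fraction rejection fraction (default 0.005 = 0.5\%).
#' @return the filtered \code{PATAssignment}; attribute \code{rejected}
#'   lists the dissolved labels.
#' @export
reject_rare <- function(assign, rare_fraction = 0.005) {
  stopifnot(inherits(assign, "PATAssignment"))
  if (rare_fraction <= 0) { attr(assign, "rejected") <- character(); return(assign) }
  counts <- table(assign$label)
  cutoff <- rare_fraction * nrow(assign)
  drop <- setdiff(names(counts)[counts < cutoff], "none")
  sel <- assign$label %in% drop
  assign$label[sel] <- "none"
  assign$tier[sel] <- "none"
  attr(assign, "rejected") <- drop
  assign
}

#' Rare-PAT rejection cutoff in cells
#'
#' The largest cell count still rejected: a PAT survives only with strictly
#' more cells than this.
#'
#' @param n_cells total number of cells.
#' @param rare_fraction rejection fraction.
#' @return integer cutoff.
#' @export
rare_cutoff <- function(n_cells, rare_fraction = 0.005) {
  x <- rare_fraction * n_cells
  as.integer(if (x == floor(x)) x - 1 else floor(x))
}

#' PAT frequency table
#'
#' Counts and fractions of each PAT per group, plus the overall tier
#' fractions (major/minor/none) with integer percentages.
#'
#' @param assign \code{PATAssignment}.
#' @param grouping optional per-cell categorical (named by cell_id or in
#'   cell order); default: a single group.
#' @return list with \code{pat} (data.frame: group, label, tier, count,
#'   fraction) and \code{tier} (data.frame: tier, count, fraction,
#'   percent).
#' @export
pat_frequency_table <- function(assign, grouping = NULL) {
  stopifnot(inherits(assign, "PATAssignment"))
  n <- nrow(assign)
  if (is.null(grouping)) grouping <- rep("all", n)
  if (!is.null(names(grouping))) grouping <- grouping[assign$cell_id]
  if (length(grouping) != n) stop("grouping must cover every cell")
  agg <- stats::aggregate(list(count = seq_len(n)),
                          by = list(group = grouping, label = assign$label,
                                    tier = assign$tier),
                          FUN = length)
  gsize <- table(grouping)
  agg$fraction <- agg$count / as.numeric(gsize[agg$group])
  agg <- agg[order(agg$group, -agg$count), ]
  rownames(agg) <- NULL
  tier_counts <- table(factor(assign$tier, levels = c("major", "minor", "none")))
  tier <- data.frame(tier = names(tier_counts),
                     count = as.integer(tier_counts),
                     fraction = as.numeric(tier_counts) / n,
                     percent = as.integer(round(100 * as.numeric(tier_counts) / n)),
                     stringsAsFactors = FALSE)
  list(pat = agg, tier = tier)
}

#' Mean module expression per PAT
#'
#' Centroid vectors used, e.g., as the similarity space of the PAT flow
#' graph and as input to any external 2-D embedding of the PAT landscape.
#'
#' @param E cells x modules module-expression matrix (or activation
#'   levels).
#' @param assign \code{PATAssignment}.
#' @param include_none include the "none" class (default FALSE).
#' @return matrix, PAT labels x modules.
#' @export
pat_centroids <- function(E, assign, include_none = FALSE) {
  stopifnot(inherits(assign, "PATAssignment"))
  E <- as.matrix(E)
  labs <- unique(assign$label)
  if (!include_none) labs <- setdiff(labs, "none")
  out <- matrix(NA_real_, length(labs), ncol(E),
                dimnames = list(labs, colnames(E)))
  for (l in labs)
    out[l, ] <- colMeans(E[assign$label == l, , drop = FALSE])
  out
}
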