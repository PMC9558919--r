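#' Construct a marker panel
#'
#' An ordered list of rules, each assigning a population name to cells that
#' are positive for all \code{positive} genes and non-positive for all
#' \code{negative} genes. A cell is positive for a gene iff its value is
#' greater than zero (presence/absence; no expression cutoff).
#'
#' @param rules list of lists with fields \code{population},
#'   \code{positive} (character) and optional \code{negative} (character).
#' @return A \code{MarkerPanel} object.
#' @export
marker_panel <- function(rules) {
  pops <- vapply(rules, function(r) r$population, character(1))
  if (anyDuplicated(pops)) stop("population names in a panel must be unique")
  rules <- lapply(rules, function(r) {
    r$negative <- if (is.null(r$negative)) character() else r$negative
    r
  })
  structure(list(rules = rules), class = "MarkerPanel")
}

#' Read a marker panel from TSV
#'
#' Columns: \code{population}, \code{positive}, \code{negative}; gene lists
#' comma-separated, \code{negative} may be empty.
#'
#' @param path TSV file with header.
#' @return A \code{MarkerPanel}.
#' @export
read_marker_panel <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = NULL)
  split_genes <- function(s)
    if (!nzchar(s)) character() else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  rules <- lapply(seq_len(nrow(tab)), function(i)
    list(population = tab$population[i],
         positive = split_genes(tab$positive[i]),
         negative = if (is.null(tab$negative)) character()
                    else split_genes(tab$negative[i])))
  marker_panel(rules)
}

#' Assign cell populations from a marker panel
#'
#' A cell matches a rule iff all required positive genes have value > 0 and
#' all required negative genes have value 0 (or below). Cells matching no
#' rule are "unassigned"; cells matching several take the first matching
#' rule in panel order and are flagged non-mono-functional. Rules whose
#' positive markers are absent from the matrix are skipped with a warning.
#'
#' @param X \code{ExpressionMatrix} (counts or normalized).
#' @param panel \code{MarkerPanel}.
#' @param car_gene optional gene identifier of a chimeric-antigen-receptor
#'   construct marker; when given, cells with any signal for it are flagged
#'   CAR-positive.
#' @return data.frame with columns \code{cell_id}, \code{population},
#'   \code{mono_functional} and, when \code{car_gene} is set,
#'   \code{car_positive}.
#' @export
assign_populations <- function(X, panel, car_gene = NULL) {
  stopifnot(inherits(X, "ExpressionMatrix"), inherits(panel, "MarkerPanel"))
  n <- length(X$cell_ids)
  positive <- function(g) as.vector(X$values[g, ] > 0)
  match_mat <- matrix(FALSE, n, 0)
  kept <- character()
  for (r in panel$rules) {
    missing <- setdiff(c(r$positive, r$negative), X$gene_ids)
    if (length(missing)) {
      warning("rule '", r$population, "' skipped; missing marker gene(s): ",
              paste(missing, collapse = ", "))
      next
    }
    ok <- rep(TRUE, n)
    for (g in r$positive) ok <- ok & positive(g)
    for (g in r$negative) ok <- ok & !positive(g)
    match_mat <- cbind(match_mat, ok)
    kept <- c(kept, r$population)
  }
  n_match <- if (ncol(match_mat)) rowSums(match_mat) else rep(0, n)
  first <- if (ncol(match_mat)) apply(match_mat, 1, function(z) which(z)[1])
           else rep(NA_integer_, n)
  population <- ifelse(n_match >= 1, kept[first], "unassigned")
  out <- data.frame(cell_id = X$cell_ids,
                    population = population,
                    mono_functional = n_match == 1,
                    stringsAsFactors = FALSE)
  if (!is.null(car_gene)) {
    if (!car_gene %in% X$gene_ids)
      warning("CAR marker gene '", car_gene, "' absent from matrix; ",
              "car_positive set to NA")
    out$car_positive <- if (car_gene %in% X$gene_ids)
      positive(car_gene) else NA
  }
  out
}

#' Score cell-cycle phase per cell
#'
#' For each signature (S and G2M), the per-cell score is the mean expression
#' of the signature genes minus the mean expression of expression-matched
#' control genes: all genes are binned by their dataset-average expression
#' into \code{n_bins} equal-frequency bins and \code{n_ctrl} control genes
#' are sampled (with the given seed) from the bin of each signature gene.
#' Phase is S if the S score is largest and positive, G2M if the G2M score
#' is at least the S score and positive, else G1 (the signatures do not
#' separate G0 from G1, so non-cycling cells default to G1).
#'
#' @param X normalized \code{ExpressionMatrix}.
#' @param s_genes,g2m_genes signature gene identifiers; each must intersect
#'   the matrix genes.
#' @param n_bins expression bins for control matching (default 25).
#' @param n_ctrl control genes sampled per signature gene (default 100).
#' @param seed integer seed for control sampling.
#' @return data.frame with columns \code{cell_id}, \code{s_score},
#'   \code{g2m_score}, \code{phase} (factor G1/G2M/S).
#' @export
score_cell_cycle <- function(X, s_genes, g2m_genes, n_bins = 25,
                             n_ctrl = 100, seed = 1) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  s_genes <- intersect(s_genes, X$gene_ids)
  g2m_genes <- intersect(g2m_genes, X$gene_ids)
  if (!length(s_genes)) stop("S signature has no gene in the matrix")
  if (!length(g2m_genes)) stop("G2M signature has no gene in the matrix")
  ## order-invariant: work in the matrix's own gene order
  s_genes <- X$gene_ids[sort(match(s_genes, X$gene_ids))]
  g2m_genes <- X$gene_ids[sort(match(g2m_genes, X$gene_ids))]

  avg <- Matrix::rowMeans(X$values)
  names(avg) <- X$gene_ids
  ## control pool excludes both signatures so that scores are referenced
  ## to genes without cell-cycle structure; matching uses an
  ## expression-centered window over the eligible genes (window width set
  ## by n_bins: roughly one bin's worth of genes, at least n_ctrl)
  eligible <- setdiff(X$gene_ids, c(s_genes, g2m_genes))
  if (!length(eligible)) stop("no control-eligible genes in the matrix")
  elig_sorted <- eligible[order(avg[eligible])]
  window <- max(n_ctrl, ceiling(length(eligible) / n_bins))

  score_one <- function(sig, seed_offset) {
    set.seed(as.integer(seed) + seed_offset)
    ctrl <- unique(unlist(lapply(sig, function(g) {
      pos <- findInterval(avg[g], avg[elig_sorted])
      lo <- max(1, min(pos - ceiling(window / 2),
                       length(elig_sorted) - window + 1))
      pool <- elig_sorted[lo:min(length(elig_sorted), lo + window - 1)]
      if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
    })))
    sig_mean <- Matrix::colMeans(X$values[sig, , drop = FALSE])
    ctrl_mean <- if (length(ctrl))
      Matrix::colMeans(X$values[ctrl, , drop = FALSE]) else 0
    sig_mean - ctrl_mean
  }
  s_score <- score_one(s_genes, 0L)
  g2m_score <- score_one(g2m_genes, 1L)
  phase <- ifelse(g2m_score >= s_score & g2m_score > 0, "G2M",
           ifelse(s_score > g2m_score & s_score > 0, "S", "G1"))
  data.frame(cell_id = X$cell_ids,
             s_score = as.numeric(s_score),
             g2m_score = as.numeric(g2m_score),
             phase = factor(phase, levels = c("G1", "G2M", "S")),
             stringsAsFactors = FALSE)
}
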