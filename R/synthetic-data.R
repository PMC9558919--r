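#' Simulate a multi-sample single-cell counts matrix with planted structure
#'
#' Draws negative-binomial counts with log-normally distributed gene baseline
#' means, plants disjoint co-expression modules whose genes are multiplied by
#' \code{effect_size} in cells of the populations that activate them, marks a
#' designated "cycling" module active in a fixed fraction of cells of every
#' population (producing a bimodal per-cell module-expression distribution),
#' and splits samples into two groups A/B where group B has the frequency of
#' one designated population reduced by \code{group_freq_shift}. The returned
#' truth object records every planted assignment, so each downstream stage
#' can be validated without external data.
#'
#' @param n_genes,n_cells,n_samples problem size. Samples are assigned to
#'   cells round-robin within groups.
#' @param n_modules number of planted modules; the last one is the cycling
#'   module.
#' @param module_size genes per module (disjoint;
#'   \code{n_modules * module_size <= n_genes}).
#' @param populations list of lists with fields \code{name}, \code{fraction}
#'   and \code{modules} (integer indices of activated non-cycling modules).
#'   Fractions must sum to 1. Default: four populations with fractions
#'   0.4/0.3/0.2/0.1 activating modules 1..4 respectively.
#' @param effect_size fold-change applied to a module's genes in cells that
#'   activate it; 1 plants no signal.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param cycling_fraction fraction of cells of every population flagged
#'   cycling (the cycling module is active only in those).
#' @param group_freq_shift in [0, 1]: group B's frequency of the designated
#'   population (\code{shift_population}) is \code{(1 - group_freq_shift)}
#'   times its group A frequency, remaining populations renormalized.
#' @param shift_population index of the population whose frequency differs
#'   between groups.
#' @param mean_log,sd_log log-normal parameters of background gene baseline
#'   means; the heavy tail (sd_log 1.5) reproduces the wide expression
#'   range of real transcriptomes, so that highly expressed signature
#'   genes have expression-matched control peers.
#' @param module_base_mu per-module baseline mean counts (recycled to
#'   \code{n_modules}); member genes draw their baseline log-normally
#'   around the module's level with spread \code{module_sd_log}. The
#'   default (ladder 1, 0.7, 0.5, 0.35 over the population modules, 4 for
#'   the cycling module) makes the modules differ in absolute expression
#'   level, with the cycling module by far the strongest, mirroring real
#'   transcriptomes where proliferation machinery is highly expressed
#'   while subpopulation programs sit at distinct moderate levels.
#' @param module_sd_log log-normal spread of member-gene baselines around
#'   their module's level; kept narrow because the genes of a
#'   transcriptional program are coherently, detectably expressed
#'   (membership of a gene with near-zero baseline is not a recoverable
#'   planted fact).
#' @param seed integer seed; output is bit-identical for equal seeds.
#'
#' @return list with \code{matrix} (counts \code{ExpressionMatrix} whose
#'   cell_meta carries \code{sample_id} and \code{group}) and \code{truth}
#'   (class \code{PlantedTruth}): \code{module_genes}, \code{population_of_cell},
#'   \code{active_modules_of_population}, \code{cycling_flag} (values
#'   "resting"/"cycling"), \code{group_of_sample}, \code{cycling_module}.
#' @export
generate_dataset <- function(n_genes = 2000, n_cells = 5000, n_samples = 8,
                             n_modules = 5, module_size = 40,
                             populations = NULL,
                             effect_size = 4, dispersion = 0.1,
                             cycling_fraction = 0.4,
                             group_freq_shift = 0.5, shift_population = 1,
                             mean_log = log(0.5), sd_log = 1.5,
                             module_base_mu = NULL,
                             module_sd_log = 0.3,
                             seed = 1) {
  if (n_modules * module_size > n_genes)
    stop("n_modules * module_size must not exceed n_genes")
  if (is.null(populations))
    populations <- list(
      list(name = "P1", fraction = 0.4, modules = 1L),
      list(name = "P2", fraction = 0.3, modules = 2L),
      list(name = "P3", fraction = 0.2, modules = 3L),
      list(name = "P4", fraction = 0.1, modules = 4L))
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  pop_names <- vapply(populations, function(p) p$name, character(1))
  if (abs(sum(fr) - 1) > 1e-8)
    stop("population fractions must sum to 1 (got ", sum(fr), ")")
  if (any(fr <= 0)) stop("population fractions must be positive")
  if (anyDuplicated(pop_names)) stop("population names must be unique")
  max_mod <- max(c(0L, unlist(lapply(populations, function(p) p$modules))))
  if (max_mod > n_modules) stop("population activates unknown module index")

  set.seed(as.integer(seed))
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  cell_ids <- sprintf("cell%06d", seq_len(n_cells))
  module_names <- sprintf("M%d", seq_len(n_modules))
  module_genes <- split(gene_ids[seq_len(n_modules * module_size)],
                        rep(seq_len(n_modules), each = module_size))
  names(module_genes) <- module_names
  cycling_module <- module_names[n_modules]

  ## samples: half per group (group A gets the ceiling half)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  group_of_sample <- ifelse(seq_len(n_samples) <= ceiling(n_samples / 2),
                            "A", "B")
  names(group_of_sample) <- sample_ids

  ## group-specific population frequencies
  freq_A <- fr
  freq_B <- fr
  freq_B[shift_population] <- fr[shift_population] * (1 - group_freq_shift)
  rest <- setdiff(seq_along(fr), shift_population)
  freq_B[rest] <- freq_B[rest] * (1 - freq_B[shift_population]) / sum(fr[rest])
  freq_B <- freq_B / sum(freq_B)

  sample_of_cell <- sample(sample_ids, n_cells, replace = TRUE)
  grp <- group_of_sample[sample_of_cell]
  pop_of_cell <- character(n_cells)
  for (g in c("A", "B")) {
    idx <- which(grp == g)
    p <- if (g == "A") freq_A else freq_B
    pop_of_cell[idx] <- sample(pop_names, length(idx), replace = TRUE, prob = p)
  }
  cycling <- stats::rbinom(n_cells, 1, cycling_fraction) == 1

  ## baseline means and fold-change matrix
  base_mu <- stats::rlnorm(n_genes, meanlog = mean_log, sdlog = sd_log)
  active_sets <- lapply(populations, function(p) module_names[p$modules])
  names(active_sets) <- pop_names

  mod_of_gene <- rep(NA_character_, n_genes)
  for (m in module_names)
    mod_of_gene[match(module_genes[[m]], gene_ids)] <- m
  if (is.null(module_base_mu))
    module_base_mu <- c(rep_len(c(1, 0.7, 0.5, 0.35), max(0, n_modules - 1)), 4)
  module_base_mu <- rep_len(module_base_mu, n_modules)
  for (mi in seq_len(n_modules)) {
    gi <- match(module_genes[[mi]], gene_ids)
    base_mu[gi] <- stats::rlnorm(length(gi),
                                 meanlog = log(module_base_mu[mi]),
                                 sdlog = module_sd_log)
  }

  counts <- matrix(0L, n_genes, n_cells)
  size <- 1 / dispersion
  ## draw cell by cell so the fold-change per (gene, cell) is explicit
  for (j in seq_len(n_cells)) {
    fold <- rep(1, n_genes)
    act <- active_sets[[pop_of_cell[j]]]
    if (cycling[j]) act <- c(act, cycling_module)
    if (length(act)) {
      boosted <- mod_of_gene %in% act
      fold[boosted] <- effect_size
    }
    counts[, j] <- stats::rnbinom(n_genes, mu = base_mu * fold, size = size)
  }
  dimnames(counts) <- list(gene_ids, cell_ids)

  meta <- data.frame(cell_id = cell_ids, sample_id = sample_of_cell,
                     group = unname(grp), stringsAsFactors = FALSE)
  X <- expression_matrix(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                     "CsparseMatrix"),
                         gene_ids, cell_ids, meta, layer_tag = "counts")
  truth <- structure(list(
    module_genes = module_genes,
    population_of_cell = stats::setNames(pop_of_cell, cell_ids),
    active_modules_of_population = active_sets,
    cycling_flag = stats::setNames(ifelse(cycling, "cycling", "resting"),
                                   cell_ids),
    group_of_sample = group_of_sample,
    cycling_module = cycling_module,
    effect_size = effect_size), class = "PlantedTruth")
  list(matrix = X, truth = truth)
}

#' Marker panel derived from planted truth
#'
#' For each population, returns the planted genes usable as consensus
#' markers: genes of modules active in that population and in no other
#' (the cycling module, active everywhere, is never a marker).
#'
#' @param truth a \code{PlantedTruth}.
#' @param n_markers markers per population (first genes of the qualifying
#'   modules).
#' @return data.frame with columns \code{population} and \code{gene}.
#' @export
planted_marker_panel <- function(truth, n_markers = 10) {
  stopifnot(inherits(truth, "PlantedTruth"))
  pops <- names(truth$active_modules_of_population)
  rows <- lapply(pops, function(p) {
    own <- truth$active_modules_of_population[[p]]
    others <- unique(unlist(truth$active_modules_of_population[setdiff(pops, p)]))
    uniq <- setdiff(own, c(others, truth$cycling_module))
    genes <- utils::head(unlist(truth$module_genes[uniq], use.names = FALSE),
                         n_markers)
    if (!length(genes)) return(NULL)
    data.frame(population = p, gene = genes, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Marker panel object from planted truth
#'
#' Builds a \code{MarkerPanel} whose rules require presence of a
#' population's own markers and absence of the other populations' markers,
#' the way consensus panels pair positive with exclusion markers. Cells
#' failing either requirement stay unassigned, trading coverage for
#' precision.
#'
#' @param truth a \code{PlantedTruth}.
#' @param n_markers positive markers per population.
#' @param n_negative exclusion markers taken from each other population.
#' @return A \code{MarkerPanel}.
#' @export
planted_panel <- function(truth, n_markers = 2, n_negative = 2) {
  pm <- planted_marker_panel(truth, n_markers = n_markers)
  pops <- unique(pm$population)
  marker_panel(lapply(pops, function(p) {
    neg <- unlist(lapply(setdiff(pops, p), function(q)
      utils::head(pm$gene[pm$population == q], n_negative)))
    list(population = p,
         positive = pm$gene[pm$population == p],
         negative = neg)
  }))
}

#' Write a generated dataset to disk in the formats the package reads
#'
#' Counts go to Matrix Market + gene/barcode lists + metadata TSV; the
#' planted truth is serialized as JSON.
#'
#' @param dataset result of \code{\link{generate_dataset}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_market(dataset$matrix,
                      file.path(dir, "matrix.mtx"),
                      file.path(dir, "genes.tsv"),
                      file.path(dir, "barcodes.tsv"),
                      file.path(dir, "cell_meta.tsv"))
  truth <- dataset$truth
  truth$population_of_cell <- as.list(truth$population_of_cell)
  truth$cycling_flag <- as.list(truth$cycling_flag)
  truth$group_of_sample <- as.list(truth$group_of_sample)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
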