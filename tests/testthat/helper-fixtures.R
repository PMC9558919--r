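# Shared fixtures and small independent oracles used across the suite.

# tiny counts matrix with named genes/cells and sample metadata
tiny_counts <- function(values, samples = NULL) {
  g <- sprintf("g%d", seq_len(nrow(values)))
  cells <- sprintf("c%d", seq_len(ncol(values)))
  meta <- data.frame(cell_id = cells,
                     sample_id = samples %||% rep("S1", length(cells)),
                     stringsAsFactors = FALSE)
  expression_matrix(values, g, cells, meta, layer_tag = "counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index, direct contingency-table formula
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# right-tail hypergeometric probability by explicit summation:
# P(X >= q) for q successes when drawing k from m successes / n failures
hyper_tail <- function(q, m, n, k) {
  xs <- q:min(m, k)
  sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
}

# small trained SOM on two archetype profiles, used by spot/upscale tests
toy_archetype_som <- function(n_per = 30, n_bg = 60, m = 12, seed = 42) {
  set.seed(seed)
  arch1 <- c(rep(2, m / 2), rep(0, m / 2))
  arch2 <- rev(arch1)
  prof <- rbind(
    t(replicate(n_per, arch1 + rnorm(m, sd = 0.1))),
    t(replicate(n_per, arch2 + rnorm(m, sd = 0.1))),
    matrix(rnorm(n_bg * m, sd = 0.1), n_bg, m))
  rownames(prof) <- sprintf("g%03d", seq_len(nrow(prof)))
  prof <- prof - rowMeans(prof)
  list(profiles = prof,
       labels = rep(c("A1", "A2", "bg"), c(n_per, n_per, n_bg)),
       model = train_som(prof, rows = 8, cols = 8, epochs = 25, seed = seed))
}

# hand-built SOMModel on a small grid: `blocks` is a list of lists with
# fields rows, cols (0-based ranges) and profile (length m); genes are laid
# onto the block units round-robin
manual_som <- function(rows, cols, m, blocks, genes_per_unit = 1) {
  n_units <- rows * cols
  weights <- matrix(0, n_units, m)
  gene_to_unit <- integer(0)
  for (b in blocks) {
    units <- as.vector(outer(b$rows, b$cols,
                             function(r, cc) r * cols + cc + 1))
    for (u in units) weights[u, ] <- b$profile
    gene_to_unit <- c(gene_to_unit, rep(units, genes_per_unit))
  }
  names(gene_to_unit) <- sprintf("gene%03d", seq_along(gene_to_unit))
  structure(list(grid_rows = rows, grid_cols = cols, weights = weights,
                 gene_to_unit = gene_to_unit, training_log = numeric(),
                 grid = cbind(row = (seq_len(n_units) - 1) %/% cols,
                              col = (seq_len(n_units) - 1) %% cols)),
            class = "SOMModel")
}

# run generation -> normalization -> meta-cells -> SOM -> spots at the
# scaled-down study configuration; memoised per seed within a test run
study_pipeline_upto_som <- local({
  cache <- list()
  function(seed) {
    key <- as.character(seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ds <- generate_dataset(seed = seed)
    Xn <- normalize_cells(ds$matrix)
    lab <- base_cluster(Xn, k = 16, seed = seed)
    M <- build_metacells(Xn, lab, cells_per_metacell = 100, seed = seed)
    som <- train_som(prepare_gene_profiles(M), rows = 20, cols = 20,
                     epochs = 60, sigma_end = 0.3, seed = seed)
    res <- list(ds = ds, Xn = Xn, M = M, som = som,
                map = extract_spots(som))
    cache[[key]] <<- res
    res
  }
})

# gene-level Jaccard of each planted module against its best-matching
# recovered module
planted_jaccard <- function(truth, map) {
  mg <- module_genes(map)
  vapply(truth$module_genes, function(tg)
    max(0, vapply(mg, function(rg)
      length(intersect(tg, rg)) / length(union(tg, rg)), numeric(1))),
    numeric(1))
}
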