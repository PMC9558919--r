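# small trained SOM plus its MetaCellSet for transfer-learning tests
upscale_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- generate_dataset(n_genes = 300, n_cells = 800, n_samples = 2,
                            n_modules = 3, module_size = 20,
                            populations = list(
                              list(name = "P1", fraction = 0.5, modules = 1L),
                              list(name = "P2", fraction = 0.5, modules = 2L)),
                            seed = 31)
    Xn <- normalize_cells(sim$matrix)
    lab <- base_cluster(Xn, k = 4, seed = 1)
    M <- build_metacells(Xn, lab, cells_per_metacell = 40, seed = 1)
    som <- train_som(prepare_gene_profiles(M), rows = 8, cols = 8,
                     epochs = 30, sigma_end = 0.3, seed = 1)
    cache <<- list(sim = sim, Xn = Xn, M = M, som = som,
                   up = fit_upscaler(som, M))
    cache
  }
})

metacell_matrix <- function(M)
  expression_matrix(t(M$centroids), colnames(M$centroids),
                    rownames(M$centroids), layer_tag = "normalized")

test_that("single-gene units pass their centered profile through", {
  fx <- upscale_fixture()
  singles <- which(vapply(seq_len(64), function(u)
    sum(fx$som$gene_to_unit == u) == 1, logical(1)))
  skip_if(length(singles) == 0, "fixture produced no single-gene unit")
  u <- singles[1]
  g <- names(fx$som$gene_to_unit)[fx$som$gene_to_unit == u]
  pred <- predict_metagenes(fx$up, metacell_matrix(fx$M))
  centered <- fx$M$centroids[, g] - mean(fx$M$centroids[, g])
  expect_equal(unname(pred[, u]), unname(centered), tolerance = 1e-10)
})

test_that("training meta-cells reproduce the stored meta-gene values", {
  fx <- upscale_fixture()
  pred <- predict_metagenes(fx$up, metacell_matrix(fx$M))
  nonempty <- which(vapply(seq_len(64), function(u)
    sum(fx$som$gene_to_unit == u) > 0, logical(1)))
  cors <- vapply(nonempty, function(u)
    suppressWarnings(cor(pred[, u], fx$som$weights[u, ])), numeric(1))
  expect_true(all(cors >= 0.95, na.rm = TRUE))
})

test_that("empty units inherit the nearest non-empty predictor", {
  fx <- upscale_fixture()
  empty <- which(vapply(seq_len(64), function(u)
    sum(fx$som$gene_to_unit == u) == 0, logical(1)))
  skip_if(length(empty) == 0, "fixture produced no empty unit")
  nonempty <- setdiff(seq_len(64), empty)
  for (u in empty[1:min(5, length(empty))]) {
    src <- fx$up$source_unit[u]
    expect_true(src %in% nonempty)
    d2 <- rowSums((fx$som$grid[nonempty, , drop = FALSE] -
                   matrix(fx$som$grid[u, ], length(nonempty), 2,
                          byrow = TRUE))^2)
    best <- min(d2)
    candidates <- nonempty[d2 <= best + 1e-12]
    expect_identical(src, candidates[1])    # tie -> lower unit index
  }
})

test_that("a SOM/meta-cell mismatch is a contract error", {
  fx <- upscale_fixture()
  M2 <- fx$M
  M2$centroids <- M2$centroids[-1, , drop = FALSE]
  expect_error(fit_upscaler(fx$som, M2), "meta-cells")
})

test_that("cell-level predictions average back to the meta-gene vectors", {
  fx <- upscale_fixture()
  P <- predict_metagenes(fx$up, fx$Xn)
  agg <- rowsum(P, fx$M$assignment[fx$Xn$cell_ids])
  agg <- agg / as.vector(table(fx$M$assignment[fx$Xn$cell_ids]))
  target <- t(fx$som$weights[, as.integer(rownames(agg)), drop = FALSE])
  expect_lt(mean(abs(agg - target)), 0.25 * stats::sd(fx$som$weights))
})

test_that("prediction is deterministic and tolerates missing genes", {
  fx <- upscale_fixture()
  X <- metacell_matrix(fx$M)
  expect_identical(predict_metagenes(fx$up, X), predict_metagenes(fx$up, X))
  # drop one member gene: warning, still finite output
  keep <- setdiff(X$gene_ids, names(fx$som$gene_to_unit)[1])
  Xd <- expression_matrix(X$values[keep, , drop = FALSE], keep, X$cell_ids,
                          layer_tag = "normalized")
  expect_warning(pred <- predict_metagenes(fx$up, Xd), "absent")
  expect_true(all(is.finite(pred)))
})

test_that("population mean portraits rank planted units at the top", {
  fx <- upscale_fixture()
  P <- predict_metagenes(fx$up, fx$Xn)
  tr <- fx$sim$truth
  p1_cells <- names(tr$population_of_cell)[tr$population_of_cell == "P1"]
  mean_pred <- colMeans(P[p1_cells, , drop = FALSE])
  units_m1 <- unique(fx$som$gene_to_unit[tr$module_genes$M1])
  top_decile <- order(mean_pred, decreasing = TRUE)[1:ceiling(64 / 10)]
  expect_gte(length(intersect(units_m1, top_decile)) / length(units_m1), 0.5)
})

test_that("the least-squares variant honours the same contract", {
  fx <- upscale_fixture()
  up_lm <- fit_upscaler(fx$som, fx$M, method = "lm")
  pred <- predict_metagenes(up_lm, metacell_matrix(fx$M))
  nonempty <- which(vapply(seq_len(64), function(u)
    sum(fx$som$gene_to_unit == u) > 0, logical(1)))
  cors <- vapply(nonempty, function(u)
    suppressWarnings(cor(pred[, u], fx$som$weights[u, ])), numeric(1))
  expect_true(all(cors >= 0.95, na.rm = TRUE))
})
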