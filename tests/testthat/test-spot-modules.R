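# model with two well-separated high blocks and the portraits activating them
two_block_fixture <- function() {
  m <- 4
  model <- manual_som(8, 8, m, list(
    list(rows = 0:1, cols = 0:1, profile = c(2, 0, 0, 0)),
    list(rows = 6:7, cols = 6:7, profile = c(0, 2, 0, 0))),
    genes_per_unit = 2)
  p1 <- portrait_of(model, model$weights[, 1])
  p2 <- portrait_of(model, model$weights[, 2])
  list(model = model, p1 = p1, p2 = p2)
}

test_that("a single high block becomes exactly one module", {
  fx <- two_block_fixture()
  map <- extract_spots(fx$model, list(fx$p1), min_units = 3)
  expect_length(map$modules, 1)
  expect_setequal(map$modules[[1]]$units, c(1, 2, 9, 10))
  expect_identical(map$modules[[1]]$label, "A")
})

test_that("disjoint high corners from two portraits give two modules", {
  fx <- two_block_fixture()
  map <- extract_spots(fx$model, list(fx$p1, fx$p2), min_units = 3)
  expect_length(map$modules, 2)
  # top-left block gets the earlier letter
  expect_identical(map$modules[[1]]$label, "A")
  expect_setequal(map$modules[[1]]$units, c(1, 2, 9, 10))
  expect_setequal(map$modules[[2]]$units, c(55, 56, 63, 64))
  # module genes are the genes of the member units, disjointly
  mg <- module_genes(map)
  expect_length(intersect(mg$A, mg$B), 0)
  expect_equal(sum(lengths(mg)), 16)
})

test_that("portraits without positive values contribute nothing", {
  fx <- two_block_fixture()
  dark <- portrait_of(fx$model, rep(-1, 64))
  map <- extract_spots(fx$model, list(dark), min_units = 1)
  expect_length(map$modules, 0)
  map2 <- extract_spots(fx$model, list(fx$p1, dark), min_units = 3)
  expect_length(map2$modules, 1)
})

test_that("adjacent blocks with distinct profiles are split at the seam", {
  m <- 4
  model <- manual_som(8, 8, m, list(
    list(rows = 0:1, cols = 0:2, profile = c(2, 0, 0.2, 0)),
    list(rows = 0:1, cols = 3:5, profile = c(0, 2, 0.2, 0))),
    genes_per_unit = 2)
  p1 <- portrait_of(model, model$weights[, 1])
  p2 <- portrait_of(model, model$weights[, 2])
  map <- extract_spots(model, list(p1, p2), min_units = 3)
  expect_length(map$modules, 2)
  expect_setequal(map$modules[[1]]$units, c(1:3, 9:11))
  expect_setequal(map$modules[[2]]$units, c(4:6, 12:14))
})

test_that("raising the threshold never grows the selected area", {
  fx <- study_pipeline_upto_som(1)
  lo <- extract_spots(fx$som, threshold_fraction = 0.90)
  hi <- extract_spots(fx$som, threshold_fraction = 0.99)
  units_lo <- unlist(lapply(lo$modules, `[[`, "units"))
  units_hi <- unlist(lapply(hi$modules, `[[`, "units"))
  expect_lte(length(units_hi), length(units_lo))
  expect_true(all(units_hi %in% units_lo))
})

test_that("module unit sets are disjoint connected regions", {
  fx <- study_pipeline_upto_som(1)
  map <- fx$map
  units <- lapply(map$modules, `[[`, "units")
  expect_equal(sum(lengths(units)), length(unique(unlist(units))))
  # connectivity: each module is one 8-neighborhood component
  for (m in map$modules) {
    r <- (m$units - 1) %/% map$grid_cols
    cc <- (m$units - 1) %% map$grid_cols
    d <- as.matrix(dist(cbind(r, cc), method = "maximum"))
    reach <- (d <= 1)
    # transitive closure by repeated multiplication
    conn <- reach
    for (i in seq_len(length(m$units))) conn <- (conn %*% reach) > 0
    expect_true(all(conn))
  }
})

test_that("module letters follow centroid scan order and are idempotent", {
  fx <- two_block_fixture()
  map <- extract_spots(fx$model, list(fx$p1, fx$p2), min_units = 3)
  relabeled <- label_modules(map)
  expect_identical(vapply(relabeled$modules, `[[`, character(1), "label"),
                   vapply(map$modules, `[[`, character(1), "label"))
  expect_identical(scportray:::.letter_labels(28)[27:28], c("AA", "AB"))
})

test_that("module expression equals the brute-force gene means", {
  set.seed(8)
  X <- normalize_cells(tiny_counts(matrix(rpois(30 * 20, 3), 30, 20)))
  sets <- list(A = c("g1", "g5", "g9"), B = "g2", C = c("g3", "missing"))
  E <- suppressWarnings(module_expression(X, sets))
  for (j in seq_len(20)) {
    expect_equal(E[j, "A"], mean(X$values[c("g1", "g5", "g9"), j]))
    expect_equal(E[j, "B"], X$values["g2", j])     # 1-gene module
    expect_equal(E[j, "C"], X$values["g3", j])     # missing gene dropped
  }
  expect_warning(module_expression(X, list(D = "nothere")), "no gene")
  # all-zero cell gives a zero row
  X0 <- normalize_cells(tiny_counts(cbind(matrix(2, 5, 3), 0)))
  E0 <- module_expression(X0, list(A = c("g1", "g2")))
  expect_equal(unname(E0[4, ]), 0)
})

test_that("gene-set over-representation matches the hypergeometric tail", {
  model <- manual_som(4, 4, 2, list(
    list(rows = 0, cols = 0:1, profile = c(1, 0))), genes_per_unit = 1)
  # module holds gene001, gene002; universe of 4 genes
  map <- extract_spots(model, list(portrait_of(model, model$weights[, 1])),
                       min_units = 1)
  universe <- c("gene001", "gene002", "x1", "x2")
  res <- geneset_annotation(map, list(S1 = c("gene001", "gene002"),
                                      S2 = c("far1", "far2")),
                            universe)
  expect_equal(res$p_value[res$set == "S1"], 1 / 6, tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "S2"], 1)    # disjoint from universe
  expect_error(geneset_annotation(map, list(S = "gene001"), character()),
               "non-empty")
  expect_error(geneset_annotation(map, list(S = "gene001"), c("x1", "x2")),
               "every module gene")

  # randomized tables against the explicit tail-sum oracle
  set.seed(13)
  genes <- sprintf("u%02d", 1:40)
  model2 <- manual_som(4, 4, 2, list(
    list(rows = 0:1, cols = 0:2, profile = c(1, 0))), genes_per_unit = 2)
  map2 <- extract_spots(model2, list(portrait_of(model2,
                                                 model2$weights[, 1])),
                        min_units = 1)
  k <- length(module_genes(map2)[[1]])
  universe2 <- c(module_genes(map2)[[1]],
                 sprintf("bg%02d", seq_len(40 - k)))
  for (i in 1:20) {
    set_i <- sample(universe2, sample(3:15, 1))
    res_i <- geneset_annotation(map2, list(S = set_i), universe2)
    ov <- length(intersect(set_i, module_genes(map2)[[1]]))
    expect_equal(res_i$p_value,
                 hyper_tail(ov, length(set_i), 40 - length(set_i), k),
                 tolerance = 1e-12)
  }
})

test_that("module maps serialize to TSV", {
  fx <- two_block_fixture()
  map <- extract_spots(fx$model, list(fx$p1, fx$p2), min_units = 3)
  d <- withr::local_tempdir()
  write_module_map(map, file.path(d, "units.tsv"), file.path(d, "genes.tsv"))
  u <- utils::read.table(file.path(d, "units.tsv"), header = TRUE, sep = "\t")
  expect_setequal(u$unit[u$label == "A"], c(1, 2, 9, 10))
  g <- utils::read.table(file.path(d, "genes.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(g), 16)
})
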