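small_sim <- function(...) {
  generate_dataset(n_genes = 300, n_cells = 600, n_samples = 4,
                   n_modules = 3, module_size = 20,
                   populations = list(
                     list(name = "P1", fraction = 0.5, modules = 1L),
                     list(name = "P2", fraction = 0.5, modules = 2L)),
                   ...)
}

test_that("generation is bit-identical for equal seeds", {
  a <- small_sim(seed = 3)
  b <- small_sim(seed = 3)
  expect_identical(as.matrix(a$matrix$values), as.matrix(b$matrix$values))
  expect_identical(a$truth$population_of_cell, b$truth$population_of_cell)
  c <- small_sim(seed = 4)
  expect_false(identical(as.matrix(a$matrix$values),
                         as.matrix(c$matrix$values)))
})

test_that("planted modules raise expression in their active population", {
  sim <- small_sim(seed = 1)
  Xn <- normalize_cells(sim$matrix)
  tr <- sim$truth
  m1 <- tr$module_genes$M1
  in_p1 <- names(tr$population_of_cell)[tr$population_of_cell == "P1"]
  in_p2 <- names(tr$population_of_cell)[tr$population_of_cell == "P2"]
  mu_active <- mean(as.matrix(Xn$values[m1, in_p1]))
  mu_inactive <- mean(as.matrix(Xn$values[m1, in_p2]))
  expect_gt(mu_active, mu_inactive + 0.2)
})

test_that("effect size 1 plants no signal", {
  sim <- small_sim(seed = 5, effect_size = 1)
  Xn <- normalize_cells(sim$matrix)
  tr <- sim$truth
  m1 <- tr$module_genes$M1
  in_p1 <- names(tr$population_of_cell)[tr$population_of_cell == "P1"]
  in_p2 <- names(tr$population_of_cell)[tr$population_of_cell == "P2"]
  diff <- mean(as.matrix(Xn$values[m1, in_p1])) - mean(as.matrix(Xn$values[m1, in_p2]))
  expect_lt(abs(diff), 0.05)
})

test_that("zero group shift leaves population frequencies balanced", {
  sim <- generate_dataset(n_genes = 100, n_cells = 4000, n_samples = 4,
                          n_modules = 2, module_size = 10,
                          populations = list(
                            list(name = "P1", fraction = 0.5, modules = 1L),
                            list(name = "P2", fraction = 0.5, modules = integer())),
                          group_freq_shift = 0, seed = 2)
  tr <- sim$truth
  grp <- tr$group_of_sample[sim$matrix$cell_meta$sample_id]
  fA <- mean(tr$population_of_cell[grp == "A"] == "P1")
  fB <- mean(tr$population_of_cell[grp == "B"] == "P1")
  # within ~4 binomial standard errors of each other
  se <- sqrt(0.25 / sum(grp == "A") + 0.25 / sum(grp == "B"))
  expect_lt(abs(fA - fB), 4 * se)
})

test_that("a positive group shift depletes the designated population in B", {
  sim <- generate_dataset(seed = 6)         # defaults: shift 0.5 on P1
  tr <- sim$truth
  grp <- tr$group_of_sample[sim$matrix$cell_meta$sample_id]
  fA <- mean(tr$population_of_cell[grp == "A"] == "P1")
  fB <- mean(tr$population_of_cell[grp == "B"] == "P1")
  expect_gt(fA, fB * 1.5)
})

test_that("infeasible population fractions are rejected", {
  expect_error(generate_dataset(populations = list(
    list(name = "P1", fraction = 0.7, modules = 1L),
    list(name = "P2", fraction = 0.7, modules = 2L))), "sum to 1")
})

test_that("the planted cycling module is bimodal across cells", {
  sim <- small_sim(seed = 9)
  Xn <- normalize_cells(sim$matrix)
  tr <- sim$truth
  e <- Matrix::colMeans(Xn$values[tr$module_genes[[tr$cycling_module]], ])
  fl <- tr$cycling_flag[Xn$cell_ids]
  hi <- e[fl == "cycling"]; lo <- e[fl == "resting"]
  pooled <- sqrt(((length(hi) - 1) * var(hi) + (length(lo) - 1) * var(lo)) /
                 (length(hi) + length(lo) - 2))
  expect_gte((mean(hi) - mean(lo)) / pooled, 2)
})

test_that("planted markers classify cells back to their populations", {
  sim <- small_sim(seed = 4)
  pm <- planted_marker_panel(sim$truth, n_markers = 3)
  expect_setequal(unique(pm$population), c("P1", "P2"))
  # markers belong to modules active in their population
  for (p in unique(pm$population)) {
    active <- unlist(sim$truth$module_genes[
      sim$truth$active_modules_of_population[[p]]])
    expect_true(all(pm$gene[pm$population == p] %in% active))
  }
  panel <- planted_panel(sim$truth)
  ann <- assign_populations(sim$matrix, panel)
  truth_pop <- sim$truth$population_of_cell[ann$cell_id]
  assigned <- ann$population != "unassigned"
  expect_gt(mean(assigned), 0.1)   # panel assigns a usable share of cells
  agreement <- mean(ann$population[assigned] == truth_pop[assigned])
  expect_gte(agreement, 0.95)
})

test_that("a generated dataset survives a disk round trip", {
  sim <- generate_dataset(n_genes = 50, n_cells = 80, n_samples = 2,
                          n_modules = 2, module_size = 5,
                          populations = list(
                            list(name = "P1", fraction = 1, modules = 1L)),
                          seed = 8)
  d <- withr::local_tempdir()
  write_dataset(sim, d)
  X <- read_matrix_market(file.path(d, "matrix.mtx"),
                          file.path(d, "genes.tsv"),
                          file.path(d, "barcodes.tsv"),
                          cell_meta = read_cell_meta(file.path(d, "cell_meta.tsv")))
  expect_equal(as.matrix(X$values), as.matrix(sim$matrix$values))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_identical(unlist(truth$module_genes$M1),
                   sim$truth$module_genes$M1)
})
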