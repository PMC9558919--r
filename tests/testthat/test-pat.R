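constructed_levels <- function(mat, mods = LETTERS[seq_len(ncol(mat))]) {
  colnames(mat) <- mods
  rownames(mat) <- sprintf("c%d", seq_len(nrow(mat)))
  mat
}

test_that("threshold objects validate their invariants", {
  expect_error(activation_thresholds(minor_sigma = 1.5), "minor_sigma")
  expect_error(activation_thresholds(rare_fraction = 1), "rare_fraction")
  thr <- activation_thresholds()
  expect_equal(thr$major_sigma, 1.0)
  expect_equal(thr$minor_sigma, 0.5)
  expect_equal(thr$rare_fraction, 0.005)
})

test_that("activation levels are pooled-sigma standardized", {
  set.seed(1)
  E <- constructed_levels(matrix(rnorm(200 * 3, mean = c(5, 0, -5)), 200, 3,
                                 byrow = TRUE))
  lv <- call_activation(E)
  centered <- sweep(E, 2, colMeans(E))
  expect_equal(lv$sigma, sd(as.vector(centered)))
  expect_equal(lv$levels, centered / lv$sigma)
  # a constant matrix is degenerate
  expect_error(call_activation(constructed_levels(matrix(1, 10, 2))),
               "degenerate")
})

test_that("major and minor tiers follow the sigma thresholds", {
  # pre-standardized levels: bypass call_activation with sigma-unit values
  lv <- constructed_levels(rbind(
    c(1.2, 1.3, -0.5),    # both above 1 sigma -> major
    c(1.2, 0.7, -0.5),    # one in (0.5, 1] -> minor
    c(0.2, 0.1, 0.3),     # none above 0.5 -> none
    c(2.0, 0.0, 0.0)),    # single module major
    mods = c("B", "D", "X"))
  a <- assign_pats(lv, module_order = c("B", "D", "X"))
  expect_identical(a$tier, c("major", "minor", "none", "major"))
  expect_identical(a$label, c("B D", "b d", "none", "B"))
})

test_that("letters are ordered by overall activation frequency", {
  # J activates in 3 cells, B in 2 -> J precedes B
  lv <- constructed_levels(rbind(
    c(1.5, 1.5),
    c(0.0, 1.5),
    c(1.5, 1.5),
    c(0.0, 1.2)),
    mods = c("B", "J"))
  a <- assign_pats(lv)
  expect_identical(attr(a, "module_order"), c("J", "B"))
  expect_identical(a$label[1], "J B")
  # with an explicit frequency ranking, the label follows it
  a2 <- assign_pats(lv, module_order = c("B", "J"))
  expect_identical(a2$label[1], "B J")
})

test_that("brute-force reclassification reproduces assign_pats", {
  set.seed(5)
  E <- constructed_levels(matrix(rnorm(500 * 4), 500, 4))
  thr <- activation_thresholds()
  lv <- call_activation(E, thr)
  a <- assign_pats(lv, thr)
  mo <- attr(a, "module_order")
  centered <- sweep(E, 2, colMeans(E))
  sigma <- sd(as.vector(centered))
  for (i in sample(500, 60)) {
    z <- centered[i, ] / sigma
    act <- names(z)[z > 0.5]
    if (!length(act)) {
      expect_identical(a$label[i], "none")
    } else {
      letters_i <- mo[mo %in% act]
      if (all(z[act] > 1)) expect_identical(a$label[i],
                                            paste(letters_i, collapse = " "))
      else expect_identical(a$label[i],
                            paste(tolower(letters_i), collapse = " "))
    }
  }
})

test_that("raising the minor threshold only shrinks activated sets", {
  set.seed(6)
  E <- constructed_levels(matrix(rnorm(300 * 3), 300, 3))
  lv <- call_activation(E)
  a_low <- assign_pats(lv, activation_thresholds(minor_sigma = 0.5))
  a_high <- assign_pats(lv, activation_thresholds(minor_sigma = 0.8))
  act_low <- attr(a_low, "activated")
  act_high <- attr(a_high, "activated")
  expect_true(all(act_high <= act_low))
})

test_that("rare-PAT rejection uses the strict fraction rule", {
  # 1000 cells; a 4-cell label is dissolved at 0.5% (4 < 5), 5-cell survives
  lab <- c(rep("A", 600), rep("B", 391), rep("C", 4), rep("D", 5))
  a <- structure(data.frame(cell_id = sprintf("c%d", 1:1000), label = lab,
                            tier = ifelse(lab == "none", "none", "major"),
                            stringsAsFactors = FALSE),
                 class = c("PATAssignment", "data.frame"))
  r <- reject_rare(a, 0.005)
  expect_identical(attr(r, "rejected"), "C")
  expect_equal(sum(r$label == "none"), 4)
  expect_equal(sum(r$label == "D"), 5)
  expect_identical(reject_rare(a, 0)$label, a$label)   # 0 -> identity
  # partition is preserved
  expect_equal(sum(table(r$tier)), 1000)
})

test_that("the printed-scale rejection cutoff arithmetic holds", {
  expect_identical(rare_cutoff(133405, 0.005), 667L)
  expect_identical(rare_cutoff(1000, 0.005), 4L)
})

test_that("frequency tables tally exactly and report tier percentages", {
  set.seed(9)
  lab <- sample(c("A", "b", "none"), 400, TRUE, prob = c(0.4, 0.4, 0.2))
  tier <- ifelse(lab == "A", "major", ifelse(lab == "b", "minor", "none"))
  a <- structure(data.frame(cell_id = sprintf("c%d", 1:400), label = lab,
                            tier = tier, stringsAsFactors = FALSE),
                 class = c("PATAssignment", "data.frame"))
  grp <- sample(c("g1", "g2"), 400, TRUE)
  ft <- pat_frequency_table(a, grp)
  # brute-force tally
  for (i in seq_len(nrow(ft$pat))) {
    row <- ft$pat[i, ]
    expect_equal(row$count, sum(lab == row$label & grp == row$group))
    expect_equal(row$fraction, row$count / sum(grp == row$group))
  }
  # single group: fractions sum to 1
  ft1 <- pat_frequency_table(a)
  expect_equal(sum(ft1$pat$fraction), 1)
  expect_equal(sum(ft1$tier$count), 400)
})
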