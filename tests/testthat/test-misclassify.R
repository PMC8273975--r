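test_that("empirical EHR matrices reproduce the published row percentages", {
  m <- ehr_misclass_matrices()
  # overall EHR-White row percentages: 94.4, 0.7, 0.0, 4.2, 0.7
  expect_equal(unname(m$overall$P[1, ]), c(0.944, 0.007, 0.0, 0.042, 0.007),
               tolerance = 1e-3)
  # stratified, low-trust EHR-Hispanic diagonal: 60.7%
  expect_equal(unname(m$stratified$P_by_y[["0"]][5, 5]), 0.607, tolerance = 1e-3)
  # the high-trust EHR-Hispanic diagonal differs (49.2%): differential
  expect_equal(unname(m$stratified$P_by_y[["1"]][5, 5]), 0.492, tolerance = 1e-3)
  for (M in list(m$overall$P, m$stratified$P_by_y[["0"]],
                 m$stratified$P_by_y[["1"]]))
    expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
  expect_identical(m$overall$direction, "inverse")
  expect_identical(m$stratified$mode, "differential")
})

test_that("constructors enforce row-stochasticity and shape", {
  expect_error(misclass_matrix(matrix(1, 2, 3)), "square")
  expect_error(misclass_matrix(matrix(c(0.5, 0.5, 0.4, 0.7), 2, 2)), "sum to 1")
  expect_error(misclass_matrix(matrix(c(1.5, -0.5, 0, 1), 2, 2, byrow = TRUE)),
               "\\[0, 1\\]")
  expect_error(misclass_matrix(P_by_y = list(diag(2))), "exactly two")
  expect_silent(misclass_matrix(diag(5)))
})

test_that("degree matrices allocate off-diagonal mass as documented", {
  expect_equal(degree_matrix(0, 5)$P, diag(5))
  m <- degree_matrix(0.5, 5, "uniform")
  expect_equal(unname(diag(m$P)), rep(0.5, 5))
  expect_equal(unname(m$P[1, -1]), rep(0.125, 4))
  tp <- degree_matrix(0.3, 5, "table_proportional")
  expect_equal(unname(diag(tp$P)), rep(0.7, 5))
  expect_equal(unname(rowSums(tp$P)), rep(1, 5))
  expect_error(degree_matrix(1.2, 5), "\\[0, 1\\]")
  # the realized misclassification fraction tracks the degree
  pop <- generate_population(pop_config(N = 50000), seed = 8)
  pop2 <- apply_misclassification(pop, degree_matrix(0.2, 5), seed = 9)
  frac <- mean(pop2$X_star != pop2$X)
  expect_lt(abs(frac - 0.2), 4 * sqrt(0.2 * 0.8 / 50000))
})

test_that("applying a generator changes only the recorded label", {
  pop <- generate_population(small_config(), seed = 10)
  ident <- misclass_matrix(diag(5), direction = "generator")
  expect_identical(apply_misclassification(pop, ident, seed = 1)$X_star, pop$X)
  G <- as_generator(ehr_misclass_matrices()$overall)
  pop2 <- apply_misclassification(pop, G, seed = 2)
  expect_identical(pop2$X, pop$X)
  expect_identical(pop2$Y, pop$Y)
  expect_identical(pop2$low_income, pop$low_income)
  expect_false(identical(pop2$X_star, pop$X))
})

test_that("inverse-direction matrices are refused with guidance", {
  pop <- generate_population(small_config(), seed = 11)
  m <- ehr_misclass_matrices()$overall
  expect_error(apply_misclassification(pop, m), "invert_direction")
})

test_that("the recorded-category distribution is the matrix image of the truth", {
  # empirical X* distribution ~= t(G) %*% p for a generator G
  cfg <- pop_config(N = 200000)
  pop <- generate_population(cfg, seed = 12)
  G <- as_generator(ehr_misclass_matrices()$overall)
  pop <- apply_misclassification(pop, G, seed = 13)
  expected <- drop(crossprod(G$P, cfg$race_probs))
  observed <- tabulate(pop$X_star, 5) / nrow(pop)
  expect_true(all(abs(observed - expected) <
                    4 * sqrt(expected * (1 - expected) / nrow(pop)) + 1e-4))
})

test_that("non-differential application is conditionally independent of the outcome", {
  cfg <- pop_config(N = 300000)
  pop <- generate_population(cfg, seed = 14)
  G <- as_generator(ehr_misclass_matrices()$overall)
  pop <- apply_misclassification(pop, G, seed = 15)
  # compare Pr(X* = j | X = 1, Y) between outcome arms (largest cell)
  for (j in c(1, 4)) {
    p1 <- mean(pop$X_star[pop$X == 1 & pop$Y == 1] == j)
    p0 <- mean(pop$X_star[pop$X == 1 & pop$Y == 0] == j)
    n <- min(sum(pop$X == 1 & pop$Y == 1), sum(pop$X == 1 & pop$Y == 0))
    expect_lt(abs(p1 - p0), 5 * sqrt(0.25 / n) + 2e-3)
  }
})

test_that("differential application is detectably outcome-dependent", {
  cfg <- pop_config(N = 100000)
  pop <- generate_population(cfg, seed = 16)
  G <- as_generator(ehr_misclass_matrices()$stratified, "direct")
  pop <- apply_misclassification(pop, G, seed = 17)
  # direct reading: Pr(X* = Hispanic | X = Hispanic, Y) is 0.607 vs 0.492
  p0 <- mean(pop$X_star[pop$X == 5 & pop$Y == 0] == 5)
  p1 <- mean(pop$X_star[pop$X == 5 & pop$Y == 1] == 5)
  expect_gt(p0 - p1, 0.05)
})

test_that("direction inversion matches the explicit joint-table construction", {
  ident <- misclass_matrix(diag(3), direction = "inverse",
                           labels = paste0("c", 1:3))
  expect_equal(invert_direction(ident, c(0.2, 0.3, 0.5))$P, diag(3))
  sym <- misclass_matrix(matrix(c(0.8, 0.2, 0.2, 0.8), 2), direction = "inverse",
                         labels = c("a", "b"))
  expect_equal(invert_direction(sym, c(0.5, 0.5))$P,
               matrix(c(0.8, 0.2, 0.2, 0.8), 2))
  # rows (0.9, 0.1 / 0.2, 0.8) with row-variable marginal (0.75, 0.25):
  # joint is ((0.675, 0.075), (0.05, 0.2)); renormalizing its columns and
  # transposing gives the frozen values below
  m <- misclass_matrix(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                       direction = "inverse", labels = c("a", "b"))
  inv <- invert_direction(m, c(0.75, 0.25))
  expect_equal(inv$P,
               matrix(c(0.9310345, 0.0689655, 0.2727273, 0.7272727),
                      2, byrow = TRUE), tolerance = 1e-7)
  expect_identical(inv$direction, "generator")
  # double inversion with the implied marginal recovers the input
  implied <- drop(crossprod(m$P, c(0.75, 0.25)))
  back <- invert_direction(inv, implied)
  expect_equal(back$P, m$P, tolerance = 1e-9)
  expect_equal(unname(rowSums(inv$P)), c(1, 1), tolerance = 1e-12)
})

test_that("inversion refuses marginals that zero out a category", {
  m <- misclass_matrix(matrix(c(1, 0, 1, 0), 2, byrow = TRUE),
                       direction = "inverse")
  expect_error(invert_direction(m, c(0.5, 0.5)), "degenerate")
})

test_that("uniform-prior inversion of the empirical matrices stays row-stochastic", {
  m <- ehr_misclass_matrices()
  for (g in list(as_generator(m$overall), as_generator(m$stratified),
                 as_generator(m$overall, "direct"),
                 as_generator(m$stratified, "direct"))) {
    mats <- if (g$mode == "non_differential") list(g$P) else g$P_by_y
    for (M in mats) expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-9)
    expect_identical(g$direction, "generator")
  }
})

test_that("matrices round-trip through CSV plus descriptor", {
  dir <- withr::local_tempdir()
  m <- ehr_misclass_matrices()
  p1 <- file.path(dir, "overall.csv")
  write_misclass_matrix(m$overall, p1)
  expect_equal(read_misclass_matrix(p1)$P, m$overall$P, tolerance = 1e-12)
  p2 <- file.path(dir, "strat.csv")
  write_misclass_matrix(m$stratified, p2)
  back <- read_misclass_matrix(p2)
  expect_equal(back$P_by_y, m$stratified$P_by_y, tolerance = 1e-12)
  expect_identical(back$direction, "inverse")
})
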