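four_eggs <- function(ms = 8, pc = 500, cov = 0.2, disp = 0.1, clutch = 1,
                      n = 4) {
  data.frame(clutch_id = clutch, lay_order = seq_len(n), marking_size = ms,
             pattern_contrast = pc, pattern_coverage = cov,
             pattern_dispersion = disp)
}

test_that("clutch means of identical eggs equal the single-egg log metrics", {
  cl <- clutch_pattern(four_eggs())
  expect_equal(cl$marking_size, log(8 + 1e-3))
  expect_equal(cl$pattern_coverage, log(0.2 + 1e-3))
  expect_equal(cl$n_eggs, 4L)
  expect_false(cl$partial)
  whole <- clutch_pattern(four_eggs(n = 7), mode = "whole")
  first4 <- clutch_pattern(four_eggs(n = 7))
  expect_equal(whole[metric_cols <- c("marking_size", "pattern_contrast",
                                      "pattern_coverage", "pattern_dispersion")],
               first4[metric_cols])
})

test_that("short clutches are flagged as partial, never silently padded", {
  cl <- clutch_pattern(four_eggs(n = 3))
  expect_true(cl$partial)
  expect_equal(cl$n_eggs, 3L)
})

test_that("only the first four eggs by lay order enter the clutch mean", {
  eggs <- four_eggs(n = 8)
  eggs$pattern_coverage <- c(rep(0.2, 4), rep(0.9, 4))
  eggs <- eggs[sample(8), ]       # order in the table must not matter
  cl <- clutch_pattern(eggs)
  expect_equal(cl$pattern_coverage, log(0.2 + 1e-3))
})

test_that("PCA percentages always sum to 100 and rank-1 input loads on PC1", {
  set.seed(5)
  base <- rnorm(50)
  rank1 <- data.frame(marking_size = base, pattern_contrast = 2 * base,
                      pattern_coverage = -base, pattern_dispersion = 0.5 * base)
  p <- pca_pattern(rank1)
  expect_equal(sum(p$percent_variance), 100)
  expect_equal(p$percent_variance[1], 100, tolerance = 1e-8)
  noisy <- as.data.frame(matrix(rnorm(200), ncol = 4,
                                dimnames = list(NULL, names(rank1))))
  expect_equal(sum(pca_pattern(noisy)$percent_variance), 100, tolerance = 1e-10)
})

test_that("uncorrelated variables share the variance equally at large n", {
  set.seed(6)
  X <- as.data.frame(matrix(rnorm(4e4), ncol = 4))
  names(X) <- c("marking_size", "pattern_contrast", "pattern_coverage",
                "pattern_dispersion")
  p <- pca_pattern(X)
  expect_true(all(abs(p$percent_variance - 25) < 1.5))
})

test_that("scores are centred, decorrelated, and reconstruct the data", {
  set.seed(7)
  Z <- matrix(rnorm(400), ncol = 4)
  X <- data.frame(marking_size = Z[, 1], pattern_contrast = 0.7 * Z[, 1] + Z[, 2],
                  pattern_coverage = Z[, 3], pattern_dispersion = Z[, 4] - 0.4 * Z[, 3])
  p <- pca_pattern(X)
  expect_lt(max(abs(colMeans(p$scores))), 1e-8)
  cv <- stats::cov(p$scores)
  expect_equal(unname(diag(cv)), p$eigenvalues, tolerance = 1e-8)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
  # loadings are orthonormal, so scores %*% t(loadings) restores the z-data
  Zs <- scale(as.matrix(X))
  attr(Zs, "scaled:center") <- attr(Zs, "scaled:scale") <- NULL
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(Zs), tolerance = 1e-8)
  # sign convention: coverage loads positively on every component
  expect_true(all(p$loadings["pattern_coverage", ] >= 0))
})

test_that("degenerate PCA inputs are rejected", {
  X <- four_eggs(n = 6)[c("marking_size", "pattern_contrast",
                          "pattern_coverage", "pattern_dispersion")]
  expect_error(pca_pattern(X), "constant")
  expect_error(pca_pattern(X[1:3, ]), "at least 5 rows")
})

test_that("clutch speckling covaries strongly on heterogeneous simulated eggs", {
  eggs <- simulate_egg_metrics(60, clutch_sizes = 8, seed = 9)
  sc <- speckle_scores(eggs)
  expect_gte(sc$pca$percent_variance[1], 40)
  expect_equal(nrow(sc$clutches), 60)
  # egg-level and clutch-level PCA orders clutches consistently
  sc2 <- speckle_scores(eggs, level = "clutch")
  expect_gt(stats::cor(sc$clutches$PC1, sc2$clutches$PC1), 0.9)
})
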