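test_that("z-standardization centres and scales, and exempts PC scores", {
  d <- data.frame(a = c(1, 2, 3), PC1 = c(0.3, -0.2, 0.5))
  z <- zstandardize(d)
  expect_equal(z$a, c(-1, 0, 1))
  expect_identical(z$PC1, d$PC1)          # bit-identical pass-through
  expect_equal(zstandardize(z)$a, z$a, tolerance = 1e-12)  # idempotent
  expect_error(zstandardize(data.frame(a = rep(2, 5))), "constant")
})

test_that("a noiseless linear construction is fitted exactly", {
  set.seed(1)
  x <- as.numeric(scale(rnorm(30)))
  d <- data.frame(y = 0.54 * x, x = x)
  f <- suppressWarnings(fit_glm(d, "y", "x", standardize = FALSE))
  i <- match("x", f$table$term)
  expect_equal(f$table$B[i], 0.54, tolerance = 1e-12)
  expect_lt(f$table$ci_upper[i] - f$table$ci_lower[i], 1e-8)
  expect_lt(suppressWarnings(summary(f$fit))$sigma, 1e-12)
})

test_that("rank deficiency is reported with the offending terms", {
  set.seed(2)
  d <- data.frame(y = rnorm(20), x1 = rnorm(20))
  d$x2 <- 2 * d$x1
  expect_error(fit_glm(d, "y", c("x1", "x2")), "x2")
})

test_that("a predictor orthogonal to the response tests at its nominal level", {
  set.seed(3)
  ps <- replicate(400, {
    d <- data.frame(y = rnorm(40), x = rnorm(40))
    fit_glm(d, "y", "x")$table$P[2]
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.08)   # P uniform under the null
})

test_that("the mixed model collapses to the GLM when group variance is zero", {
  set.seed(4)
  n <- 120
  d <- data.frame(mass = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                  origin_nest = rep(1:6, each = 20),
                  foster_nest = rep(1:6, times = 20))
  # remove all between-group signal so the REML variance sits on the boundary
  grp <- interaction(d$foster_nest, d$origin_nest, drop = TRUE)
  d$mass <- d$mass - stats::ave(d$mass, grp)
  suppressWarnings(lf <- fit_lmm(d, "mass", c("x1", "x2")))
  gf <- fit_glm(d[c("mass", "x1", "x2")], "mass", c("x1", "x2"))
  expect_true(lf$singular)
  expect_lt(lf$random_variance$estimate, 1e-8)
  expect_equal(lf$table$B, gf$table$B, tolerance = 1e-6)
})

test_that("the closed-form REML surface agrees with the lme4 fit", {
  ex <- generate_experiment(experiment_params(n_nests = 16, seed = 6))
  f <- suppressWarnings(fit_chick_mass(ex, day = 15))
  d <- chick_data(ex, day = 15)
  d$.grp <- interaction(d$foster_nest, d$origin_nest, drop = TRUE)
  d <- zstandardize(d, columns = setdiff(names(d)[vapply(d, is.numeric, logical(1))],
                                         c("origin_nest", "foster_nest")))
  X <- stats::model.matrix(~ lay_date + brood_size + PC1_origin + sex +
                             avg_egg_mass + PC1_foster_laid + clutch_size +
                             clutch_size_foster + PC1_foster_incubated, data = d)
  # independent maximisation of the hand-written REML log-likelihood
  opt <- stats::optim(c(0.3, 0.7), function(th) {
    -eggspeckle:::reml_loglik_nested(th[1], th[2], d$mass, X, d$.grp)
  }, method = "L-BFGS-B", lower = c(1e-6, 1e-6))
  expect_equal(opt$par[1], f$random_variance$estimate, tolerance = 1e-3)
  expect_equal(opt$par[2], f$random_variance$residual, tolerance = 1e-3)
})

test_that("fixed effects are invariant to affine rescaling of raw inputs", {
  ex <- generate_experiment(experiment_params(n_nests = 16, seed = 7))
  d <- provisioning_data(ex)
  f1 <- fit_provisioning(d)
  d2 <- d
  d2$prey_male <- 10 + 3 * d2$prey_male
  d2$brood_size <- 100 * d2$brood_size
  f2 <- fit_provisioning(d2)
  expect_equal(f1$table$B, f2$table$B, tolerance = 1e-9)
})

test_that("rejection rates behave at the alpha extremes", {
  p <- experiment_params(n_nests = 8)
  rr0 <- rejection_rate(p, fit_provisioning, "PC1_incubated", reps = 5, alpha = 0)
  expect_identical(rr0$rate, 0)
  strong <- experiment_params(n_nests = 16, speckling_to_provisioning_slope = 0.9,
                              residual_sd = 0.05)
  rr1 <- rejection_rate(strong, fit_provisioning, "PC1_incubated", reps = 15)
  expect_equal(rr1$rate, 1)
})

test_that("paired t-tests handle degenerate and zero-mean differences", {
  eggs <- simulate_egg_metrics(6, clutch_sizes = 4, seed = 8)  # all eggs photographed
  f4 <- clutch_pattern(eggs, first_n = 4)
  wh <- clutch_pattern(eggs, mode = "whole")
  res <- paired_t(f4, wh)
  expect_true(all(res$note == "zero difference"))
  expect_true(all(is.na(res$t)))
  # differences (1, -1, 0, 0, 0) give t = 0 exactly
  f4b <- data.frame(clutch_id = 1:5, marking_size = c(1, -1, 0, 0, 0),
                    pattern_contrast = 1, pattern_coverage = 1,
                    pattern_dispersion = 1)
  whb <- data.frame(clutch_id = 1:5, marking_size = 0,
                    pattern_contrast = 1 - c(1, -1, 0, 0, 0),
                    pattern_coverage = 1, pattern_dispersion = 1)
  res2 <- paired_t(f4b, whb)
  expect_equal(res2$t[res2$variable == "marking_size"], 0)
  expect_equal(res2$t[res2$variable == "pattern_contrast"], 0)
  expect_error(paired_t(f4b[1, ], whb[1, ]), "at least 2")
})

test_that("fit tables carry the reporting contract", {
  ex <- generate_experiment(experiment_params(n_nests = 16, seed = 9))
  f <- fit_provisioning(ex)
  expect_s3_class(f, "speckle_fit")
  expect_equal(f$table$term[1], "(Intercept)")
  expect_equal(f$table$term[2], "brood_size")   # rows follow the predictor order
  expect_true(all(f$table$P >= 0 & f$table$P <= 1))
  expect_true(all(f$table$F >= 0))
  expect_true(all(f$table$ci_lower <= f$table$B & f$table$B <= f$table$ci_upper))
  expect_equal(unname(coef(f)), f$table$B)
  ci <- confint(f)
  expect_equal(unname(ci[, 1]), f$table$ci_lower)
})
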