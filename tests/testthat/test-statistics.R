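test_that("z-normalisation: hand case, affine invariance, constant input", {
  expect_equal(znormalize(c(2, 4, 6)), c(-1, 0, 1))
  x <- c(3.1, 0.2, -5, 8, 2.2)
  z <- znormalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(znormalize(2.5 * x + 7), z, tolerance = 1e-12)
  expect_error(znormalize(rep(4, 5)), "zero standard deviation")
})

test_that("bivariate screening reproduces the exact t-test p-values", {
  set.seed(21)
  n <- 10
  y <- stats::rnorm(n)
  # orthogonalised zero-correlation predictor
  x0 <- stats::rnorm(n)
  x0 <- stats::residuals(stats::lm(x0 ~ y))
  tab <- data.frame(peak_strain = y, self = y, ortho = x0,
                    const = rep(1, n), noise = stats::rnorm(n))
  sc <- bivariate_screen(tab)
  expect_equal(sc$pearson_r[sc$predictor == "self"], 1, tolerance = 1e-12)
  expect_lt(sc$p_value[sc$predictor == "self"], 1e-12)
  expect_equal(sc$pearson_r[sc$predictor == "ortho"], 0, tolerance = 1e-9)
  expect_equal(sc$p_value[sc$predictor == "ortho"], 1, tolerance = 1e-9)
  expect_equal(sc$flag[sc$predictor == "const"], "constant")
  expect_true(is.na(sc$pearson_r[sc$predictor == "const"]))
  # agreement with cor.test
  ct <- stats::cor.test(tab$noise, y)
  expect_equal(sc$p_value[sc$predictor == "noise"], unname(ct$p.value),
               tolerance = 1e-12)
  # n = 10, r = 0.6 is not significant at alpha = 0.05
  r <- 0.6
  p <- 2 * stats::pt(-abs(r * sqrt(8 / (1 - r^2))), df = 8)
  expect_gt(p, 0.05)
})

test_that("Box-Cox: lambda recovers the generating transform family", {
  set.seed(33)
  ln <- boxcox_transform(exp(stats::rnorm(4000, 0, 0.4)))
  expect_lt(abs(ln$lambda), 0.15)              # log-normal -> lambda ~ 0
  nm <- boxcox_transform(pmax(0.5, stats::rnorm(4000, 10, 2.5)))
  expect_lt(abs(nm$lambda - 1), 0.35)          # already normal -> lambda ~ 1
  # lambda = 1 branch is a pure location shift
  y <- c(1.5, 2, 4, 9)
  expect_equal(boxcox_transform(y, lambda_grid = 1)$transformed, y - 1)
  expect_error(boxcox_transform(c(1, -2, 3)), "positive")
  # profile-likelihood maximiser agrees with MASS::boxcox on a shared grid
  skip_if_not_installed("MASS")
  set.seed(34)
  yy <- exp(stats::rnorm(200, 1, 0.3))
  grid <- seq(-2, 2, by = 0.01)
  bc <- MASS::boxcox(yy ~ 1, lambda = grid, plotit = FALSE)
  expect_equal(boxcox_transform(yy, lambda_grid = grid)$lambda,
               bc$x[which.max(bc$y)], tolerance = 1e-9)
})

test_that("noiseless data generated from the published equation is recovered exactly", {
  set.seed(55)
  n <- 40
  tab <- data.frame(
    trunk_flexion_at_maxGRF = stats::runif(n, 5, 40),
    hip_flexion_at_maxGRF = stats::runif(n, 20, 70),
    ankle_flexion_at_maxGRF = stats::runif(n, 5, 35),
    max_knee_flexion = stats::runif(n, 40, 90))
  tab$peak_strain <- with(tab, predict_peak_strain(
    trunk = trunk_flexion_at_maxGRF, hip = hip_flexion_at_maxGRF,
    knee = max_knee_flexion, ankle = ankle_flexion_at_maxGRF))
  # a perfect fit makes lm's own F-statistics degenerate; that is the point
  fit <- suppressWarnings(fit_empirical_model(
    tab, predictors = c("max_knee_flexion", "ankle_flexion_at_maxGRF",
                        "hip_flexion_at_maxGRF", "trunk_flexion_at_maxGRF"),
    transform = "log"))
  pub <- published_strain_model()$coefficients
  expect_equal(unname(fit$coefficients["(Intercept)"]), 9.09, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["max_knee_flexion"]),
               unname(pub["max_knee_flexion"]), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["trunk_flexion_at_maxGRF"]),
               unname(pub["trunk_flexion_at_maxGRF"]), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("contribution accounting: sequential shares plus error total 100", {
  set.seed(66)
  n <- 30
  tab <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n), c = stats::rnorm(n))
  tab$peak_strain <- exp(0.5 + 0.3 * tab$a - 0.2 * tab$b + stats::rnorm(n, 0, 0.2))
  fit <- fit_empirical_model(tab, c("a", "b", "c"))
  expect_equal(sum(fit$contribution_pct), 100, tolerance = 0.1)
  expect_true("error" %in% names(fit$contribution_pct))
  # single-predictor fit: R^2 equals the squared Pearson correlation
  f1 <- fit_empirical_model(tab, "a", transform = "identity")
  expect_equal(f1$r_squared, stats::cor(tab$a, tab$peak_strain)^2,
               tolerance = 1e-12)
  expect_equal(unname(f1$contribution_pct["a"]), 100 * f1$r_squared,
               tolerance = 1e-9)
})

test_that("rank-deficient designs fail with the collinear column named", {
  set.seed(67)
  tab <- data.frame(a = stats::rnorm(12))
  tab$b <- 2 * tab$a
  tab$peak_strain <- exp(1 + tab$a + stats::rnorm(12, 0, 0.1))
  expect_error(fit_empirical_model(tab, c("a", "b")), "collinear.*b")
  expect_error(fit_empirical_model(tab[1:3, ], c("a", "b")),
               "need n > number of predictors")
})

test_that("published-equation evaluator: constant case, hand value, monotonicity", {
  expect_equal(predict_peak_strain(0, 0, 0, 0), exp(9.09), tolerance = 1e-12)
  # hand evaluation with the printed rounded coefficients:
  # 9.09 + 0.07*60 - 0.266*20 - 0.136*40 - 0.165*10 = 0.88
  rounded <- published_strain_model()
  rounded$coefficients[] <- c(9.09, 0.07, -0.266, -0.136, -0.165)
  expect_equal(predict_peak_strain(trunk = 10, hip = 40, knee = 60, ankle = 20,
                                   model = rounded),
               exp(0.88), tolerance = 1e-9)
  expect_equal(exp(0.88), 2.41, tolerance = 0.002)
  # strictly decreasing in trunk/hip/ankle, increasing in knee
  base <- predict_peak_strain(trunk = 10, hip = 40, knee = 60, ankle = 20)
  expect_lt(predict_peak_strain(11, 40, 60, 20), base)
  expect_lt(predict_peak_strain(10, 41, 60, 20), base)
  expect_lt(predict_peak_strain(10, 40, 60, 21), base)
  expect_gt(predict_peak_strain(10, 40, 61, 20), base)
  expect_warning(predict_peak_strain(150, 40, 60, 20), "envelope")
  # published diagnostics carry the reported fit quality
  pub <- published_strain_model()
  expect_equal(pub$r_squared, 0.9004)
  expect_equal(sum(pub$contribution_pct), 100, tolerance = 0.1)
})
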