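# Textbook Cox--de Boor recursion, coded independently of splineDesign.
coxdeboor <- function(x, knots, ord) {
  nb <- length(knots) - ord
  B <- matrix(0, length(x), length(knots) - 1)
  for (j in seq_len(length(knots) - 1)) {
    B[, j] <- as.numeric(x >= knots[j] & x < knots[j + 1])
  }
  for (d in 2:ord) {
    Bn <- matrix(0, length(x), length(knots) - d)
    for (j in seq_len(length(knots) - d)) {
      a <- if (knots[j + d - 1] > knots[j]) {
        (x - knots[j]) / (knots[j + d - 1] - knots[j]) * B[, j]
      } else 0
      b <- if (knots[j + d] > knots[j + 1]) {
        (knots[j + d] - x) / (knots[j + d] - knots[j + 1]) * B[, j + 1]
      } else 0
      Bn[, j] <- a + b
    }
    B <- Bn
  }
  B[, seq_len(nb), drop = FALSE]
}

test_that("log-plus-one transform behaves at and away from zero", {
  expect_equal(log1p_catch(0), 0)
  expect_equal(log1p_catch(exp(1) - 1), 1)
  x <- sort(runif(50, 0, 100))
  expect_true(all(diff(log1p_catch(x)) > 0))
  expect_error(log1p_catch(-1), "non-negative")
})

test_that("B-spline basis is a partition of unity with the stated penalty
           null space", {
  set.seed(5)
  x <- runif(200)
  bs <- spline_basis(x, k = 10)
  expect_equal(rowSums(bs$B), rep(1, 200), tolerance = 1e-12)
  # second-difference penalty annihilates constant and linear coefficients
  expect_equal(drop(t(rep(1, 10)) %*% bs$S %*% rep(1, 10)), 0,
               tolerance = 1e-12)
  lin <- seq_len(10)
  expect_equal(drop(t(lin) %*% bs$S %*% lin), 0, tolerance = 1e-10)
  expect_error(spline_basis(rep(1:5, 10), k = 10), "distinct")
})

test_that("basis evaluation matches the Cox--de Boor recursion", {
  set.seed(15)
  x <- runif(50, 0.05, 0.95)
  bs <- spline_basis(c(0, 1, runif(30)), k = 8)
  oracle <- coxdeboor(x, bs$knots, ord = 4)
  ours <- splines::splineDesign(bs$knots, x, ord = 4)
  expect_equal(ours, oracle, tolerance = 1e-12)
})

test_that("a noise-free linear effect collapses to one degree of freedom
           with the slope recovered", {
  set.seed(25)
  n <- 2000
  x1 <- runif(n); x2 <- runif(n)
  y <- 3 + 2 * x1
  fit <- fit_additive(y, data.frame(x1 = x1, x2 = x2))
  expect_lt(abs(fit$terms$x1$edf - 1), 0.2)
  pe <- partial_effect(fit, "x1", grid = c(0.25, 0.75))
  expect_equal(diff(pe$fit) / 0.5, 2, tolerance = 1e-3)
  # the zero-signal term contributes (numerically) nothing
  pe2 <- partial_effect(fit, "x2")
  expect_lt(max(abs(pe2$fit)), 1e-3)
})

test_that("a sine effect is recovered with small partial-effect error", {
  set.seed(35)
  n <- 2000
  x1 <- runif(n); x2 <- runif(n)
  y <- sin(2 * pi * x1) + rnorm(n, 0, 0.1)
  fit <- fit_additive(y, data.frame(x1 = x1, x2 = x2))
  g <- seq(0.02, 0.98, length.out = 100)
  pe <- partial_effect(fit, "x1", grid = g)
  truth <- sin(2 * pi * g) - mean(sin(2 * pi * x1))
  expect_lt(sqrt(mean((pe$fit - truth)^2)), 0.1)
  expect_gt(fit$terms$x1$edf, 3)  # genuinely non-linear
  expect_lte(fit$terms$x1$edf, fit$terms$x1$ref_df + 1e-8)
  expect_lte(fit$terms$x1$ref_df, 9 + 1e-8)
})

test_that("fitted plus residuals reconstruct the response exactly and
           deviance explained equals unadjusted R-squared", {
  set.seed(45)
  n <- 400
  d <- data.frame(a = runif(n), b = runif(n))
  y <- d$a^2 + rnorm(n, 0, 0.2)
  fit <- fit_additive(y, d)
  expect_identical(fit$residuals, y - fit$fitted)
  expect_equal(fit$fitted + fit$residuals, y, tolerance = 1e-12)
  r2_unadj <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  expect_equal(fit$deviance_explained, r2_unadj, tolerance = 1e-12)
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, d), fit$fitted, tolerance = 1e-8)
})

test_that("smoothing limits drive the effective degrees of freedom to
           their bounds", {
  set.seed(55)
  n <- 500
  d <- data.frame(a = runif(n))
  y <- sin(4 * d$a) + rnorm(n, 0, 0.1)
  lofit <- fit_additive(y, d, lambda_grid = 1e-8)
  hifit <- fit_additive(y, d, lambda_grid = 1e10)
  expect_gt(lofit$terms$a$edf, 8.5)   # ~ k - 1 under the centering constraint
  expect_lt(abs(hifit$terms$a$edf - 1), 0.05)  # linear limit
})

test_that("the GCV optimum beats random smoothing parameters", {
  set.seed(65)
  n <- 600
  d <- data.frame(a = runif(n), b = runif(n))
  y <- cos(3 * d$a) + 0.5 * d$b + rnorm(n, 0, 0.3)
  fit <- fit_additive(y, d)
  # GCV score of a fit restricted to one candidate lambda
  score <- function(lambdas) {
    f <- fit_additive(y, d, lambda_grid = lambdas, max_sweeps = 1)
    f$gcv
  }
  for (i in 1:20) {
    lam <- 10^runif(1, -6, 8)
    expect_lte(fit$gcv, score(lam) * (1 + 1e-6))
  }
})

test_that("all-noise responses rarely produce significant smooths", {
  set.seed(75)
  hits <- 0
  for (i in 1:50) {
    n <- 300
    d <- data.frame(a = runif(n))
    y <- rnorm(n)
    fit <- fit_additive(y, d)
    if (fit$terms$a$p_value > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 42)  # ~90% at a loose tolerance
})

test_that("confidence bands are symmetric, shrink with n, and locate a
           known peak", {
  set.seed(85)
  gen <- function(n) {
    x <- runif(n)
    list(x = x, y = exp(-(x - 0.6)^2 / 0.02) + rnorm(n, 0, 0.1))
  }
  d1 <- gen(400); d2 <- gen(1600)
  f1 <- fit_additive(d1$y, data.frame(x = d1$x))
  f2 <- fit_additive(d2$y, data.frame(x = d2$x))
  g <- seq(0.05, 0.95, length.out = 120)
  p1 <- partial_effect(f1, "x", grid = g)
  p2 <- partial_effect(f2, "x", grid = g)
  expect_equal(p1$fit - p1$lower, p1$upper - p1$fit, tolerance = 1e-10)
  expect_lt(mean(p2$upper - p2$lower), mean(p1$upper - p1$lower))
  # peak of the unimodal truth at 0.6, recovered within the IQR resolution
  expect_lt(abs(g[which.max(p2$fit)] - 0.6), 0.15)
})

test_that("optimal range follows the narrowest-band rule", {
  pe <- data.frame(x = seq(0, 1, length.out = 101),
                   fit = sin(seq(0, pi, length.out = 101)))
  pe$se <- 0.5 + (pe$x - 0.55)^2        # narrowest near 0.55
  pe$lower <- pe$fit - 1.96 * pe$se
  pe$upper <- pe$fit + 1.96 * pe$se
  class(pe) <- c("partial_effect", "data.frame")
  opt <- optimal_range(pe)
  expect_false(opt$noninformative)
  expect_true(opt$range[1] <= 0.55 && 0.55 <= opt$range[2])

  # constant width: whole grid, flagged non-informative
  pe2 <- pe
  pe2$se <- 1
  pe2$lower <- pe2$fit - 1.96; pe2$upper <- pe2$fit + 1.96
  opt2 <- optimal_range(pe2)
  expect_true(opt2$noninformative)
  expect_equal(opt2$indices, 1:101)

  # fraction 0 keeps only the single narrowest point
  opt3 <- optimal_range(pe, fraction = 0)
  expect_equal(length(opt3$indices), 1)
})

test_that("the additive fit agrees with an independent penalized-spline
           implementation on a shared dataset", {
  skip_if_not_installed("mgcv")
  set.seed(95)
  n <- 1000
  d <- data.frame(a = runif(n), b = runif(n))
  y <- sin(2 * pi * d$a) + 2 * (d$b - 0.5)^2 + rnorm(n, 0, 0.2)
  ours <- fit_additive(y, d)
  ref <- mgcv::gam(y ~ s(a, bs = "ps", k = 10) + s(b, bs = "ps", k = 10),
                   data = d, method = "GCV.Cp")
  # same data, same smooth family: fitted curves agree closely
  expect_gt(cor(fitted(ref), ours$fitted), 0.999)
  expect_lt(abs(summary(ref)$dev.expl - ours$deviance_explained), 0.01)
})
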