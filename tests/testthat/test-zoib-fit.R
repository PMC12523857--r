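test_that("negative log posterior reduces to the likelihood and matches a
           row-wise oracle", {
  # single row, y = 0.5, intercept-only: -log((1 - zoi) * dbeta) = -log(0.8)
  pr <- zoib_params(beta_mu = 0, beta_phi = log(2),
                    beta_zoi = stats::qlogis(0.2), beta_coi = 0,
                    prior_scale = 1)
  X1 <- matrix(1, 1, 1)
  nlp <- zoib_neglogpost(pr, y = 0.5, X = X1)
  expect_equal(nlp, -log(0.8), tolerance = 1e-10)  # intercepts unpenalized

  # vanishing penalty: huge prior scale reduces to the pure -loglik
  set.seed(52)
  fx <- make_zoib_data(n = 60, seed = 52)
  pr2 <- fx$truth
  pr2$prior_scale <- 1e12
  lp <- zoib_linpred(pr2, fx$X)
  loglik <- sum(dzoib(fx$data$y, lp$mu, lp$phi, lp$zoi, lp$coi, log = TRUE))
  expect_equal(zoib_neglogpost(pr2, fx$data$y, fx$X), -loglik,
               tolerance = 1e-8)

  # independently coded sum over rows, including the Laplace penalty
  pr3 <- fx$truth
  pr3$prior_scale <- 0.7
  pen <- sum(sqrt(c(pr3$beta_mu[-1], pr3$beta_phi[-1], pr3$beta_zoi[-1],
                    pr3$beta_coi[-1])^2 + 1e-16)) / 0.7
  expect_equal(zoib_neglogpost(pr3, fx$data$y, fx$X), -loglik + pen,
               tolerance = 1e-8)
})

test_that("analytic gradient matches finite differences", {
  set.seed(63)
  fx <- make_zoib_data(n = 150, seed = 63, n_blocks = 4)
  dat <- zoibcatch:::zoib_prepare(fx$data$y, fx$X, fx$block)
  th <- zoibcatch:::params_to_theta(fx$truth, dat) +
    rnorm(4 * dat$p + dat$B + 1, 0, 0.05)
  g <- zoibcatch:::zoib_nlp_grad(th, dat, prior_scale = 0.8)
  h <- 1e-6
  for (i in seq_along(th)) {
    tp <- th; tm <- th
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    num <- (zoibcatch:::zoib_nlp_theta(tp, dat, 0.8) -
              zoibcatch:::zoib_nlp_theta(tm, dat, 0.8)) / (2 * h)
    expect_equal(unname(g[i]), num, tolerance = 1e-4)
  }
})

test_that("MAP stays at the truth when initialized there", {
  fx <- make_zoib_data(n = 2000, seed = 74)
  dat <- zoibcatch:::zoib_prepare(fx$data$y, fx$X)
  th_true <- zoibcatch:::params_to_theta(fx$truth, dat)
  m <- zoibcatch:::zoib_fit_map(dat, prior_scale = 1, init = th_true)
  # a local optimum near the truth: displacement bounded by sampling error
  expect_lt(max(abs(m$theta - th_true)), 0.3)
})

test_that("intercept-only MAP matches empirical boundary fractions and
           interior mean", {
  set.seed(85)
  n <- 2000
  truth <- zoib_params(beta_mu = stats::qlogis(0.6), beta_phi = log(6),
                       beta_zoi = stats::qlogis(0.2),
                       beta_coi = stats::qlogis(0.35))
  y <- rzoib(n, 0.6, 6, 0.2, 0.35)
  d <- data.frame(y = y)
  fit <- suppressWarnings(zoib(y ~ 1, d))
  cf <- coef(fit)
  frac_b <- mean(y == 0 | y == 1)
  frac_1 <- mean(y[y == 0 | y == 1] == 1)
  mean_mid <- mean(y[y > 0 & y < 1])
  se <- 3 / sqrt(n)
  expect_lt(abs(plogis(cf["zoi:(Intercept)"]) - frac_b), 3 * se)
  expect_lt(abs(plogis(cf["coi:(Intercept)"]) - frac_1), 6 * se)
  expect_lt(abs(plogis(cf["mu:(Intercept)"]) - mean_mid), 3 * se)
})

test_that("MAP recovers known coefficients within 0.2", {
  fx <- make_zoib_data(
    n = 2000, seed = 96,
    params = zoib_params(beta_mu = c(0.2, 0.5, -0.4),
                         beta_phi = log(8),
                         beta_zoi = c(stats::qlogis(0.15), 0.3, 0),
                         beta_coi = stats::qlogis(0.4)))
  fit <- zoib(y ~ x1 + x2, fx$data, standardize = FALSE)
  cf <- coef(fit)
  expect_lt(abs(cf["mu:x1"] - 0.5), 0.2)
  expect_lt(abs(cf["mu:x2"] - (-0.4)), 0.2)
  expect_lt(abs(cf["zoi:x1"] - 0.3), 0.2)
  expect_equal(fit$convergence, 0)
})

test_that("zoib object methods are coherent", {
  fx <- make_zoib_data(n = 600, seed = 107)
  fit <- zoib(y ~ x1 + x2 + x3, fx$data)
  expect_s3_class(fit, "zoib")
  expect_equal(length(fitted(fit)), 600)
  expect_equal(residuals(fit), fx$data$y - fitted(fit))
  expect_true(all(fitted(fit) >= 0 & fitted(fit) <= 1))
  # prediction on new data transforms covariates back to original scale
  nd <- fx$data[1:5, ]
  expect_equal(predict(fit, nd), fitted(fit)[1:5], tolerance = 1e-10)
  comp <- predict(fit, nd, type = "components")
  expect_named(comp, c("mu", "phi", "zoi", "coi"))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= fit$theta & fit$theta <= ci[, 2]))
  s <- summary(fit)
  expect_s3_class(s, "summary.zoib")
  expect_output(print(s), "Zero-one inflated beta")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(600, 2))
})

test_that("all-boundary responses flag the Beta component unidentifiable", {
  set.seed(118)
  d <- data.frame(y = sample(c(0, 1), 200, replace = TRUE, prob = c(.6, .4)),
                  x1 = rnorm(200))
  fit <- zoib(y ~ x1, d)
  expect_false(fit$identifiable[["beta"]])
  expect_true(fit$identifiable[["zoi"]])
  # inflation components still estimated sensibly
  expect_lt(abs(plogis(coef(fit)["zoi:(Intercept)"]) - 1), 0.01)
  expect_lt(abs(plogis(coef(fit)["coi:(Intercept)"]) - mean(d$y)), 0.1)
})

test_that("metrics formulas satisfy the hand-computable cases", {
  expect_equal(unname(fit_metrics(c(0.3, 0.7), c(0.3, 0.7))), c(0, 0, 1))
  expect_equal(unname(fit_metrics(c(0, 1), c(1, 0))), c(1, 1, -3))
  y <- c(1, 2, 3, 4)
  expect_equal(unname(fit_metrics(y, rep(mean(y), 4))["r2"]), 0)
  expect_error(fit_metrics(1:3, 1:4), "length")
  const <- fit_metrics(rep(1, 5), rnorm(5))
  expect_true(is.na(const["r2"]))
})

test_that("MAE never exceeds RMSE", {
  set.seed(129)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    m <- fit_metrics(rnorm(n), rnorm(n))
    expect_lte(m[["mae"]], m[["rmse"]] + 1e-12)
  }
})

test_that("k-fold CV partitions rows and scores held-out folds", {
  fx <- make_zoib_data(n = 1000, seed = 140, n_blocks = 20)
  fit <- zoib(y ~ x1 + x2 + x3, fx$data, block = "blk")
  cv <- kfold_cv(fit, k = 5, blocking = "record", seed = 3)
  expect_equal(sort(unname(unlist(cv$per_fold$n))), rep(200, 5))
  expect_equal(sum(cv$per_fold$n), 1000)
  # every row in exactly one held-out fold
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_equal(length(cv$fold), 1000)
  expect_true(all(is.finite(cv$mean)))

  cvb <- kfold_cv(fit, k = 4, blocking = "spatial_block", seed = 3)
  # spatial blocking keeps whole blocks together
  for (b in unique(fx$data$blk)) {
    expect_equal(length(unique(cvb$fold[fx$data$blk == b])), 1)
  }
})

test_that("held-out R2 approaches the oracle computed from true proportions", {
  fx <- make_zoib_data(
    n = 2000, seed = 151,
    params = zoib_params(beta_mu = c(0.2, 0.8, -0.6),
                         beta_phi = log(10),
                         beta_zoi = c(stats::qlogis(0.1), 0.5, 0),
                         beta_coi = stats::qlogis(0.5)))
  fit <- zoib(y ~ x1 + x2, fx$data, standardize = FALSE)
  cv <- kfold_cv(fit, k = 5, blocking = "record", seed = 7)
  lp <- zoib_linpred(fx$truth, fx$X)
  oracle <- fit_metrics(fx$data$y, zoib_mean(lp$mu, lp$zoi, lp$coi))
  expect_lt(abs(cv$mean[["r2"]] - oracle[["r2"]]), 0.1)
})

test_that("split_catch conserves mass and divides by effort", {
  r <- data.frame(mixed_catch_kg = 1000, sets = 2)
  s <- split_catch(r, 0.3)
  expect_equal(unlist(s[, c("blue_kg", "chub_kg", "blue_per_set",
                            "chub_per_set")], use.names = FALSE),
               c(300, 700, 150, 350))
  expect_equal(split_catch(r, 1)$blue_kg, 1000)
  set.seed(162)
  r2 <- data.frame(mixed_catch_kg = rlnorm(200, 8, 1),
                   sets = sample(1:5, 200, TRUE))
  s2 <- split_catch(r2, runif(200))
  # chub is the exact remainder, so totals reconstruct to the last bit
  expect_identical(s2$chub_kg, r2$mixed_catch_kg - s2$blue_kg)
  expect_true(all(abs(s2$blue_kg + s2$chub_kg - r2$mixed_catch_kg) <=
                    2 * .Machine$double.eps * r2$mixed_catch_kg))
  expect_error(split_catch(r2, 1.2), "p_blue")
})
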