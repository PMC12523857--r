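test_that("weighted centroid arithmetic and reductions", {
  expect_equal(weighted_centroid(150, 40, 2), c(lon = 150, lat = 40))
  expect_equal(weighted_centroid(c(150, 152), c(40, 42), c(1, 3)),
               c(lon = 151.5, lat = 41.5))
  set.seed(4)
  lon <- runif(30, 140, 160); lat <- runif(30, 30, 45)
  expect_equal(weighted_centroid(lon, lat, rep(2, 30)),
               c(lon = mean(lon), lat = mean(lat)))
  expect_error(weighted_centroid(lon, lat, rep(0, 30)), "zero")
  expect_error(weighted_centroid(lon, lat, c(-1, rep(1, 29))),
               "non-negative")
})

test_that("centroid is translation-equivariant", {
  set.seed(14)
  lon <- runif(50, 140, 160); lat <- runif(50, 30, 45); w <- runif(50)
  c0 <- weighted_centroid(lon, lat, w)
  c1 <- weighted_centroid(lon + 2.5, lat - 1.25, w)
  expect_equal(c1, c0 + c(lon = 2.5, lat = -1.25), tolerance = 1e-12)
})

test_that("species-proportion weights are dual: the total-weighted average
           of both species' centroids is the record centroid", {
  set.seed(24)
  lon <- runif(200, 140, 160); lat <- runif(200, 30, 45)
  p <- runif(200)
  cb <- weighted_centroid(lon, lat, p)
  cc <- weighted_centroid(lon, lat, 1 - p)
  wb <- sum(p); wc <- sum(1 - p)
  mix <- (cb * wb + cc * wc) / (wb + wc)
  expect_equal(mix, weighted_centroid(lon, lat, rep(1, 200)),
               tolerance = 1e-10)
})

test_that("bootstrap intervals are reproducible, degenerate at a point,
           and shrink like one over root n", {
  set.seed(34)
  b1 <- centroid_bootstrap(rep(150, 5), rep(40, 5), runif(5), B = 100,
                           seed = 1)
  expect_equal(b1$lon, c(150, 150))
  expect_equal(b1$lat, c(40, 40))

  lon <- rnorm(100, 150); lat <- rnorm(100, 40); w <- runif(100)
  r1 <- centroid_bootstrap(lon, lat, w, B = 300, seed = 9)
  r2 <- centroid_bootstrap(lon, lat, w, B = 300, seed = 9)
  expect_identical(r1, r2)

  lon4 <- rnorm(400, 150); lat4 <- rnorm(400, 40); w4 <- runif(400)
  r4 <- centroid_bootstrap(lon4, lat4, w4, B = 300, seed = 9)
  ratio <- diff(r1$lat) / diff(r4$lat)
  expect_gt(ratio, 1.4)   # ~2 with loose tolerance
  expect_lt(ratio, 2.9)
})

test_that("OLS trend reproduces an exactly linear drift and the closed
           form on random data", {
  years <- 2014:2023
  vals <- 40.61 + 0.3062 * (years - 2014)
  tr <- ols_trend(years, vals)
  expect_equal(tr$slope, 0.3062, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1, tolerance = 1e-9)

  const <- ols_trend(years, rep(41, 10))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)
  expect_true(const$degenerate)

  set.seed(44)
  for (i in 1:5) {
    x <- 2000 + 1:12
    y <- rnorm(12)
    tr <- ols_trend(x, y)
    # closed-form OLS oracle
    bx <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    ax <- mean(y) - bx * mean(x)
    res <- y - ax - bx * x
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    se <- sqrt(sum(res^2) / 10 / sum((x - mean(x))^2))
    p <- 2 * pt(-abs(bx / se), 10)
    expect_equal(tr$slope, bx, tolerance = 1e-10)
    expect_equal(tr$intercept, ax, tolerance = 1e-8)
    expect_equal(tr$r_squared, r2, tolerance = 1e-10)
    expect_equal(tr$p_value, p, tolerance = 1e-10)
  }
  expect_error(ols_trend(c(1, 1, 2), c(1, 2, 3)), "distinct")
})

test_that("Jarque-Bera matches its moment formula, its null case and a
           frozen reference implementation", {
  # symmetric set with S = 0 and K exactly 3 gives JB = 0, p = 1
  x0 <- c(-1, 1, 0, 0, 0, 0)
  jb0 <- jarque_bera(x0)
  expect_equal(unname(jb0["statistic"]), 0, tolerance = 1e-10)
  expect_equal(unname(jb0["p_value"]), 1, tolerance = 1e-10)

  set.seed(54)
  for (i in 1:5) {
    x <- rt(40, 5)
    n <- length(x)
    m <- x - mean(x)
    S <- mean(m^3) / mean(m^2)^1.5
    K <- mean(m^4) / mean(m^2)^2
    jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
    expect_equal(unname(jarque_bera(x)["statistic"]), jb,
                 tolerance = 1e-10)
  }

  # power sanity: a strongly skewed sample is rejected
  set.seed(64)
  expect_lt(jarque_bera(rexp(500))[["p_value"]], 0.01)
  expect_error(jarque_bera(rep(1, 10)), "zero-variance")
  expect_error(jarque_bera(1:3), "at least 4")
})

test_that("the omnibus and Jarque-Bera tests reproduce reference values", {
  # frozen values from an independent implementation of the same tests
  x <- c(0.30471707975443135, -1.0399841062404955, 0.7504511958064572,
         0.9405647163912139, -1.9510351886538364, -1.302179506862318,
         0.12784040316728537, -0.3162425923435822, -0.016801157504288795,
         -0.85304392757358, 0.8793979748628286, 0.7777919354289483,
         0.06603069756121605, 1.1272412069680329, 0.4675093422520456,
         -0.8592924628832382, 0.36875078408249884, -0.9588826008289989,
         0.8784503013072725, -0.049925910986252896)
  expect_equal(unname(jarque_bera(x)),
               c(1.443529562527971, 0.4858940022362458), tolerance = 1e-8)
  expect_equal(unname(omnibus_normtest(x)),
               c(1.6864868152130585, 0.43031257851165605), tolerance = 1e-8)

  y <- c(1.2473859498136242, 0.22357637221232038, 1.8379702641444624,
         1.2270858632142592, 0.6557961539630006, 0.41708670631181666,
         0.45331968929826566, 0.07707714705565474, 0.17963225437455377,
         0.6853204516042503, 0.3886802361598213, 1.2642068575651064,
         0.7084906274161253, 0.23792995429801636, 0.4610883362574712,
         0.6415567371905141, 0.34383336143779325, 0.3219112209063105,
         0.8789146821925446, 0.29694720892879944, 1.3337024250318834,
         1.3908639862459073, 1.0840829279651931, 0.07302834798043581,
         1.1340675017227546, 1.3543379878651725, 1.1220396514574276,
         0.2800491202364232, 0.3209361910360324, 0.1657359073015982)
  expect_equal(unname(jarque_bera(y)),
               c(2.48083234400199, 0.28926380938708646), tolerance = 1e-8)
  expect_equal(unname(omnibus_normtest(y)),
               c(3.342414931225356, 0.18801990095467266), tolerance = 1e-8)

  expect_error(omnibus_normtest(rnorm(7)), "n >= 8")
  expect_error(omnibus_normtest(rep(2, 20)), "zero-variance")
})

test_that("the omnibus test holds its nominal size on normal samples", {
  set.seed(74)
  rej <- 0
  for (i in 1:200) {
    if (omnibus_normtest(rnorm(100))[["p_value"]] < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.12)
})

test_that("centroid distance series uses great-circle distance and detects
           convergence", {
  a <- data.frame(year = 2014:2023, lon = rep(150, 10), lat = rep(40, 10))
  expect_true(all(centroid_distance_series(a, a)$distances$distance_km == 0))

  b <- a
  b$lat <- b$lat + 1
  d1 <- centroid_distance_series(a, b)$distances$distance_km
  expect_true(all(abs(d1 - 111.2) < 0.5))

  # linearly converging series: strongly negative trend, R2 near 1
  conv <- a
  conv$lat <- 40 + seq(2, 0.2, length.out = 10)
  cd <- centroid_distance_series(a, conv)
  expect_lt(cd$trend$slope, 0)
  expect_gt(cd$trend$r_squared, 0.99)

  expect_error(centroid_distance_series(a, transform(a, year = year + 100)),
               "common years")
})

test_that("annual centroid series stays inside each year's point cloud and
           flags sparse years", {
  set.seed(84)
  d <- data.frame(year = rep(2014:2016, c(50, 50, 4)),
                  lon = runif(104, 150, 155), lat = runif(104, 38, 42),
                  w = runif(104))
  cs <- centroid_series(d, weight = "w", B = 200, seed = 2, min_records = 10)
  expect_equal(cs$year, 2014:2016)
  expect_true(all(cs$lon >= 150 & cs$lon <= 155))
  expect_true(all(cs$lon_lower <= cs$lon & cs$lon <= cs$lon_upper))
  expect_true(all(cs$lat_lower <= cs$lat & cs$lat <= cs$lat_upper))
  expect_identical(cs$flagged, c(FALSE, FALSE, TRUE))
})
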