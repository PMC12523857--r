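#' Abundance-weighted centroid
#'
#' The weighted arithmetic mean position
#' `(sum(lon * w) / sum(w), sum(lat * w) / sum(w))` -- the centre of
#' gravity of a species' abundance field, computed in plain degree space.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param w non-negative weights (species proportions or catches); at
#'   least one must be strictly positive.
#' @return named numeric vector `c(lon, lat)`.
#' @examples
#' weighted_centroid(c(150, 152), c(40, 42), c(1, 3))  # (151.5, 41.5)
#' @export
weighted_centroid <- function(lon, lat, w) {
  if (length(lon) != length(lat) || length(lon) != length(w)) {
    stop("'lon', 'lat' and 'w' must have equal length", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  sw <- sum(w)
  if (sw <= 0) stop("undefined centroid: all weights are zero", call. = FALSE)
  c(lon = sum(lon * w) / sw, lat = sum(lat * w) / sw)
}

#' Bootstrap confidence interval for a weighted centroid
#'
#' Resamples whole records (position + weight pairs) with replacement `B`
#' times, recomputes the centroid of each resample, and returns percentile
#' intervals for longitude and latitude.  Degenerate resamples with zero
#' total weight are redrawn (capped retries).
#'
#' @param lon,lat,w as in [weighted_centroid()]; at least 2 points.
#' @param B number of bootstrap resamples.
#' @param level interval coverage.
#' @param seed integer seed.
#' @param max_retries redraw cap for all-zero-weight resamples.
#' @return a list with `lon` and `lat`, each `c(lower, upper)`, plus the
#'   point estimate `centroid`.
#' @export
centroid_bootstrap <- function(lon, lat, w, B = 1000, level = 0.95,
                               seed = NULL, max_retries = 100) {
  n <- length(lon)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  est <- weighted_centroid(lon, lat, w)
  boots <- matrix(NA_real_, B, 2)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    tries <- 0
    while (sum(w[idx]) <= 0 && tries < max_retries) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- tries + 1
    }
    if (sum(w[idx]) <= 0) {
      stop("could not draw a resample with positive total weight",
           call. = FALSE)
    }
    boots[b, ] <- weighted_centroid(lon[idx], lat[idx], w[idx])
  }
  a <- (1 - level) / 2
  list(centroid = est,
       lon = stats::quantile(boots[, 1], c(a, 1 - a), names = FALSE),
       lat = stats::quantile(boots[, 2], c(a, 1 - a), names = FALSE))
}

#' Annual centroid trajectory with bootstrap intervals
#'
#' Computes the abundance-weighted centroid and its bootstrap confidence
#' interval for every year of a record table.
#'
#' @param data data frame with columns `year`, `lon`, `lat` and the
#'   weight column.
#' @param weight name of the weight column (a species proportion, or a
#'   catch-weighted proportion).
#' @param B,level,seed bootstrap settings, see [centroid_bootstrap()].
#' @param min_records years with fewer records are flagged in the output
#'   (`flagged = TRUE`), not dropped.
#' @return a data frame of class `"centroid_series"`: one row per year
#'   with `lon`, `lat`, their CI bounds, `n` and `flagged`.
#' @export
centroid_series <- function(data, weight = "p_blue", B = 1000, level = 0.95,
                            seed = NULL, min_records = 10) {
  stopifnot(all(c("year", "lon", "lat", weight) %in% names(data)))
  if (!is.null(seed)) set.seed(seed)
  years <- sort(unique(data$year))
  rows <- lapply(years, function(y) {
    d <- data[data$year == y, ]
    ci <- centroid_bootstrap(d$lon, d$lat, d[[weight]], B = B, level = level)
    data.frame(year = y, lon = ci$centroid[["lon"]],
               lat = ci$centroid[["lat"]],
               lon_lower = ci$lon[1], lon_upper = ci$lon[2],
               lat_lower = ci$lat[1], lat_upper = ci$lat[2],
               n = nrow(d), flagged = nrow(d) < min_records)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("centroid_series", "data.frame")
  out
}

#' Ordinary least squares trend with residual normality diagnostics
#'
#' Fits `values ~ years` by OLS and reports the slope (degrees per year
#' for centroid series), intercept, R-squared, the two-sided slope
#' p-value, and residual normality diagnostics from [jarque_bera()] and
#' [omnibus_normtest()] (the latter requires at least 8 points).
#'
#' @param years numeric predictor (at least 3 distinct values).
#' @param values numeric response.
#' @return an object of class `"trend_fit"`: a list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `slope_ci` (95%), `residuals`,
#'   `omnibus_p`, `jarque_bera_p` and a `degenerate` flag for constant
#'   responses.
#' @export
ols_trend <- function(years, values) {
  if (length(unique(years)) < 3) {
    stop("need at least 3 distinct years", call. = FALSE)
  }
  if (length(years) != length(values)) stop("size mismatch", call. = FALSE)
  fit <- stats::lm(values ~ years)
  # exact linear inputs are legitimate here; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))
  degenerate <- stats::var(values) == 0
  res <- stats::residuals(fit)
  jb <- if (!degenerate && length(res) >= 4) jarque_bera(res) else
    c(statistic = NA_real_, p_value = NA_real_)
  om <- if (!degenerate && length(res) >= 8) omnibus_normtest(res) else
    c(statistic = NA_real_, p_value = NA_real_)
  ci <- tryCatch(suppressWarnings(stats::confint(fit, "years",
                                                 level = 0.95)),
                 error = function(e) matrix(NA_real_, 1, 2))
  structure(
    list(slope = if (degenerate) 0 else unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = if (degenerate) 0 else sm$r.squared,
         p_value = if (degenerate) NA_real_ else
           sm$coefficients[2, "Pr(>|t|)"],
         slope_ci = c(lower = ci[1, 1], upper = ci[1, 2]),
         residuals = res,
         omnibus_p = unname(om["p_value"]),
         jarque_bera_p = unname(jb["p_value"]),
         degenerate = degenerate, lm = fit),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("OLS trend: slope =", format(x$slope, digits = 4),
      "per year (95% CI", format(x$slope_ci[1], digits = 4), "to",
      format(x$slope_ci[2], digits = 4), ")\n")
  cat("R2 =", format(x$r_squared, digits = 3),
      " slope p =", format(x$p_value, digits = 3), "\n")
  cat("residual normality: Omnibus p =", format(x$omnibus_p, digits = 3),
      " Jarque-Bera p =", format(x$jarque_bera_p, digits = 3), "\n")
  if (x$degenerate) cat("note: constant response (degenerate fit)\n")
  invisible(x)
}

#' Jarque--Bera residual normality test
#'
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with sample skewness `S` and sample
#' kurtosis `K` (moment definitions); the p-value is from a chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param residuals numeric vector, `n >= 4`, non-constant.
#' @return named vector `c(statistic, p_value)`.
#' @export
jarque_bera <- function(residuals) {
  n <- length(residuals)
  if (n < 4) stop("need at least 4 residuals", call. = FALSE)
  m <- residuals - mean(residuals)
  m2 <- mean(m^2)
  if (m2 == 0) stop("zero-variance residuals", call. = FALSE)
  S <- mean(m^3) / m2^1.5
  K <- mean(m^4) / m2^2
  jb <- n / 6 * (S^2 + (K - 3)^2 / 4)
  c(statistic = jb, p_value = stats::pchisq(jb, 2, lower.tail = FALSE))
}

#' D'Agostino--Pearson omnibus normality test
#'
#' Combines the variance-stabilized z-scores of sample skewness
#' (D'Agostino's transform) and sample kurtosis (Anscombe--Glynn
#' transform) into `K^2 = z1^2 + z2^2`, referred to a chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param residuals numeric vector, `n >= 8`, non-constant.
#' @return named vector `c(statistic, p_value)`.
#' @export
omnibus_normtest <- function(residuals) {
  n <- length(residuals)
  if (n < 8) stop("omnibus test requires n >= 8", call. = FALSE)
  m <- residuals - mean(residuals)
  m2 <- mean(m^2)
  if (m2 == 0) stop("zero-variance residuals", call. = FALSE)
  g1 <- mean(m^3) / m2^1.5
  b2 <- mean(m^4) / m2^2

  # skewness z-score (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z-score (Anscombe & Glynn 1983)
  E <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  x <- (b2 - E) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  denom <- 1 + x * sqrt(2 / (A - 4))
  z2 <- (1 - 2 / (9 * A) -
           sign(denom) * (abs((1 - 2 / A) / denom))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  c(statistic = k2, p_value = stats::pchisq(k2, 2, lower.tail = FALSE))
}

#' Inter-centroid distance series and its trend
#'
#' Great-circle (haversine) distance in km between two species' annual
#' centroids for every common year, with an OLS trend; a negative slope
#' indicates distributional convergence.
#'
#' @param series_a,series_b [centroid_series()] data frames.
#' @return a list with `distances` (data frame `year`, `distance_km`) and
#'   `trend` (a [ols_trend()] fit, `NULL` with fewer than 3 common
#'   years).
#' @export
centroid_distance_series <- function(series_a, series_b) {
  common <- intersect(series_a$year, series_b$year)
  if (length(common) == 0) stop("no common years", call. = FALSE)
  a <- series_a[match(common, series_a$year), ]
  b <- series_b[match(common, series_b$year), ]
  d_km <- geosphere::distHaversine(cbind(a$lon, a$lat),
                                   cbind(b$lon, b$lat)) / 1000
  distances <- data.frame(year = common, distance_km = d_km)
  trend <- if (length(common) >= 3 ) ols_trend(common, d_km) else NULL
  list(distances = distances, trend = trend)
}
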