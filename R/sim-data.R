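#' Configuration for the synthetic fishery generator
#'
#' Bundles every setting of the synthetic-data module: the spatial domain,
#' the simulated years and fishing days, grid resolutions, the
#' data-generating ZOIB truth, the annual drift of the population centre,
#' and the target salinity/sea-surface-height correlation.  All randomness
#' derives from `seed` through named substreams, so any generator output
#' can be reproduced independently.
#'
#' @param spatial_domain list with `lon` and `lat` ranges in decimal
#'   degrees (no antimeridian crossing: `max(lon) < 180`).
#' @param years inclusive integer range of simulated years.
#' @param n_records_per_year logbook records (vessel-days) per year.
#' @param n_days_per_year distinct fishing days per year, spread over the
#'   May--November season; the fleet reports in parallel on each day.
#' @param fine_resolution grid spacing in degrees of the physics variables.
#' @param coarse_resolution grid spacing of the chlorophyll field only.
#' @param true_params a [zoib_params()] object: the data-generating truth
#'   of the species-proportion process on standardized covariates
#'   (intercept plus one coefficient per entry of `true_covariates`).
#' @param true_covariates environmental variables driving the latent
#'   proportion process.
#' @param drift_lon_per_year,drift_lat_per_year annual displacement of the
#'   population centre, degrees per year.
#' @param start_center named vector `c(lon=, lat=)`: population centre in
#'   the first year.
#' @param spread named vector `c(lon=, lat=)`: standard deviation of
#'   record positions around the centre, degrees.
#' @param sss_ssh_target_corr target Pearson correlation between the SSS
#'   and SSH fields, in `[-1, 1]`.
#' @param catch_meanlog,catch_sdlog log-normal parameters of the daily
#'   mixed catch in kg.
#' @param catch_env_coef named coefficients adding an environmental signal
#'   (on standardized covariates, log scale) to the catch magnitude, so
#'   catch per set reflects local habitat quality; names must be a subset
#'   of `true_covariates`.
#' @param n_vessels number of distinct vessel labels.
#' @param seed master integer seed.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(spatial_domain = list(lon = c(140, 175),
                                             lat = c(30, 50)),
                       years = 2014:2023,
                       n_records_per_year = 200,
                       n_days_per_year = 12,
                       fine_resolution = 0.083,
                       coarse_resolution = 0.25,
                       true_params = default_true_params(),
                       true_covariates = c("SST", "SSS", "CHLA"),
                       drift_lon_per_year = 0.55,
                       drift_lat_per_year = 0.3,
                       start_center = c(lon = 149, lat = 38.5),
                       spread = c(lon = 2, lat = 1.5),
                       sss_ssh_target_corr = 0.72,
                       catch_meanlog = 9, catch_sdlog = 0.8,
                       catch_env_coef = c(SST = 0.4, CHLA = 0.3),
                       n_vessels = 25, seed = 1) {
  if (fine_resolution <= 0 || coarse_resolution <= 0) {
    stop("resolutions must be positive", call. = FALSE)
  }
  if (length(years) == 0) stop("'years' must be non-empty", call. = FALSE)
  if (diff(spatial_domain$lon) <= 0 || diff(spatial_domain$lat) <= 0) {
    stop("spatial domain box is degenerate", call. = FALSE)
  }
  if (max(spatial_domain$lon) >= 180) {
    stop("domain must not cross the antimeridian (lon max < 180)",
         call. = FALSE)
  }
  if (abs(sss_ssh_target_corr) > 1) {
    stop("'sss_ssh_target_corr' must lie in [-1, 1]", call. = FALSE)
  }
  if (n_records_per_year < 0) {
    stop("'n_records_per_year' must be non-negative", call. = FALSE)
  }
  stopifnot(inherits(true_params, "zoib_params"))
  if (length(true_params$beta_mu) != length(true_covariates) + 1) {
    stop("'true_params' coefficients must have length ",
         length(true_covariates) + 1, " (intercept + true covariates)",
         call. = FALSE)
  }
  structure(
    list(spatial_domain = spatial_domain, years = sort(years),
         n_records_per_year = n_records_per_year,
         n_days_per_year = n_days_per_year,
         fine_resolution = fine_resolution,
         coarse_resolution = coarse_resolution,
         true_params = true_params, true_covariates = true_covariates,
         drift_lon_per_year = drift_lon_per_year,
         drift_lat_per_year = drift_lat_per_year,
         start_center = start_center, spread = spread,
         sss_ssh_target_corr = sss_ssh_target_corr,
         catch_meanlog = catch_meanlog, catch_sdlog = catch_sdlog,
         catch_env_coef = catch_env_coef,
         n_vessels = n_vessels, seed = as.integer(seed)),
    class = "sim_config")
}

#' Default data-generating ZOIB truth
#'
#' Strong covariate control of the species composition, as expected for
#' two species with clearly differentiated thermal and salinity niches:
#' the blue-mackerel share rises with temperature, falls with salinity
#' and rises with chlorophyll, and the environment also modulates the
#' boundary (single-species) probability and its direction.  Boundary
#' days occur at a baseline rate of about 12%, of which about 40% are
#' pure-blue days.  Effect sizes are calibrated so the environmental
#' covariates explain the dominant share of proportion variance,
#' comparable to what such mixed-catch regressions report in practice.
#'
#' @return a [zoib_params()] object.
#' @export
default_true_params <- function() {
  zoib_params(
    beta_mu  = c(stats::qlogis(0.45), 1.5, -1.0, 0.6),
    beta_phi = c(log(20), 0, 0, 0),
    beta_zoi = c(stats::qlogis(0.10), -1.0, 0.6, 0),
    beta_coi = c(stats::qlogis(0.4), 1.8, 0, 0),
    sigma_u = 0.3, prior_scale = 1)
}

# Fixed standardization constants for the generator's covariates; the
# truth is defined on these scales so replicates are comparable.  The
# scales approximate the record-level variability of conditions a fleet
# actually samples (a few degrees of ocean), not the full-domain range,
# so configured effect sizes translate into a realistic explanatory share
# of the proportion process.
sim_cov_center <- c(SST = 20, CHLA = 0.5, SSS = 33.7, SSH = 0.55,
                    UO = 0.05, VO = 0.02, MLD = 40)
sim_cov_scale <- c(SST = 2, CHLA = 0.15, SSS = 0.2, SSH = 0.2,
                   UO = 0.12, VO = 0.1, MLD = 10)

# Named substream seeds derived from the master seed.
sim_substream <- function(config, k) {
  ((config$seed %% 1000003L) * 2017L + as.integer(k)) %% 2147483629L
}

#' Fishing days of a simulation configuration
#'
#' `n_days_per_year` days per year, evenly spread over the May--November
#' fishing season.
#'
#' @param config a [sim_config()].
#' @return vector of `Date`s.
#' @export
sim_dates <- function(config) {
  doys <- unique(round(seq(121, 334, length.out = config$n_days_per_year)))
  as.Date(unlist(lapply(config$years, function(y) {
    format(as.Date(paste0(y, "-01-01")) + doys - 1)
  })))
}

grid_axis <- function(range, res) {
  seq(range[1] + res / 2, range[2], by = res)
}

# Smooth Gaussian surface: white noise on a coarse grid, bilinearly
# interpolated to the target axes.  Consumes the current RNG stream.
smooth_noise <- function(lon_axis, lat_axis, scale_deg = 3, sd = 1) {
  cl <- seq(min(lon_axis) - scale_deg, max(lon_axis) + scale_deg,
            by = scale_deg)
  ca <- seq(min(lat_axis) - scale_deg, max(lat_axis) + scale_deg,
            by = scale_deg)
  Z <- matrix(stats::rnorm(length(cl) * length(ca), sd = sd),
              length(cl), length(ca))
  interp_w <- function(t, c) {
    i <- findInterval(t, c, all.inside = TRUE)
    w <- (t - c[i]) / (c[i + 1] - c[i])
    W <- matrix(0, length(t), length(c))
    W[cbind(seq_along(t), i)] <- 1 - w
    W[cbind(seq_along(t), i + 1)] <- w
    W
  }
  interp_w(lon_axis, cl) %*% Z %*% t(interp_w(lat_axis, ca))
}

# All (or a subset of) daily fields for one date.  Deterministic per
# (config, variable, date): each variable draws its noise under its own
# derived seed.  SSH is built from SSS with in-sample orthogonalization so
# their field-wide Pearson correlation equals the target exactly.
sim_fields_for_date <- function(config, date,
                                variables = c("SST", "CHLA", "SSS", "SSH",
                                              "UO", "VO", "MLD")) {
  date <- as.Date(date)
  doy <- as.integer(format(date, "%j"))
  lon <- grid_axis(config$spatial_domain$lon, config$fine_resolution)
  lat <- grid_axis(config$spatial_domain$lat, config$fine_resolution)
  lon_c <- grid_axis(config$spatial_domain$lon, config$coarse_resolution)
  lat_c <- grid_axis(config$spatial_domain$lat, config$coarse_resolution)
  latg <- function(ax_lon, ax_lat) {
    matrix(rep(ax_lat, each = length(ax_lon)), length(ax_lon))
  }
  var_id <- c(SST = 1L, CHLA = 2L, SSS = 3L, SSH = 4L, UO = 5L, VO = 6L,
              MLD = 7L)
  seed_for <- function(v) {
    sim_substream(config, as.integer(julian(date)) * 11L + var_id[[v]])
  }
  need_sss <- any(c("SSS", "SSH") %in% variables)
  out <- list()

  if ("SST" %in% variables) {
    set.seed(seed_for("SST"))
    v <- 26 - 0.6 * (latg(lon, lat) - 30) +
      3.5 * cos(2 * pi * (doy - 232) / 365.25) +
      smooth_noise(lon, lat, 3, 0.6)
    out$SST <- env_field("SST", date, lon, lat, v)
  }
  if ("CHLA" %in% variables) {
    set.seed(seed_for("CHLA"))
    lg <- log(0.3) + 0.04 * (latg(lon_c, lat_c) - 30) +
      0.3 * cos(2 * pi * (doy - 120) / 365.25) +
      smooth_noise(lon_c, lat_c, 4, 0.35)
    out$CHLA <- env_field("CHLA", date, lon_c, lat_c, exp(lg))
  }
  if (need_sss) {
    set.seed(seed_for("SSS"))
    # no seasonal term: keeps the pooled record-level SSS/SSH correlation
    # at the per-field target instead of diluting it across days
    sss <- 34.2 - 0.05 * (latg(lon, lat) - 30) +
      smooth_noise(lon, lat, 4, 0.25)
    if ("SSS" %in% variables) out$SSS <- env_field("SSS", date, lon, lat, sss)
    if ("SSH" %in% variables) {
      set.seed(seed_for("SSH"))
      # same spatial structure as the SSS anomaly, so subsampled records
      # see (in expectation) the same correlation as the full field
      z <- smooth_noise(lon, lat, 4, 0.25)
      s_std <- (sss - mean(sss)) / stats::sd(sss)
      z_res <- z - mean(z) - s_std * (sum((z - mean(z)) * s_std) /
                                        sum(s_std^2))
      z_std <- z_res / stats::sd(z_res)
      rho <- config$sss_ssh_target_corr
      ssh <- 0.55 + 0.25 * (rho * s_std + sqrt(1 - rho^2) * z_std)
      out$SSH <- env_field("SSH", date, lon, lat, ssh)
    }
  }
  if ("UO" %in% variables) {
    set.seed(seed_for("UO"))
    out$UO <- env_field("UO", date, lon, lat,
                        0.05 + smooth_noise(lon, lat, 3, 0.12))
  }
  if ("VO" %in% variables) {
    set.seed(seed_for("VO"))
    out$VO <- env_field("VO", date, lon, lat,
                        0.02 + smooth_noise(lon, lat, 3, 0.1))
  }
  if ("MLD" %in% variables) {
    set.seed(seed_for("MLD"))
    # moderate seasonal amplitude so MLD is not collinear with the SST
    # cycle at the record level
    v <- pmax(40 + 10 * cos(2 * pi * (doy - 20) / 365.25) +
                0.8 * (latg(lon, lat) - 30) + smooth_noise(lon, lat, 4, 8),
              5)
    out$MLD <- env_field("MLD", date, lon, lat, v)
  }
  out[variables[variables %in% names(out)]]
}

#' Generate daily gridded environmental fields
#'
#' Builds smooth synthetic rasters of SST, chlorophyll (on its own coarser
#' grid), SSS, SSH, current components and mixed-layer depth.  SST carries
#' a latitudinal gradient plus a seasonal cycle plus smooth noise; SSH is
#' a noisy affine function of SSS calibrated so that their field-wide
#' Pearson correlation equals `config$sss_ssh_target_corr`.  Identical
#' `(config, seed)` reproduce bit-identical rasters.
#'
#' @param config a [sim_config()].
#' @param dates dates to generate; defaults to [sim_dates()].
#' @param variables subset of the seven standard variables.
#' @return a list of [env_field()] objects (one per variable per day).
#' @export
generate_env_fields <- function(config, dates = sim_dates(config),
                                variables = c("SST", "CHLA", "SSS", "SSH",
                                              "UO", "VO", "MLD")) {
  stopifnot(inherits(config, "sim_config"))
  dates <- as.Date(dates)
  out <- list()
  for (i in seq_along(dates)) {
    out <- c(out, sim_fields_for_date(config, dates[i], variables))
  }
  out
}

#' Generate synthetic logbook records with latent species proportions
#'
#' Record positions are drawn each year around a population centre that
#' moves by `(drift_lon_per_year, drift_lat_per_year)` annually.  Each
#' record carries a latent true blue-mackerel proportion `p_true` drawn
#' from the ZOIB process of `config$true_params`, evaluated at the
#' environmental covariates of the record's *drift-corrected* position --
#' the habitat field moves with the population, so the abundance-weighted
#' centroid drifts at exactly the configured rate in expectation.  Mixed
#' catch mass is log-normal; haul counts are `1 + Poisson`.
#'
#' @param config a [sim_config()].
#' @param fields optional pre-generated list of [env_field()] covering the
#'   required variables and dates; when omitted, fields are generated on
#'   the fly (identical results either way).
#' @return a data frame of class `"logbook"`: `vessel_id`, `date`, `lon`,
#'   `lat`, `sets`, `mixed_catch_kg`, `year`, and the latent `p_true`.
#' @export
generate_logbook <- function(config, fields = NULL) {
  stopifnot(inherits(config, "sim_config"))
  years <- config$years
  n_per <- config$n_records_per_year
  all_dates <- sim_dates(config)
  if (!is.null(fields)) {
    have <- vapply(fields, function(f) field_key(f$variable, f$date), "")
    names(fields) <- have
    want <- as.vector(outer(config$true_covariates, format(all_dates),
                            function(v, d) paste(v, d)))
    miss <- setdiff(want, have)
    if (length(miss) > 0) {
      stop("fields are missing: ", paste(utils::head(miss, 3), collapse = "; "),
           if (length(miss) > 3) " ..." else "", call. = FALSE)
    }
  }
  empty <- data.frame(vessel_id = character(0), date = as.Date(character(0)),
                      lon = numeric(0), lat = numeric(0),
                      sets = integer(0), mixed_catch_kg = numeric(0),
                      year = integer(0), p_true = numeric(0))
  class(empty) <- c("logbook", "data.frame")
  if (n_per == 0) return(empty)

  # spatial random effect of the truth, on 1-degree blocks in the
  # drift-corrected reference frame
  set.seed(sim_substream(config, 3L))
  dom <- config$spatial_domain
  blk_lon <- seq(floor(dom$lon[1]), ceiling(dom$lon[2]) - 1)
  blk_lat <- seq(floor(dom$lat[1]), ceiling(dom$lat[2]) - 1)
  u_names <- as.vector(outer(blk_lon, blk_lat, function(a, b)
    paste(a, b, sep = "_")))
  u <- stats::rnorm(length(u_names), sd = config$true_params$sigma_u)
  names(u) <- u_names

  # phase 1: all record-level randomness in the logbook substream
  set.seed(sim_substream(config, 2L))
  recs <- do.call(rbind, lapply(seq_along(years), function(iy) {
    y <- years[iy]
    ydates <- all_dates[format(all_dates, "%Y") == as.character(y)]
    ctr_lon <- config$start_center[["lon"]] +
      config$drift_lon_per_year * (iy - 1)
    ctr_lat <- config$start_center[["lat"]] +
      config$drift_lat_per_year * (iy - 1)
    lon <- truncnorm_draw(n_per, ctr_lon, config$spread[["lon"]], dom$lon)
    lat <- truncnorm_draw(n_per, ctr_lat, config$spread[["lat"]], dom$lat)
    data.frame(
      vessel_id = sprintf("V%03d", sample.int(config$n_vessels, n_per,
                                              replace = TRUE)),
      date = sample(ydates, n_per, replace = TRUE),
      lon = lon, lat = lat,
      sets = 1L + stats::rpois(n_per, 1),
      year = y,
      u1 = stats::runif(n_per), u2 = stats::runif(n_per),
      u3 = stats::runif(n_per), u4 = stats::runif(n_per))
  }))

  # phase 2: covariates at the drift-corrected reference position, then a
  # deterministic quantile transform of the pre-drawn uniforms
  iy <- match(recs$year, years)
  ref_lon <- pmin(pmax(recs$lon - config$drift_lon_per_year * (iy - 1),
                       dom$lon[1]), dom$lon[2])
  ref_lat <- pmin(pmax(recs$lat - config$drift_lat_per_year * (iy - 1),
                       dom$lat[1]), dom$lat[2])
  ref <- data.frame(date = recs$date, lon = ref_lon, lat = ref_lat)

  Xs <- matrix(NA_real_, nrow(recs), length(config$true_covariates),
               dimnames = list(NULL, config$true_covariates))
  udates <- sort(unique(recs$date))
  for (i in seq_along(udates)) {
    d <- udates[i]
    rows <- which(recs$date == d)
    fl <- if (is.null(fields)) {
      sim_fields_for_date(config, d, config$true_covariates)
    } else {
      fields[vapply(config$true_covariates, function(v)
        field_key(v, d), "")]
    }
    m <- match_env(ref[rows, , drop = FALSE], fl,
                   variables = config$true_covariates)
    Xs[rows, ] <- as.matrix(m$matched[, tolower(config$true_covariates),
                                      drop = FALSE])
  }
  for (v in config$true_covariates) {
    Xs[, v] <- (Xs[, v] - sim_cov_center[[v]]) / sim_cov_scale[[v]]
  }
  X <- cbind(1, Xs)

  blk <- paste(floor(ref_lon), floor(ref_lat), sep = "_")
  pars <- config$true_params
  pars$u <- u
  lp <- zoib_linpred(pars, X, blk)
  p_true <- ifelse(
    recs$u1 < lp$zoi,
    as.numeric(recs$u2 < lp$coi),
    stats::qbeta(recs$u3, lp$mu * lp$phi, (1 - lp$mu) * lp$phi))

  # catch magnitude tracks local habitat quality (quantile transform of a
  # pre-drawn uniform keeps the draw independent of the evaluation path)
  meanlog <- rep(config$catch_meanlog, nrow(recs))
  for (v in intersect(names(config$catch_env_coef),
                      config$true_covariates)) {
    meanlog <- meanlog + config$catch_env_coef[[v]] * Xs[, v]
  }
  recs$mixed_catch_kg <- stats::qlnorm(recs$u4, meanlog, config$catch_sdlog)

  out <- recs[, c("vessel_id", "date", "lon", "lat", "sets",
                  "mixed_catch_kg", "year")]
  out$p_true <- p_true
  rownames(out) <- NULL
  class(out) <- c("logbook", "data.frame")
  out
}

truncnorm_draw <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < range[1] | x > range[2]
  tries <- 0
  while (any(bad) && tries < 100) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < range[1] | x > range[2]
    tries <- tries + 1
  }
  pmin(pmax(x, range[1]), range[2])
}

#' Generate species-composition sampling events
#'
#' A random subset of logbook records becomes sampling events at which a
#' fixed number of individuals is identified to species.  The blue count
#' is binomial with the record's latent true proportion, so latent
#' boundary states (exact 0/1 days) are preserved as counts `0` or
#' `n_individuals`.
#'
#' @param records a logbook from [generate_logbook()] (needs `p_true`).
#' @param n_individuals individuals identified per event (conventionally
#'   at least 1000).
#' @param subsample_fraction fraction of records sampled, in `(0, 1]`.
#' @param seed integer seed.
#' @return data frame: `date`, `lon`, `lat`, `n_individuals`, `n_blue`,
#'   `n_chub`, `proportion_blue`, plus the parent record's `year` and
#'   latent `p_true`.
#' @export
generate_sampling_events <- function(records, n_individuals = 1000,
                                     subsample_fraction = 0.5, seed = NULL) {
  if (!"p_true" %in% names(records)) {
    stop("'records' must carry the latent 'p_true' column", call. = FALSE)
  }
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("'subsample_fraction' must lie in (0, 1]", call. = FALSE)
  }
  if (n_individuals < 1) stop("'n_individuals' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  m <- max(1L, round(subsample_fraction * n))
  idx <- if (m >= n) seq_len(n) else sort(sample.int(n, m))
  ev <- records[idx, c("date", "lon", "lat", "year", "p_true")]
  ev$n_individuals <- as.integer(n_individuals)
  ev$n_blue <- stats::rbinom(length(idx), n_individuals, records$p_true[idx])
  ev$n_chub <- ev$n_individuals - ev$n_blue
  ev$proportion_blue <- ev$n_blue / ev$n_individuals
  rownames(ev) <- NULL
  ev
}
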