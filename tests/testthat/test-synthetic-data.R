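test_that("configuration invariants are enforced", {
  expect_error(tiny_sim_config(fine_resolution = 0), "resolutions")
  expect_error(tiny_sim_config(years = integer(0)), "years")
  expect_error(tiny_sim_config(
    spatial_domain = list(lon = c(150, 150), lat = c(38, 44))), "degenerate")
  expect_error(tiny_sim_config(
    spatial_domain = list(lon = c(170, 185), lat = c(38, 44))),
    "antimeridian")
  expect_error(tiny_sim_config(sss_ssh_target_corr = 1.2), "\\[-1, 1\\]")
})

test_that("identical config and seed reproduce bit-identical rasters", {
  cfg <- tiny_sim_config()
  d <- sim_dates(cfg)[1:2]
  f1 <- generate_env_fields(cfg, d)
  f2 <- generate_env_fields(cfg, d)
  expect_identical(f1, f2)
  expect_equal(length(f1), 14)  # 7 variables x 2 days
})

test_that("chlorophyll lives on the coarse grid, physics on the fine grid", {
  cfg <- sim_config(seed = 2)
  d <- sim_dates(cfg)[1]
  fl <- generate_env_fields(cfg, d, variables = c("SST", "CHLA"))
  sst <- fl[[which(vapply(fl, function(f) f$variable, "") == "SST")]]
  chla <- fl[[which(vapply(fl, function(f) f$variable, "") == "CHLA")]]
  expect_equal(diff(sst$lon_axis)[1], 0.083, tolerance = 1e-12)
  expect_equal(diff(chla$lon_axis)[1], 0.25, tolerance = 1e-12)
})

test_that("SSS/SSH field-wide correlation hits the configured target", {
  cfg <- tiny_sim_config(fine_resolution = 0.05)  # > 10^4 cells
  fl <- generate_env_fields(cfg, sim_dates(cfg)[1],
                            variables = c("SSS", "SSH"))
  sss <- fl[[1]]$values; ssh <- fl[[2]]$values
  expect_gte(length(sss), 1e4)
  expect_lt(abs(cor(as.vector(sss), as.vector(ssh)) - 0.72), 0.05)

  cfg2 <- tiny_sim_config(fine_resolution = 0.05, sss_ssh_target_corr = 0.3)
  fl2 <- generate_env_fields(cfg2, sim_dates(cfg2)[1],
                             variables = c("SSS", "SSH"))
  expect_lt(abs(cor(as.vector(fl2[[1]]$values),
                    as.vector(fl2[[2]]$values)) - 0.3), 0.05)
})

test_that("SST combines a latitudinal gradient with a seasonal cycle", {
  cfg <- tiny_sim_config()
  dts <- sim_dates(cfg)
  summer <- generate_env_fields(cfg, dts[which.max(format(dts, "%m") == "08")],
                                variables = "SST")[[1]]
  # colder at high latitude
  south <- mean(summer$values[, 1:3])
  north <- mean(summer$values[, ncol(summer$values) - (0:2)])
  expect_gt(south, north)
})

test_that("logbook generation respects the domain, determinism and the
           empty case", {
  cfg <- tiny_sim_config()
  lb1 <- generate_logbook(cfg)
  lb2 <- generate_logbook(cfg)
  expect_identical(lb1, lb2)
  expect_equal(nrow(lb1), 60 * 5)
  expect_true(all(lb1$lon >= 150 & lb1$lon <= 156))
  expect_true(all(lb1$lat >= 38 & lb1$lat <= 44))
  expect_true(all(lb1$sets >= 1))
  expect_true(all(lb1$mixed_catch_kg >= 0))
  expect_true(all(lb1$p_true >= 0 & lb1$p_true <= 1))

  # pre-generated fields give the identical logbook
  fields <- generate_env_fields(cfg)
  expect_identical(generate_logbook(cfg, fields), lb1)

  empty <- generate_logbook(tiny_sim_config(n_records_per_year = 0))
  expect_equal(nrow(empty), 0)
})

test_that("missing covariate fields are reported", {
  cfg <- tiny_sim_config()
  fields <- generate_env_fields(cfg, variables = c("SST", "SSS"))
  expect_error(generate_logbook(cfg, fields), "CHLA")
})

test_that("latent boundary fractions match the generating inflation rates", {
  cfg <- tiny_sim_config(
    n_records_per_year = 500, years = 2014:2017,
    true_params = zoib_params(beta_mu = c(0.2, 0, 0, 0),
                              beta_phi = log(6),
                              beta_zoi = stats::qlogis(0.2),
                              beta_coi = stats::qlogis(0.4),
                              sigma_u = 0.2))
  lb <- generate_logbook(cfg)
  n <- nrow(lb)
  expect_gte(n, 2000)
  p0 <- 0.2 * 0.6; p1 <- 0.2 * 0.4
  expect_lt(abs(mean(lb$p_true == 0) - p0), 3 * sqrt(p0 * (1 - p0) / n))
  expect_lt(abs(mean(lb$p_true == 1) - p1), 3 * sqrt(p1 * (1 - p1) / n))
})

test_that("sampling events preserve boundary states and binomial noise", {
  cfg <- tiny_sim_config()
  lb <- generate_logbook(cfg)
  ev <- generate_sampling_events(lb, n_individuals = 1000,
                                 subsample_fraction = 1, seed = 5)
  expect_equal(nrow(ev), nrow(lb))  # subsample_fraction = 1: one per record
  expect_true(all(ev$n_blue + ev$n_chub == ev$n_individuals))
  expect_equal(ev$proportion_blue, ev$n_blue / 1000)
  ones <- ev$p_true == 1
  if (any(ones)) expect_true(all(ev$n_blue[ones] == 1000))
  zeros <- ev$p_true == 0
  if (any(zeros)) expect_true(all(ev$n_blue[zeros] == 0))

  # binomial standard error at p = 0.5: ~99.7% of draws within 3 SE
  lb2 <- lb[rep(1, 2000), ]
  lb2$p_true <- 0.5
  ev2 <- generate_sampling_events(lb2, n_individuals = 1000,
                                  subsample_fraction = 1, seed = 6)
  inside <- abs(ev2$proportion_blue - 0.5) <= 3 * sqrt(0.25 / 1000)
  expect_gt(mean(inside), 0.985)

  expect_error(generate_sampling_events(lb, subsample_fraction = 0), "0, 1")
  expect_error(generate_sampling_events(lb, n_individuals = 0), ">= 1")
})

test_that("zero drift leaves the abundance-weighted centroid statistically
           stationary", {
  cfg <- tiny_sim_config(n_records_per_year = 150, years = 2014:2021,
                         seed = 11)
  lb <- generate_logbook(cfg)
  cs <- centroid_series(lb, weight = "p_true", B = 200, seed = 1)
  tr <- ols_trend(cs$year, cs$lat)
  expect_true(tr$slope_ci[["lower"]] <= 0 && 0 <= tr$slope_ci[["upper"]])
})

test_that("tables round-trip through their CSV formats", {
  cfg <- tiny_sim_config()
  lb <- generate_logbook(cfg)
  ev <- generate_sampling_events(lb, seed = 2)
  tmp <- tempfile(fileext = ".csv")
  write_logbook(lb, tmp, include_latent = TRUE)
  back <- read_logbook(tmp)
  expect_equal(back$mixed_catch_kg, lb$mixed_catch_kg)
  expect_equal(back$date, lb$date)
  write_sampling_events(ev, tmp, include_latent = TRUE)
  ev2 <- read_sampling_events(tmp)
  expect_equal(ev2$n_blue, ev$n_blue)
  expect_equal(ev2$proportion_blue, ev$proportion_blue)

  fl <- generate_env_fields(cfg, sim_dates(cfg)[1], variables = c("SST"))
  write_env_fields_csv(fl, tmp)
  fl2 <- read_env_fields_csv(tmp)
  expect_equal(fl2[[1]]$values, fl[[1]]$values)
  expect_equal(fl2[[1]]$lon_axis, fl[[1]]$lon_axis)
  unlink(tmp)
})

test_that("environmental fields round-trip through the CF NetCDF adapter", {
  skip_if_not_installed("ncdf4")
  cfg <- tiny_sim_config()
  fl <- generate_env_fields(cfg, sim_dates(cfg)[1:2], variables = "SST")
  tmp <- tempfile(fileext = ".nc")
  write_env_fields_nc(fl, tmp)
  back <- read_env_fields_nc(tmp)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$values, fl[[1]]$values, tolerance = 1e-12)
  expect_equal(back[[2]]$date, fl[[2]]$date)
  expect_equal(back[[1]]$lon_axis, fl[[1]]$lon_axis)
  unlink(tmp)
})
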