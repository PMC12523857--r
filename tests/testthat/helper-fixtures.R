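# Shared fixtures, built in code at test time.

# Simulated ZOIB regression dataset with known truth.
make_zoib_data <- function(n = 1000, seed = 1,
                           params = zoib_params(
                             beta_mu = c(0.2, 0.5, -0.3, 0.2),
                             beta_phi = log(8),
                             beta_zoi = stats::qlogis(0.15),
                             beta_coi = stats::qlogis(0.4)),
                           n_blocks = 0) {
  set.seed(seed)
  p <- length(params$beta_mu) - 1
  d <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(d) <- paste0("x", seq_len(p))
  X <- cbind(1, as.matrix(d))
  block <- NULL
  if (n_blocks > 0) {
    block <- sample(sprintf("B%d", seq_len(n_blocks)), n, replace = TRUE)
    params$u <- stats::setNames(rnorm(n_blocks, 0, params$sigma_u),
                                sprintf("B%d", seq_len(n_blocks)))
    d$blk <- block
  }
  d$y <- zoib_simulate(params, X, block, seed = seed + 1)
  list(data = d, X = X, truth = params, block = block)
}

# Small-domain generator configuration for fast tests.
tiny_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(
    spatial_domain = list(lon = c(150, 156), lat = c(38, 44)),
    years = 2014:2018, n_records_per_year = 60, n_days_per_year = 4,
    fine_resolution = 0.25, coarse_resolution = 0.5,
    start_center = c(lon = 152, lat = 40),
    spread = c(lon = 0.8, lat = 0.8),
    drift_lon_per_year = 0, drift_lat_per_year = 0, seed = 7)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Small environmental field with deterministic values.
toy_field <- function(variable = "SST", date = as.Date("2020-06-01"),
                      lon = seq(150, 152, by = 0.5),
                      lat = seq(40, 41, by = 0.5),
                      fun = function(lo, la) lo + 10 * la) {
  env_field(variable, date, lon, lat, outer(lon, lat, Vectorize(fun)))
}
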