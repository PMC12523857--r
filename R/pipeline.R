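#' Configuration of the end-to-end apportionment pipeline
#'
#' Collects every stage's settings: the synthetic-data configuration (or
#' paths to externally supplied CSV inputs), the collinearity screen, the
#' ZOIB fit, cross-validation, the additive-model stage and the centroid
#' stage.  Defaults mirror the conventional analysis settings: a 0.7
#' correlation threshold, 4 MCMC chains of 4000 iterations with 2000
#' burn-in, 5 CV folds, 1000 bootstrap resamples at the 95% level.
#'
#' @param outdir output directory (created if missing).
#' @param sim a [sim_config()]; its seed is re-derived from `seed`.
#' @param inputs optional list of paths `logbook`, `events`, `env_fields`
#'   replacing the simulate stage.
#' @param collinearity_threshold pairwise `|r|` threshold.
#' @param priority covariate priority order for [correlation_filter()].
#' @param zoib_method `"map"` or `"mcmc"` for the fit stage.
#' @param chains,iter,burn_in,prior_scale ZOIB fit settings.
#' @param block_degrees spatial block size in degrees for the random
#'   effect and block CV.
#' @param cv_k,cv_blocking,run_cv cross-validation settings.
#' @param events_fraction,n_individuals sampling-event generation.
#' @param gam_k,gam_grid additive-model basis dimension and curve grid.
#' @param boot_B,boot_level,min_records,centroid_weighting centroid-stage
#'   settings; weighting is `"proportion"` (per-record species
#'   proportion) or `"catch"` (proportion times catch mass).
#' @param seed master seed recorded in every output's metadata.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir = tempfile("zoibrun"),
                            sim = sim_config(),
                            inputs = NULL,
                            collinearity_threshold = 0.7,
                            priority = NULL,
                            zoib_method = c("map", "mcmc"),
                            chains = 4, iter = 4000, burn_in = 2000,
                            prior_scale = 1, block_degrees = 1,
                            cv_k = 5,
                            cv_blocking = c("spatial_block", "record"),
                            run_cv = FALSE,
                            events_fraction = 0.5, n_individuals = 1000,
                            gam_k = 10, gam_grid = 200,
                            boot_B = 1000, boot_level = 0.95,
                            min_records = 10,
                            centroid_weighting = c("proportion", "catch"),
                            seed = 1) {
  stopifnot(collinearity_threshold > 0, collinearity_threshold <= 1,
            block_degrees > 0, boot_level > 0, boot_level < 1)
  sim$seed <- as.integer(seed)
  structure(
    list(outdir = outdir, sim = sim, inputs = inputs,
         collinearity_threshold = collinearity_threshold,
         priority = priority, zoib_method = match.arg(zoib_method),
         chains = chains, iter = iter, burn_in = burn_in,
         prior_scale = prior_scale, block_degrees = block_degrees,
         cv_k = cv_k, cv_blocking = match.arg(cv_blocking), run_cv = run_cv,
         events_fraction = events_fraction, n_individuals = n_individuals,
         gam_k = gam_k, gam_grid = gam_grid, boot_B = boot_B,
         boot_level = boot_level, min_records = min_records,
         centroid_weighting = match.arg(centroid_weighting),
         seed = as.integer(seed)),
    class = "pipeline_config")
}

spatial_block_of <- function(lon, lat, degrees = 1) {
  paste(floor(lon / degrees), floor(lat / degrees), sep = "_")
}

#' Run the full apportionment pipeline
#'
#' Executes the stages simulate, match, filter, fit, split, gam and
#' centroids in order, writing every artifact as CSV/JSON under
#' `config$outdir`.  A stage is skipped when its outputs exist and the
#' MD5 hashes of its inputs match those recorded in the run manifest, so
#' deleting one intermediate file reruns only the downstream stages.  The
#' run is fully deterministic under a fixed `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list of stages with input/output hashes,
#'   seed, package version and config hash), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out, ...)

  cfg_path <- pth("config.json")
  jsonlite::write_json(config[setdiff(names(config), "sim")],
                       cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)

  manifest_path <- pth("manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else list(stages = list())

  stages <- list(
    list(name = "simulate", inputs = cfg_path,
         outputs = pth(c("logbook.csv", "events.csv", "env_fields.csv"))),
    list(name = "match",
         inputs = pth(c("config.json", "logbook.csv", "events.csv",
                        "env_fields.csv")),
         outputs = pth(c("matched_logbook.csv", "matched_events.csv"))),
    list(name = "filter",
         inputs = pth(c("config.json", "matched_events.csv")),
         outputs = pth(c("correlations.csv", "retained_vars.json"))),
    list(name = "fit",
         inputs = pth(c("config.json", "matched_events.csv",
                        "matched_logbook.csv", "retained_vars.json")),
         outputs = pth(c("zoib_fit.json", "predicted_p.csv"))),
    list(name = "split",
         inputs = pth(c("config.json", "matched_logbook.csv",
                        "predicted_p.csv")),
         outputs = pth("split_catch.csv")),
    list(name = "gam",
         inputs = pth(c("config.json", "split_catch.csv",
                        "retained_vars.json")),
         outputs = pth(c("gam_summary.csv", "partial_effects.csv"))),
    list(name = "centroids",
         inputs = pth(c("config.json", "split_catch.csv")),
         outputs = pth(c("centroids.csv", "trends.csv",
                         "centroid_distance.csv"))))

  runner <- list(simulate = stage_simulate, match = stage_match,
                 filter = stage_filter, fit = stage_fit,
                 split = stage_split, gam = stage_gam,
                 centroids = stage_centroids)

  manifest <- list(package_version = as.character(
                     utils::packageVersion("zoibcatch")),
                   seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   stages = list())
  for (st in stages) {
    in_hash <- unname(tools::md5sum(st$inputs))
    rec <- NULL
    for (s in old_manifest$stages) if (identical(s$name, st$name)) rec <- s
    up_to_date <- all(file.exists(st$outputs)) && !is.null(rec) &&
      identical(unlist(rec$input_md5), unname(in_hash)) &&
      !anyNA(in_hash)
    if (!up_to_date) {
      res <- tryCatch(runner[[st$name]](config, out),
                      error = function(e) e)
      if (inherits(res, "error")) {
        manifest$stages <- c(manifest$stages, list(list(
          name = st$name, status = "failed",
          message = conditionMessage(res))))
        jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                             digits = NA)
        stop("pipeline stage '", st$name, "' failed: ",
             conditionMessage(res), call. = FALSE)
      }
    }
    manifest$stages <- c(manifest$stages, list(list(
      name = st$name,
      status = if (up_to_date) "skipped" else "ran",
      inputs = st$inputs, input_md5 = unname(tools::md5sum(st$inputs)),
      outputs = st$outputs, output_md5 = unname(tools::md5sum(st$outputs)))))
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

stage_simulate <- function(config, out) {
  if (!is.null(config$inputs)) {
    file.copy(config$inputs$logbook, file.path(out, "logbook.csv"),
              overwrite = TRUE)
    file.copy(config$inputs$events, file.path(out, "events.csv"),
              overwrite = TRUE)
    file.copy(config$inputs$env_fields, file.path(out, "env_fields.csv"),
              overwrite = TRUE)
    return(invisible())
  }
  fields <- generate_env_fields(config$sim)
  lb <- generate_logbook(config$sim, fields)
  ev <- generate_sampling_events(lb, n_individuals = config$n_individuals,
                                 subsample_fraction = config$events_fraction,
                                 seed = config$seed + 101L)
  write_logbook(lb, file.path(out, "logbook.csv"), include_latent = TRUE)
  write_sampling_events(ev, file.path(out, "events.csv"),
                        include_latent = TRUE)
  write_env_fields_csv(fields, file.path(out, "env_fields.csv"))
  invisible()
}

stage_match <- function(config, out) {
  fields <- read_env_fields_csv(file.path(out, "env_fields.csv"))
  # align the coarse chlorophyll grid with the physics grid first
  fine <- NULL
  for (f in fields) if (f$variable != "CHLA") { fine <- f; break }
  if (!is.null(fine)) {
    for (i in seq_along(fields)) {
      if (fields[[i]]$variable == "CHLA") {
        fields[[i]] <- regrid(fields[[i]], fine$lon_axis, fine$lat_axis)
      }
    }
  }
  lb <- read_logbook(file.path(out, "logbook.csv"))
  ev <- read_sampling_events(file.path(out, "events.csv"))
  mlb <- match_env(lb, fields)
  mev <- match_env(ev, fields)
  message("match: dropped ", mlb$n_dropped, " logbook and ",
          mev$n_dropped, " event records with missing covariates")
  utils::write.csv(mlb$matched, file.path(out, "matched_logbook.csv"),
                   row.names = FALSE)
  utils::write.csv(mev$matched, file.path(out, "matched_events.csv"),
                   row.names = FALSE)
  invisible()
}

stage_filter <- function(config, out) {
  mev <- utils::read.csv(file.path(out, "matched_events.csv"))
  cand <- intersect(tolower(names(env_units)), names(mev))
  flt <- correlation_filter(mev, cand,
                            threshold = config$collinearity_threshold,
                            priority = config$priority)
  message("filter: removed ", length(flt$dropped), " variable(s): ",
          paste(flt$dropped, collapse = ", "))
  utils::write.csv(as.data.frame(flt$correlations),
                   file.path(out, "correlations.csv"))
  jsonlite::write_json(list(retained = flt$retained,
                            dropped = flt$dropped),
                       file.path(out, "retained_vars.json"))
  invisible()
}

stage_fit <- function(config, out) {
  mev <- utils::read.csv(file.path(out, "matched_events.csv"))
  mlb <- utils::read.csv(file.path(out, "matched_logbook.csv"))
  retained <- unlist(jsonlite::read_json(
    file.path(out, "retained_vars.json"))$retained)
  mev$proportion_blue <- mev$n_blue / mev$n_individuals
  mev$block <- spatial_block_of(mev$lon, mev$lat, config$block_degrees)
  form <- stats::as.formula(paste("proportion_blue ~",
                                  paste(retained, collapse = " + ")))
  fit <- zoib(form, mev, block = "block",
              prior_scale = config$prior_scale,
              method = config$zoib_method, chains = config$chains,
              iter = config$iter, burn_in = config$burn_in,
              seed = config$seed + 202L)
  report <- list(seed = config$seed, method = config$zoib_method,
                 n = fit$dat$n, coefficients = as.list(coef(fit)),
                 sigma_u = fit$coefficients$sigma_u)
  if (!is.null(fit$rhat)) {
    report$rhat <- as.list(fit$rhat[is.finite(fit$rhat)])
    report$max_rhat <- max(fit$rhat, na.rm = TRUE)
  }
  if (!is.null(fit$draws)) {
    post <- posterior_matrix(fit$draws)
    long <- data.frame(
      chain = rep(rep(seq_len(dim(fit$draws$draws)[1]),
                      each = dim(fit$draws$draws)[2] - fit$draws$burn_in),
                  times = ncol(post)),
      parameter = rep(colnames(post), each = nrow(post)),
      value = as.vector(post))
    utils::write.csv(long, file.path(out, "draws.csv"), row.names = FALSE)
  }
  if (config$run_cv) {
    cv <- kfold_cv(fit, k = config$cv_k, blocking = config$cv_blocking,
                   seed = config$seed + 303L)
    report$cv <- list(per_fold = cv$per_fold, mean = as.list(cv$mean))
  }
  jsonlite::write_json(report, file.path(out, "zoib_fit.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  mlb$block <- spatial_block_of(mlb$lon, mlb$lat, config$block_degrees)
  p <- predict(fit, newdata = mlb, block = "block")
  utils::write.csv(data.frame(p_blue = p),
                   file.path(out, "predicted_p.csv"), row.names = FALSE)
  invisible()
}

stage_split <- function(config, out) {
  mlb <- utils::read.csv(file.path(out, "matched_logbook.csv"))
  p <- utils::read.csv(file.path(out, "predicted_p.csv"))$p_blue
  sp <- split_catch(mlb, p)
  utils::write.csv(sp, file.path(out, "split_catch.csv"), row.names = FALSE)
  invisible()
}

stage_gam <- function(config, out) {
  sp <- utils::read.csv(file.path(out, "split_catch.csv"))
  retained <- unlist(jsonlite::read_json(
    file.path(out, "retained_vars.json"))$retained)
  curves <- list(); tabs <- list()
  for (species in c("blue", "chub")) {
    y <- log1p_catch(sp[[paste0(species, "_per_set")]])
    fit <- fit_additive(y, sp[retained], k = config$gam_k)
    tab <- summary(fit)$table
    tab <- cbind(species = species, tab,
                 deviance_explained = fit$deviance_explained,
                 r_squared = fit$r_squared)
    tabs[[species]] <- tab
    for (v in retained) {
      pe <- partial_effect(fit, v, grid = seq(
        fit$terms[[v]]$basis$range[1], fit$terms[[v]]$basis$range[2],
        length.out = config$gam_grid))
      opt <- optimal_range(pe)
      curves[[paste(species, v)]] <- cbind(species = species, variable = v,
                                           pe,
                                           opt_lo = opt$range[1],
                                           opt_hi = opt$range[2])
    }
  }
  utils::write.csv(do.call(rbind, tabs), file.path(out, "gam_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, curves),
                   file.path(out, "partial_effects.csv"), row.names = FALSE)
  invisible()
}

stage_centroids <- function(config, out) {
  sp <- utils::read.csv(file.path(out, "split_catch.csv"))
  if (!"year" %in% names(sp)) sp$year <- as.integer(format(as.Date(sp$date),
                                                           "%Y"))
  weights <- list(
    blue = if (config$centroid_weighting == "catch")
      sp$p_blue * sp$mixed_catch_kg else sp$p_blue,
    chub = if (config$centroid_weighting == "catch")
      (1 - sp$p_blue) * sp$mixed_catch_kg else 1 - sp$p_blue)
  series <- list(); trends <- list()
  for (species in c("blue", "chub")) {
    d <- data.frame(year = sp$year, lon = sp$lon, lat = sp$lat,
                    w = weights[[species]])
    cs <- centroid_series(d, weight = "w", B = config$boot_B,
                          level = config$boot_level,
                          seed = config$seed + 404L,
                          min_records = config$min_records)
    series[[species]] <- cbind(species = species, cs)
    for (axis in c("lat", "lon")) {
      tr <- ols_trend(cs$year, cs[[axis]])
      trends[[paste(species, axis)]] <- data.frame(
        species = species, axis = axis, slope = tr$slope,
        intercept = tr$intercept, r_squared = tr$r_squared,
        p_value = tr$p_value, slope_lower = tr$slope_ci[["lower"]],
        slope_upper = tr$slope_ci[["upper"]],
        omnibus_p = tr$omnibus_p, jarque_bera_p = tr$jarque_bera_p)
    }
  }
  utils::write.csv(do.call(rbind, series), file.path(out, "centroids.csv"),
                   row.names = FALSE)
  dist <- centroid_distance_series(series$blue, series$chub)
  if (!is.null(dist$trend)) {
    trends[["distance"]] <- data.frame(
      species = "both", axis = "distance_km", slope = dist$trend$slope,
      intercept = dist$trend$intercept,
      r_squared = dist$trend$r_squared, p_value = dist$trend$p_value,
      slope_lower = dist$trend$slope_ci[["lower"]],
      slope_upper = dist$trend$slope_ci[["upper"]],
      omnibus_p = dist$trend$omnibus_p,
      jarque_bera_p = dist$trend$jarque_bera_p)
  }
  utils::write.csv(do.call(rbind, trends), file.path(out, "trends.csv"),
                   row.names = FALSE)
  utils::write.csv(dist$distances, file.path(out, "centroid_distance.csv"),
                   row.names = FALSE)
  invisible()
}

#' Validate pipeline input files
#'
#' Checks the schemas and value ranges of logbook, sampling-event and
#' environmental-field CSVs: required columns, non-negative catches, haul
#' counts of at least one, coordinates within plausible ranges, species
#' counts that sum to the sample size, the seven-variable environmental
#' roster, and date coverage of the records by the fields.
#'
#' @param paths named list with any of `logbook`, `events`, `env_fields`.
#' @return a data frame of findings (`file`, `location`, `message`);
#'   zero rows means all checks passed.
#' @export
validate_inputs <- function(paths) {
  findings <- list()
  note <- function(file, location, message) {
    findings[[length(findings) + 1]] <<- data.frame(
      file = file, location = location, message = message)
  }
  lb <- NULL; fields_df <- NULL
  if (!is.null(paths$logbook)) {
    if (!file.exists(paths$logbook)) {
      stop("cannot read '", paths$logbook, "'", call. = FALSE)
    }
    lb <- utils::read.csv(paths$logbook)
    need <- c("vessel_id", "date", "lon", "lat", "sets", "mixed_catch_kg")
    miss <- setdiff(need, names(lb))
    if (length(miss)) {
      note("logbook", "header", paste("missing column(s):",
                                      paste(miss, collapse = ", ")))
    } else {
      bad <- which(lb$mixed_catch_kg < 0)
      for (r in bad) note("logbook", paste0("row ", r, ", mixed_catch_kg"),
                          "negative catch")
      bad <- which(lb$sets < 1)
      for (r in bad) note("logbook", paste0("row ", r, ", sets"),
                          "haul count below 1")
      if (any(lb$lat < -90 | lb$lat > 90)) {
        note("logbook", "lat", "latitude outside [-90, 90]")
      }
      if (any(lb$lon < -180 | lb$lon > 360)) {
        note("logbook", "lon", "longitude outside [-180, 360]")
      }
    }
  }
  if (!is.null(paths$events)) {
    if (!file.exists(paths$events)) {
      stop("cannot read '", paths$events, "'", call. = FALSE)
    }
    ev <- utils::read.csv(paths$events)
    need <- c("date", "lon", "lat", "n_individuals", "n_blue", "n_chub")
    miss <- setdiff(need, names(ev))
    if (length(miss)) {
      note("events", "header", paste("missing column(s):",
                                     paste(miss, collapse = ", ")))
    } else {
      bad <- which(ev$n_blue + ev$n_chub != ev$n_individuals)
      for (r in bad) note("events", paste0("row ", r),
                          "species counts do not sum to n_individuals")
    }
  }
  if (!is.null(paths$env_fields)) {
    if (!file.exists(paths$env_fields)) {
      stop("cannot read '", paths$env_fields, "'", call. = FALSE)
    }
    fields_df <- utils::read.csv(paths$env_fields)
    have <- unique(toupper(fields_df$variable))
    miss <- setdiff(names(env_units), have)
    for (v in miss) note("env_fields", "roster",
                         paste("missing variable:", v))
    if (!is.null(lb) && "date" %in% names(lb)) {
      uncovered <- setdiff(unique(as.character(lb$date)),
                           unique(as.character(fields_df$date)))
      for (d in uncovered) note("env_fields", "dates",
                                paste("no fields for record date", d))
    }
  }
  if (length(findings) == 0) {
    return(data.frame(file = character(0), location = character(0),
                      message = character(0)))
  }
  do.call(rbind, findings)
}
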