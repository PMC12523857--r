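# Plain-text serialization of the pipeline's tables and rasters.

env_units <- c(SST = "degC", CHLA = "mg m-3", SSS = "1e-3", SSH = "m",
               UO = "m s-1", VO = "m s-1", MLD = "m")

#' Write and read logbook / sampling-event tables
#'
#' Logbooks are written with columns `vessel_id, date, lon, lat, sets,
#' mixed_catch_kg` (ISO-8601 dates); sampling events with `date, lon,
#' lat, n_individuals, n_blue, n_chub`.  Latent ground-truth columns from
#' the generator (`p_true`, `year`, `proportion_blue`) are kept only when
#' `include_latent = TRUE`.
#'
#' @param x data frame to write.
#' @param path file path.
#' @param include_latent keep generator ground-truth columns?
#' @return `path`, invisibly (writers); a data frame (readers).
#' @export
write_logbook <- function(x, path, include_latent = FALSE) {
  cols <- c("vessel_id", "date", "lon", "lat", "sets", "mixed_catch_kg")
  if (include_latent) cols <- c(cols, intersect(c("year", "p_true"), names(x)))
  utils::write.csv(x[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_logbook
#' @export
read_logbook <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  if (!"year" %in% names(x)) x$year <- as.integer(format(x$date, "%Y"))
  class(x) <- c("logbook", "data.frame")
  x
}

#' @rdname write_logbook
#' @export
write_sampling_events <- function(x, path, include_latent = FALSE) {
  cols <- c("date", "lon", "lat", "n_individuals", "n_blue", "n_chub")
  if (include_latent) {
    cols <- c(cols, intersect(c("year", "p_true", "proportion_blue"),
                              names(x)))
  }
  utils::write.csv(x[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_logbook
#' @export
read_sampling_events <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$date <- as.Date(x$date)
  if (!"proportion_blue" %in% names(x)) {
    x$proportion_blue <- x$n_blue / x$n_individuals
  }
  if (!"year" %in% names(x)) x$year <- as.integer(format(x$date, "%Y"))
  x
}

#' Write and read environmental fields as long-format CSV
#'
#' One row per cell: `variable, date, lon, lat, value`.  Suited to the
#' small grids used in tests and examples; large rasters are better kept
#' in memory or in NetCDF (see [write_env_fields_nc()]).
#'
#' @param fields list of [env_field()] objects.
#' @param path CSV path.
#' @return `path` invisibly (writer); a list of [env_field()] (reader).
#' @export
write_env_fields_csv <- function(fields, path) {
  rows <- lapply(fields, function(f) {
    data.frame(variable = f$variable, date = format(f$date),
               lon = rep(f$lon_axis, times = length(f$lat_axis)),
               lat = rep(f$lat_axis, each = length(f$lon_axis)),
               value = as.vector(f$values))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_fields_csv
#' @export
read_env_fields_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(x$variable, x$date))) {
    d <- x[paste(x$variable, x$date) == key, ]
    lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
    v <- matrix(NA_real_, length(lon), length(lat))
    v[cbind(match(d$lon, lon), match(d$lat, lat))] <- d$value
    out[[key]] <- env_field(d$variable[1], as.Date(d$date[1]), lon, lat, v)
  }
  out
}

#' Optional CF NetCDF adapter for environmental fields
#'
#' Writes one variable's dated fields to a CF-convention NetCDF file with
#' dimensions `(time, lat, lon)`, or reads such a file back into
#' [env_field()] objects.  Requires the suggested `ncdf4` package.
#'
#' @param fields list of [env_field()] objects of a single variable.
#' @param path NetCDF file path.
#' @param variable variable name to read (defaults to the file's first
#'   non-coordinate variable).
#' @return `path` invisibly (writer); a list of [env_field()] (reader).
#' @export
write_env_fields_nc <- function(fields, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("the NetCDF adapter requires the 'ncdf4' package", call. = FALSE)
  }
  vars <- unique(vapply(fields, function(f) f$variable, ""))
  if (length(vars) != 1) {
    stop("write one variable per NetCDF file", call. = FALSE)
  }
  dates <- as.Date(vapply(fields, function(f) format(f$date), ""))
  f1 <- fields[[1]]
  dim_t <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                            as.numeric(dates), calendar = "standard")
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", f1$lat_axis)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", f1$lon_axis)
  nv <- ncdf4::ncvar_def(vars, env_units[[vars]] %||% "",
                         list(dim_lon, dim_lat, dim_t), missval = NA,
                         prec = "double")
  nc <- ncdf4::nc_create(path, nv)
  on.exit(ncdf4::nc_close(nc))
  for (i in seq_along(fields)) {
    ncdf4::ncvar_put(nc, nv, fields[[i]]$values,
                     start = c(1, 1, i),
                     count = c(length(f1$lon_axis), length(f1$lat_axis), 1))
  }
  invisible(path)
}

#' @rdname write_env_fields_nc
#' @export
read_env_fields_nc <- function(path, variable = NULL) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("the NetCDF adapter requires the 'ncdf4' package", call. = FALSE)
  }
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(variable)) variable <- names(nc$var)[1]
  lon <- ncdf4::ncvar_get(nc, "lon")
  lat <- ncdf4::ncvar_get(nc, "lat")
  times <- as.Date(ncdf4::ncvar_get(nc, "time"), origin = "1970-01-01")
  arr <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  lapply(seq_along(times), function(i) {
    env_field(variable, times[i], lon, lat, arr[, , i])
  })
}
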