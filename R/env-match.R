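#' Gridded environmental field
#'
#' One dated raster of a single environmental variable on a regular
#' longitude/latitude grid.  Coordinates are cell centres in decimal
#' degrees; `values` is indexed `[lon, lat]`.
#'
#' @param variable variable name, one of `"SST"` (deg C), `"CHLA"`
#'   (mg/m^3), `"SSS"` (permil), `"SSH"` (m), `"UO"` (m/s), `"VO"` (m/s),
#'   `"MLD"` (m) -- other names are allowed but the standard roster is
#'   validated by [validate_inputs()].
#' @param date a `Date` (daily fields).
#' @param lon_axis,lat_axis strictly increasing cell-centre coordinates.
#' @param values numeric matrix, `dim = c(length(lon_axis),
#'   length(lat_axis))`; `NA` marks missing cells.
#' @return an object of class `"env_field"`.
#' @export
env_field <- function(variable, date, lon_axis, lat_axis, values) {
  lon_axis <- as.numeric(lon_axis); lat_axis <- as.numeric(lat_axis)
  if (length(lon_axis) == 0 || length(lat_axis) == 0) {
    stop("empty coordinate axis", call. = FALSE)
  }
  if (any(diff(lon_axis) <= 0) || any(diff(lat_axis) <= 0)) {
    stop("coordinate axes must be strictly increasing", call. = FALSE)
  }
  values <- as.matrix(values)
  if (!identical(dim(values), c(length(lon_axis), length(lat_axis)))) {
    stop("'values' must have dim (n_lon, n_lat)", call. = FALSE)
  }
  structure(list(variable = variable, date = as.Date(date),
                 lon_axis = lon_axis, lat_axis = lat_axis, values = values),
            class = "env_field")
}

#' @export
print.env_field <- function(x, ...) {
  cat("env_field:", x$variable, "on", format(x$date), "--",
      length(x$lon_axis), "x", length(x$lat_axis), "cells, lon [",
      min(x$lon_axis), ",", max(x$lon_axis), "], lat [",
      min(x$lat_axis), ",", max(x$lat_axis), "]\n")
  invisible(x)
}

# Index of the nearest cell centre for each target coordinate, ties broken
# toward the lower index.
nearest_index <- function(targets, centres) {
  if (length(centres) == 1) return(rep(1L, length(targets)))
  i <- findInterval(targets, centres, all.inside = TRUE)
  d_lo <- abs(targets - centres[i])
  d_hi <- abs(targets - centres[pmin(i + 1, length(centres))])
  ifelse(d_hi < d_lo, pmin(i + 1, length(centres)), i)
}

#' Regrid an environmental field by nearest neighbour
#'
#' Each target cell takes the value of the nearest source cell centre
#' (Euclidean distance in degrees, axes handled independently on a regular
#' grid); ties go to the lower index.  Missing source values propagate.
#'
#' @param field an [env_field()].
#' @param target_lon_axis,target_lat_axis strictly increasing target axes.
#' @param method only `"nearest"` is supported.
#' @return a new [env_field()] on the target axes.
#' @export
regrid <- function(field, target_lon_axis, target_lat_axis,
                   method = "nearest") {
  stopifnot(inherits(field, "env_field"))
  method <- match.arg(method, "nearest")
  if (any(diff(target_lon_axis) <= 0) || any(diff(target_lat_axis) <= 0)) {
    stop("target axes must be strictly increasing", call. = FALSE)
  }
  ilon <- nearest_index(target_lon_axis, field$lon_axis)
  ilat <- nearest_index(target_lat_axis, field$lat_axis)
  env_field(field$variable, field$date, target_lon_axis, target_lat_axis,
            field$values[ilon, ilat, drop = FALSE])
}

# Lookup key for one dated field.
field_key <- function(variable, date) paste(variable, format(as.Date(date)))

#' Join records to same-day environmental values
#'
#' Matches each georeferenced record to the value of every environmental
#' field of the same calendar day at the nearest cell centre (degree-space
#' distance; ties broken toward the lower latitude index, then the lower
#' longitude index).  Records whose nearest cell is missing for any
#' variable are dropped and counted.
#'
#' @param records data frame with columns `date`, `lon`, `lat`.
#' @param fields list of [env_field()] objects covering every record date
#'   for every variable.
#' @param variables variables to extract; defaults to all variables present
#'   in `fields`.
#' @return a list with `matched` (the records plus one lower-case column
#'   per variable) and `n_dropped` (records removed for missing
#'   covariates).
#' @export
match_env <- function(records, fields, variables = NULL) {
  stopifnot(is.data.frame(records))
  if (!all(c("date", "lon", "lat") %in% names(records))) {
    stop("'records' needs columns date, lon, lat", call. = FALSE)
  }
  vars_avail <- unique(vapply(fields, function(f) f$variable, ""))
  if (is.null(variables)) variables <- vars_avail
  keys <- vapply(fields, function(f) field_key(f$variable, f$date), "")
  names(fields) <- keys

  dates <- as.Date(records$date)
  out <- records
  for (v in variables) {
    out[[tolower(v)]] <- NA_real_
  }
  for (d in unique(format(dates))) {
    rows <- which(format(dates) == d)
    for (v in variables) {
      f <- fields[[field_key(v, d)]]
      if (is.null(f)) {
        stop("no ", v, " field for date ", d, call. = FALSE)
      }
      # tie rule: lower lat index first, then lower lon index
      ilat <- nearest_index(records$lat[rows], f$lat_axis)
      ilon <- nearest_index(records$lon[rows], f$lon_axis)
      out[rows, tolower(v)] <- f$values[cbind(ilon, ilat)]
    }
  }
  cov_cols <- tolower(variables)
  complete <- stats::complete.cases(out[, cov_cols, drop = FALSE])
  list(matched = out[complete, , drop = FALSE],
       n_dropped = sum(!complete))
}

#' Iterative pairwise collinearity filter
#'
#' Computes the Pearson correlation matrix of the candidate covariates
#' and, while any pair has `|r| >= threshold`, removes the lower-priority
#' member of the worst-offending pair.  All retained pairs end up with
#' `|r| < threshold`.  The conventional threshold in habitat-model
#' covariate screening is 0.7.
#'
#' @param data data frame containing the candidate columns.
#' @param candidate_vars column names to screen.
#' @param threshold correlation magnitude at or above which a pair is
#'   considered collinear.
#' @param priority character vector ordering all candidates from most to
#'   least ecologically important; the later member of a collinear pair is
#'   dropped.  Default order: SST, CHLA, SSS, MLD, UO, VO, SSH (matched
#'   case-insensitively against `candidate_vars`).
#' @return a list with `retained`, `dropped` and the full correlation
#'   matrix `correlations`.
#' @export
correlation_filter <- function(data, candidate_vars,
                               threshold = 0.7, priority = NULL) {
  if (is.null(priority)) {
    default <- c("SST", "CHLA", "SSS", "MLD", "UO", "VO", "SSH")
    priority <- candidate_vars[order(match(toupper(candidate_vars), default))]
  }
  if (!all(candidate_vars %in% names(data))) {
    stop("candidate variables missing from 'data'", call. = FALSE)
  }
  if (!all(candidate_vars %in% priority)) {
    stop("'priority' must cover all candidate variables", call. = FALSE)
  }
  M <- as.matrix(data[, candidate_vars, drop = FALSE])
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) < 2) stop("need at least 2 complete-case rows", call. = FALSE)

  const <- apply(M, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("constant column(s) ", paste(candidate_vars[const], collapse = ", "),
            "; their correlations are treated as 0", call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(M))
  R[!is.finite(R)] <- 0
  diag(R) <- 1

  retained <- candidate_vars
  dropped <- character(0)
  rank_of <- function(v) match(v, priority)
  repeat {
    sub <- abs(R[retained, retained, drop = FALSE])
    diag(sub) <- 0
    worst <- max(sub)
    if (worst < threshold || length(retained) < 2) break
    ij <- which(sub == worst, arr.ind = TRUE)[1, ]
    pair <- retained[ij]
    loser <- pair[which.max(rank_of(pair))]
    dropped <- c(dropped, loser)
    retained <- setdiff(retained, loser)
  }
  list(retained = retained, dropped = dropped, correlations = R)
}
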