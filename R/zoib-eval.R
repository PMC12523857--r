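#' Prediction accuracy metrics
#'
#' Root mean square error, mean absolute error and coefficient of
#' determination: `RMSE = sqrt(mean((y - yhat)^2))`,
#' `MAE = mean(|y - yhat|)`,
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.  `R2` can be
#' negative for predictors worse than the mean, and is `NA` (with a
#' `degenerate` attribute) when `y` is constant.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return named numeric vector `c(rmse, mae, r2)`.
#' @examples
#' fit_metrics(c(0, 1), c(1, 0))   # rmse 1, mae 1, r2 -3
#' @export
fit_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop("'y' and 'yhat' must have equal length", call. = FALSE)
  }
  if (length(y) == 0) stop("empty input", call. = FALSE)
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  out <- c(rmse = sqrt(rss / length(y)),
           mae = mean(abs(y - yhat)),
           r2 = if (tss > 0) 1 - rss / tss else NA_real_)
  if (tss == 0) attr(out, "degenerate") <- "constant observed values"
  out
}

#' K-fold cross-validation of a ZOIB regression
#'
#' Partitions the data into `k` folds -- either by row
#' (`blocking = "record"`) or by spatial block
#' (`blocking = "spatial_block"`, the default, so that entire blocks are
#' held out together) -- refits the model on each training set and scores
#' predicted expected proportions on the held-out fold with
#' [fit_metrics()].  Refits use the fast MAP estimator by default; set
#' `method = "mcmc"` for full posterior refits.
#'
#' @param object a fitted [zoib()] model (its data and settings are
#'   reused).
#' @param k number of folds.
#' @param blocking fold assignment unit.
#' @param seed integer seed for the fold assignment.
#' @param method refit method, `"map"` or `"mcmc"`.
#' @param ... passed to the refits (e.g. `chains`, `iter`).
#' @return an object of class `"zoib_cv"`: per-fold metrics, their means,
#'   and the fold assignment.
#' @export
kfold_cv <- function(object, k = 5, blocking = c("spatial_block", "record"),
                     seed = NULL, method = c("map", "mcmc"), ...) {
  stopifnot(inherits(object, "zoib"))
  blocking <- match.arg(blocking)
  method <- match.arg(method)
  if (k < 2) stop("'k' must be at least 2", call. = FALSE)
  n <- object$dat$n
  if (!is.null(seed)) set.seed(seed)

  if (blocking == "spatial_block") {
    if (object$dat$B == 0) {
      stop("spatial_block CV requires a model fitted with a 'block'",
           call. = FALSE)
    }
    lev <- object$dat$block_levels
    bfold <- sample(rep_len(seq_len(k), length(lev)))
    fold <- bfold[object$dat$block]
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  sizes <- tabulate(fold, k)
  if (any(sizes < 2)) stop("a fold has fewer than 2 rows", call. = FALSE)

  per_fold <- matrix(NA_real_, k, 3, dimnames = list(NULL, c("rmse", "mae", "r2")))
  for (f in seq_len(k)) {
    test <- fold == f
    dtr <- zoib_prepare(object$y[!test],
                        object$X[!test, , drop = FALSE],
                        if (!is.null(object$block)) object$block[!test])
    refit <- if (method == "map") {
      zoib_fit_map(dtr, object$prior_scale)
    } else {
      m <- zoib_fit_map(dtr, object$prior_scale)
      dr <- zoib_fit_mcmc(dtr, m, object$prior_scale,
                          seed = if (is.null(seed)) NULL else seed + f, ...)
      m$theta <- colMeans(posterior_matrix(dr))
      m
    }
    pars <- theta_to_params(refit$theta, dtr, object$prior_scale)
    lp <- zoib_linpred(pars, object$X[test, , drop = FALSE],
                       if (!is.null(object$block)) object$block[test])
    yhat <- zoib_mean(lp$mu, lp$zoi, lp$coi)
    per_fold[f, ] <- fit_metrics(object$y[test], yhat)
  }
  structure(list(per_fold = as.data.frame(cbind(fold = seq_len(k),
                                                n = sizes, per_fold)),
                 mean = colMeans(per_fold), k = k, blocking = blocking,
                 fold = fold),
            class = "zoib_cv")
}

#' @export
print.zoib_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation (", x$blocking, " folds)\n", sep = "")
  print(x$per_fold, digits = 4, row.names = FALSE)
  cat("mean: rmse", format(x$mean["rmse"], digits = 4),
      " mae", format(x$mean["mae"], digits = 4),
      " r2", format(x$mean["r2"], digits = 4), "\n")
  invisible(x)
}

#' Split mixed catches into per-species quantities
#'
#' Applies a predicted (or observed) blue-mackerel proportion to mixed
#' catch records, yielding species-specific catch and effort-standardized
#' catch per set.  Totals are conserved: the chub share is computed as the
#' exact remainder `mixed_catch_kg - blue_kg`, so the two species' catches
#' reconstruct the mixed total to within one unit in the last place.
#'
#' @param records data frame with columns `mixed_catch_kg` (>= 0) and
#'   `sets` (>= 1).
#' @param p_blue proportion(s) in `[0, 1]`, recycled over rows.
#' @return `records` with added columns `p_blue`, `blue_kg`, `chub_kg`,
#'   `blue_per_set`, `chub_per_set`.
#' @examples
#' split_catch(data.frame(mixed_catch_kg = 1000, sets = 2), p_blue = 0.3)
#' @export
split_catch <- function(records, p_blue) {
  if (!all(c("mixed_catch_kg", "sets") %in% names(records))) {
    stop("'records' needs columns 'mixed_catch_kg' and 'sets'", call. = FALSE)
  }
  if (any(p_blue < 0 | p_blue > 1)) {
    stop("'p_blue' must lie in [0, 1]", call. = FALSE)
  }
  if (any(records$sets < 1)) stop("'sets' must be >= 1", call. = FALSE)
  p <- rep_len(p_blue, nrow(records))
  records$p_blue <- p
  records$blue_kg <- p * records$mixed_catch_kg
  records$chub_kg <- records$mixed_catch_kg - records$blue_kg
  records$blue_per_set <- records$blue_kg / records$sets
  records$chub_per_set <- records$chub_kg / records$sets
  records
}
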