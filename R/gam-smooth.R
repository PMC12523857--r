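#' Log-plus-one catch transform
#'
#' `ln(catch + 1)`: keeps zero-catch records in the additive model (0 maps
#' to 0) while stabilizing the heavy right tail of catch-per-set values.
#'
#' @param catch_per_set non-negative catch values.
#' @return natural log of `catch + 1`.
#' @export
log1p_catch <- function(catch_per_set) {
  if (any(catch_per_set < 0)) {
    stop("catch values must be non-negative", call. = FALSE)
  }
  log1p(catch_per_set)
}

#' Cubic B-spline basis with second-difference penalty
#'
#' Builds a cubic B-spline basis of dimension `k` on an unclamped uniform
#' knot grid extending past the data range (the P-spline convention),
#' together with the second-difference penalty matrix `t(D) %*% D` whose
#' null space contains coefficient vectors constant or linear in knot
#' index -- with uniform unclamped knots these correspond exactly to
#' constant and linear functions, so heavy smoothing shrinks a term to a
#' straight line.  Basis rows sum to one (partition of unity) over the
#' data range.
#'
#' @param x covariate vector with at least `k` distinct values.
#' @param k basis dimension (number of B-spline functions), default 10.
#' @return a list of class `"spline_basis"`: `B` (n x k basis matrix),
#'   `S` (k x k penalty), `knots` (full knot vector), `k`, and `range`.
#' @export
spline_basis <- function(x, k = 10) {
  ux <- sort(unique(x))
  if (length(ux) < k) {
    stop("fewer than k = ", k, " distinct covariate values; reduce 'k'",
         call. = FALSE)
  }
  if (k < 4) stop("'k' must be at least 4 for cubic splines", call. = FALSE)
  lo <- ux[1]; hi <- ux[length(ux)]
  # unclamped uniform knots extending past the data range: the Greville
  # sites are then linear in index everywhere, so the second-difference
  # penalty's null space is exactly the constant + linear functions
  h <- (hi - lo) / (k - 3)
  knots <- lo + ((1:(k + 4)) - 4) * h
  knots[4] <- lo        # pin the support ends against rounding drift
  knots[k + 1] <- hi
  B <- splines::splineDesign(knots, x, ord = 4)
  D <- diff(diag(k), differences = 2)
  structure(list(B = B, S = crossprod(D), knots = knots, k = k,
                 range = c(lo, hi)),
            class = "spline_basis")
}

# Evaluate a spline_basis at new points (clamped to the knot range).
eval_basis <- function(basis, x) {
  x <- pmin(pmax(x, basis$range[1]), basis$range[2])
  splines::splineDesign(basis$knots, x, ord = 4)
}

#' Fit a Gaussian additive model with penalized splines
#'
#' Models a (transformed) response as an intercept plus one centred cubic
#' spline smooth per covariate, `y ~ s(x1) + ... + s(xJ) + e`, estimated
#' by penalized least squares.  Each term's smoothing parameter is chosen
#' by generalized cross-validation (coordinate descent over a log-spaced
#' grid); each smooth carries a sum-to-zero constraint over the observed
#' covariate values so the intercept is identifiable.  Per-term effective
#' degrees of freedom are the trace of the term's block of the influence
#' matrix; p-values are approximate Wald-type tests of the term's
#' coefficients against zero.
#'
#' @param y numeric response (already transformed, e.g. via
#'   [log1p_catch()]).
#' @param covariates data frame (or named list) of numeric covariate
#'   vectors, one smooth per column.
#' @param k basis dimension per smooth.
#' @param lambda_grid candidate smoothing parameters for the GCV search.
#' @param max_sweeps maximum coordinate-descent sweeps over the terms.
#' @return an object of class `"additive_fit"` with methods [print()],
#'   [summary()], [predict()], [fitted()], [residuals()] and [plot()];
#'   see [partial_effect()] and [optimal_range()] for response curves.
#' @export
fit_additive <- function(y, covariates, k = 10,
                         lambda_grid = 10^seq(-6, 8, length.out = 29),
                         max_sweeps = 5) {
  covariates <- as.data.frame(covariates)
  J <- ncol(covariates)
  n <- length(y)
  if (n != nrow(covariates)) stop("size mismatch", call. = FALSE)
  if (anyNA(y) || anyNA(covariates)) {
    stop("complete cases required", call. = FALSE)
  }

  terms <- vector("list", J)
  names(terms) <- names(covariates)
  Xblocks <- vector("list", J)
  for (j in seq_len(J)) {
    bs <- spline_basis(covariates[[j]], k)
    cvec <- colSums(bs$B)
    Q <- qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
    Xj <- bs$B %*% Q
    if (qr(Xj)$rank < ncol(Xj)) {
      stop("rank-deficient smooth for term '", names(covariates)[j], "'",
           call. = FALSE)
    }
    terms[[j]] <- list(variable = names(covariates)[j], basis = bs, Q = Q,
                       S = crossprod(Q, bs$S %*% Q), lambda = 1)
    Xblocks[[j]] <- Xj
  }
  X <- cbind(`(Intercept)` = 1, do.call(cbind, Xblocks))
  idx <- split(1 + seq_len(J * (k - 1)), rep(seq_len(J), each = k - 1))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)

  pen_matrix <- function(lambdas) {
    P <- matrix(0, ncol(X), ncol(X))
    for (j in seq_len(J)) P[idx[[j]], idx[[j]]] <- lambdas[j] * terms[[j]]$S
    P
  }
  gcv_score <- function(lambdas) {
    P <- pen_matrix(lambdas)
    G <- solve(XtX + P, XtX)
    beta <- solve(XtX + P, Xty)
    rss <- sum((y - X %*% beta)^2)
    edf <- sum(diag(G))
    n * rss / (n - edf)^2
  }

  # coordinate descent over the grid; near-ties resolve toward the larger
  # lambda so exactly-representable (e.g. noise-free linear) signals get
  # the smooth limit rather than an arbitrary interpolant
  lambda_grid <- sort(lambda_grid)
  pick <- function(scores) {
    m <- min(scores)
    max(which(scores <= m + 1e-7 * (1 + abs(m))))
  }
  lambdas <- rep(1, J)
  best <- gcv_score(lambdas)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (j in seq_len(J)) {
      scores <- vapply(lambda_grid, function(l) {
        lam <- lambdas; lam[j] <- l
        gcv_score(lam)
      }, 0)
      l_new <- lambda_grid[pick(scores)]
      if (l_new != lambdas[j]) {
        lambdas[j] <- l_new
        changed <- TRUE
      }
    }
    score <- gcv_score(lambdas)
    if (!changed || score >= best - 1e-10) {
      best <- min(best, score)
      break
    }
    best <- score
  }
  # one golden-section refinement per term between neighbouring grid points
  step <- if (length(lambda_grid) > 1) {
    lambda_grid[2] / lambda_grid[1]
  } else 10
  for (j in seq_len(J)) {
    opt <- stats::optimize(function(ll) {
      lam <- lambdas; lam[j] <- exp(ll)
      gcv_score(lam)
    }, interval = log(c(lambdas[j] / step, lambdas[j] * step)))
    if (opt$objective < best - 1e-12 * (1 + abs(best))) {
      lambdas[j] <- exp(opt$minimum)
      best <- opt$objective
    }
  }

  P <- pen_matrix(lambdas)
  Ainv <- solve(XtX + P)
  beta <- drop(Ainv %*% Xty)
  fitted <- drop(X %*% beta)
  residuals <- y - fitted
  rss <- sum(residuals^2)
  tss <- sum((y - mean(y))^2)
  G <- Ainv %*% XtX
  edf_all <- diag(G)
  ref_all <- diag(2 * G - G %*% G)
  edf_total <- sum(edf_all)
  sigma2 <- rss / (n - edf_total)
  Vb <- sigma2 * Ainv                 # Bayesian cov, used for bands
  Ve <- sigma2 * (G %*% Ainv)         # frequentist cov, used for tests

  for (j in seq_len(J)) {
    ij <- idx[[j]]
    terms[[j]]$lambda <- lambdas[j]
    terms[[j]]$coef <- beta[ij]
    terms[[j]]$edf <- sum(edf_all[ij])
    terms[[j]]$ref_df <- sum(ref_all[ij])
    terms[[j]]$Vb <- Vb[ij, ij]
    Vej <- Ve[ij, ij]
    ev <- eigen((Vej + t(Vej)) / 2, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-10
    r <- sum(pos)
    bj <- drop(crossprod(ev$vectors[, pos, drop = FALSE], beta[ij]))
    Tstat <- sum(bj^2 / ev$values[pos])
    terms[[j]]$statistic <- Tstat
    terms[[j]]$p_value <- stats::pf(Tstat / r, r, n - edf_total,
                                    lower.tail = FALSE)
    terms[[j]]$x <- covariates[[j]]
  }

  structure(
    list(y = y, fitted = fitted, residuals = residuals,
         intercept = beta[1], coefficients = beta, terms = terms,
         idx = idx, n = n, k = k, lambdas = lambdas,
         edf_total = edf_total, sigma2 = sigma2, gcv = best,
         deviance_explained = 1 - rss / tss,
         r_squared = 1 - (rss / (n - edf_total)) / (tss / (n - 1)),
         Vb = Vb, Ve = Ve),
    class = "additive_fit")
}

#' @export
print.additive_fit <- function(x, ...) {
  cat("Penalized-spline additive model:", length(x$terms), "smooths, n =",
      x$n, "\n")
  cat("deviance explained:", format(x$deviance_explained, digits = 4),
      "  adj. R2:", format(x$r_squared, digits = 4), "\n")
  print(summary(x)$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.additive_fit <- function(object, ...) {
  tab <- data.frame(
    variable = vapply(object$terms, `[[`, "", "variable"),
    edf = vapply(object$terms, `[[`, 0, "edf"),
    ref_df = vapply(object$terms, `[[`, 0, "ref_df"),
    statistic = vapply(object$terms, `[[`, 0, "statistic"),
    p_value = vapply(object$terms, `[[`, 0, "p_value"),
    row.names = NULL)
  out <- list(table = tab, deviance_explained = object$deviance_explained,
              r_squared = object$r_squared, sigma2 = object$sigma2,
              edf_total = object$edf_total, n = object$n)
  class(out) <- "summary.additive_fit"
  out
}

#' @export
print.summary.additive_fit <- function(x, ...) {
  cat("Approximate significance of smooth terms:\n")
  print(x$table, digits = 4, row.names = FALSE)
  cat("\nAdj. R2 =", format(x$r_squared, digits = 4),
      "  Deviance explained =", format(x$deviance_explained, digits = 4),
      "  n =", x$n, "\n")
  invisible(x)
}

#' @export
fitted.additive_fit <- function(object, ...) object$fitted

#' @export
residuals.additive_fit <- function(object, ...) object$residuals

#' @export
predict.additive_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  out <- rep(unname(object$intercept), nrow(newdata))
  for (tm in object$terms) {
    if (!tm$variable %in% names(newdata)) {
      stop("newdata lacks '", tm$variable, "'", call. = FALSE)
    }
    Bg <- eval_basis(tm$basis, newdata[[tm$variable]]) %*% tm$Q
    out <- out + drop(Bg %*% tm$coef)
  }
  out
}

#' Centred partial-effect curve of one smooth term
#'
#' Evaluates the selected smooth on a grid with a pointwise 95% confidence
#' band (`+- 1.96` standard errors from the coefficient covariance).
#'
#' @param fit an [fit_additive()] object.
#' @param variable name of the smooth.
#' @param grid evaluation points; default 200 equally spaced points over
#'   the observed range.
#' @param level band coverage, default 0.95.
#' @return a data frame of class `"partial_effect"` with columns `x`,
#'   `fit`, `se`, `lower`, `upper`.
#' @export
partial_effect <- function(fit, variable, grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "additive_fit"))
  tm <- fit$terms[[variable]]
  if (is.null(tm)) stop("no smooth term '", variable, "'", call. = FALSE)
  if (is.null(grid)) {
    grid <- seq(tm$basis$range[1], tm$basis$range[2], length.out = 200)
  }
  Bg <- eval_basis(tm$basis, grid) %*% tm$Q
  est <- drop(Bg %*% tm$coef)
  se <- sqrt(pmax(rowSums((Bg %*% tm$Vb) * Bg), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(x = grid, fit = est, se = se,
                    lower = est - z * se, upper = est + z * se)
  attr(out, "variable") <- variable
  class(out) <- c("partial_effect", "data.frame")
  out
}

#' Optimal environmental range from confidence-band width
#'
#' Identifies the covariate interval where the confidence band around the
#' fitted response curve is narrowest: the grid points whose band width
#' falls in the narrowest `fraction` of widths are selected and the
#' largest contiguous run is returned (ties broken toward the run
#' containing the curve maximum).  A constant-width band yields the whole
#' grid flagged non-informative.
#'
#' @param pe a [partial_effect()] data frame.
#' @param fraction the narrowest fraction of band widths considered,
#'   default 0.2; `fraction = 0` selects only the single narrowest point.
#' @return a list: `range` (covariate interval), `indices` (grid indices),
#'   `noninformative` flag.
#' @export
optimal_range <- function(pe, fraction = 0.2) {
  stopifnot(inherits(pe, "partial_effect"))
  width <- pe$upper - pe$lower
  if (diff(range(width)) <= 1e-12 * max(1, mean(width))) {
    return(list(range = range(pe$x), indices = seq_along(pe$x),
                noninformative = TRUE))
  }
  thr <- if (fraction <= 0) min(width) else {
    stats::quantile(width, fraction, names = FALSE)
  }
  ok <- width <= thr + 1e-12
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values)
  lens <- runs$lengths[cand]
  best <- cand[lens == max(lens)]
  if (length(best) > 1) {
    imax <- which.max(pe$fit)
    contains <- vapply(best, function(b) {
      imax >= starts[b] && imax <= ends[b]
    }, TRUE)
    best <- if (any(contains)) best[which(contains)[1]] else best[1]
  }
  ii <- starts[best]:ends[best]
  list(range = range(pe$x[ii]), indices = ii, noninformative = FALSE)
}

#' @export
plot.additive_fit <- function(x, pages = 1, ...) {
  J <- length(x$terms)
  op <- graphics::par(mfrow = grDevices::n2mfrow(J))
  on.exit(graphics::par(op))
  for (tm in x$terms) {
    pe <- partial_effect(x, tm$variable)
    graphics::plot(pe$x, pe$fit, type = "l",
                   xlab = tm$variable,
                   ylab = sprintf("s(%s, %.2f)", tm$variable, tm$edf),
                   ylim = range(pe$lower, pe$upper), ...)
    graphics::lines(pe$x, pe$lower, lty = 2)
    graphics::lines(pe$x, pe$upper, lty = 2)
  }
  invisible(x)
}
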