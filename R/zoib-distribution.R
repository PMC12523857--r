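#' Zero-one inflated beta (ZOIB) density
#'
#' Density of the mixture distribution on `[0, 1]` with point masses at the
#' boundaries and a Beta density on the open interval.  With probability
#' `zoi` the outcome is a boundary value, which equals 1 with conditional
#' probability `coi`; otherwise it is drawn from a Beta distribution in the
#' mean--precision parameterization `Beta(mu * phi, (1 - mu) * phi)`.
#'
#' @param x vector of proportions in `[0, 1]`.
#' @param mu Beta component mean, in `(0, 1)`.
#' @param phi Beta component precision, `> 0`.
#' @param zoi probability that the outcome is exactly 0 or 1, in `[0, 1]`.
#' @param coi conditional probability that a boundary outcome is 1, in
#'   `[0, 1]`.
#' @param log logical; return the log density?
#'
#' @details At the boundaries the "density" is the point-mass probability:
#'   `zoi * (1 - coi)` at 0 and `zoi * coi` at 1.  In the interior it is
#'   `(1 - zoi) * dbeta(x, mu * phi, (1 - mu) * phi)`.  Arguments are
#'   recycled to a common length.
#'
#' @return numeric vector of (log) densities.
#' @seealso [rzoib()], [zoib_mean()]
#' @examples
#' dzoib(c(0, 0.5, 1), mu = 0.5, phi = 2, zoi = 0.2, coi = 0.5)
#' @export
dzoib <- function(x, mu, phi, zoi, coi, log = FALSE) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("'x' must lie in [0, 1]", call. = FALSE)
  }
  check_zoib_args(mu, phi, zoi, coi)
  n <- max(length(x), length(mu), length(phi), length(zoi), length(coi))
  x <- rep_len(x, n)
  mu <- rep_len(mu, n)
  phi <- rep_len(phi, n)
  zoi <- rep_len(zoi, n)
  coi <- rep_len(coi, n)

  out <- numeric(n)
  at0 <- x == 0
  at1 <- x == 1
  mid <- !at0 & !at1
  # log(0) = -Inf is the correct degenerate value when an atom is absent
  out[at0] <- log(zoi[at0]) + log1p(-coi[at0])
  out[at1] <- log(zoi[at1]) + log(coi[at1])
  out[mid] <- log1p(-zoi[mid]) +
    stats::dbeta(x[mid], mu[mid] * phi[mid], (1 - mu[mid]) * phi[mid],
                 log = TRUE)
  if (log) out else exp(out)
}

#' Draw from the zero-one inflated beta distribution
#'
#' @param n number of draws.
#' @inheritParams dzoib
#' @return numeric vector of length `n` with values in `[0, 1]`; boundary
#'   values are exact 0s and 1s.
#' @examples
#' set.seed(1)
#' y <- rzoib(1000, mu = 0.6, phi = 5, zoi = 0.3, coi = 0.4)
#' mean(y == 0); mean(y == 1)
#' @export
rzoib <- function(n, mu, phi, zoi, coi) {
  check_zoib_args(mu, phi, zoi, coi)
  mu <- rep_len(mu, n)
  phi <- rep_len(phi, n)
  zoi <- rep_len(zoi, n)
  coi <- rep_len(coi, n)
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  boundary <- stats::runif(n) < zoi
  if (any(boundary)) {
    y[boundary] <- as.numeric(stats::runif(sum(boundary)) < coi[boundary])
  }
  y
}

#' Mean of the zero-one inflated beta distribution
#'
#' `E(Y) = zoi * coi + (1 - zoi) * mu`: the one-atom contributes `zoi * coi`,
#' the zero-atom nothing, and the Beta component `(1 - zoi) * mu`.  This is
#' the predicted species proportion used to split mixed catches.
#'
#' @inheritParams dzoib
#' @return numeric vector of means in `[0, 1]`.
#' @export
zoib_mean <- function(mu, zoi, coi) {
  check_zoib_args(mu, 1, zoi, coi)
  zoi * coi + (1 - zoi) * mu
}

check_zoib_args <- function(mu, phi, zoi, coi) {
  if (any(mu <= 0 | mu >= 1)) stop("'mu' must lie in (0, 1)", call. = FALSE)
  if (any(phi <= 0)) stop("'phi' must be positive", call. = FALSE)
  if (any(zoi < 0 | zoi > 1)) stop("'zoi' must lie in [0, 1]", call. = FALSE)
  if (any(coi < 0 | coi > 1)) stop("'coi' must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' ZOIB regression parameter set
#'
#' Bundles the coefficient vectors of the four linear predictors of the ZOIB
#' regression together with the spatial random effect.  Links are the
#' conventional ones: logit for the Beta mean `mu`, the boundary probability
#' `zoi` and the conditional one-probability `coi`; log for the precision
#' `phi`.  The spatial random effect `u` enters the `mu` predictor only,
#' indexed by spatial block.
#'
#' @param beta_mu,beta_phi,beta_zoi,beta_coi numeric coefficient vectors,
#'   one entry per design-matrix column (intercept first).  `beta_mu` sets
#'   the length; the others may be scalars, interpreted as intercept-only
#'   (slopes zero).
#' @param u optional named numeric vector of spatial random-effect values,
#'   one per spatial block.
#' @param sigma_u random-effect standard deviation, `> 0`.
#' @param prior_scale Laplace prior scale for the non-intercept regression
#'   coefficients, `> 0`.
#' @return an object of class `"zoib_params"`.
#' @examples
#' zoib_params(beta_mu = c(0, 0.5), beta_phi = c(log(5), 0),
#'             beta_zoi = qlogis(0.2), beta_coi = qlogis(0.4))
#' @export
zoib_params <- function(beta_mu, beta_phi = 0, beta_zoi = 0, beta_coi = 0,
                        u = NULL, sigma_u = 1, prior_scale = 1) {
  p <- length(beta_mu)
  pad <- function(b) {
    if (length(b) == p) b
    else if (length(b) == 1) c(b, rep(0, p - 1))  # intercept only
    else stop("coefficient vectors must have length 1 or ", p, call. = FALSE)
  }
  beta_phi <- pad(beta_phi)
  beta_zoi <- pad(beta_zoi)
  beta_coi <- pad(beta_coi)
  if (sigma_u <= 0) stop("'sigma_u' must be positive", call. = FALSE)
  if (prior_scale <= 0) stop("'prior_scale' must be positive", call. = FALSE)
  structure(
    list(beta_mu = beta_mu, beta_phi = beta_phi, beta_zoi = beta_zoi,
         beta_coi = beta_coi, u = u, sigma_u = sigma_u,
         prior_scale = prior_scale),
    class = "zoib_params")
}

#' Evaluate the four ZOIB linear predictors
#'
#' Maps a parameter set and design matrix to per-row distribution
#' parameters: `mu = plogis(X beta_mu + u[block])`, `phi = exp(X beta_phi)`,
#' `zoi = plogis(X beta_zoi)`, `coi = plogis(X beta_coi)`.
#'
#' @param params a [zoib_params()] object.
#' @param X design matrix (intercept column included).
#' @param block optional integer/factor vector of spatial block labels per
#'   row, indexing `params$u`.  Blocks absent from `params$u` get a zero
#'   random effect.
#' @return a data frame with columns `mu`, `phi`, `zoi`, `coi`.
#' @export
zoib_linpred <- function(params, X, block = NULL) {
  stopifnot(inherits(params, "zoib_params"))
  X <- as.matrix(X)
  if (ncol(X) != length(params$beta_mu)) {
    stop("design matrix has ", ncol(X), " columns but coefficients have length ",
         length(params$beta_mu), call. = FALSE)
  }
  eta_mu <- drop(X %*% params$beta_mu)
  if (!is.null(block)) {
    if (length(block) != nrow(X)) {
      stop("'block' length must match the rows of 'X'", call. = FALSE)
    }
    if (!is.null(params$u)) {
      uu <- params$u[as.character(block)]
      uu[is.na(uu)] <- 0
      eta_mu <- eta_mu + uu
    }
  }
  data.frame(
    mu  = stats::plogis(eta_mu),
    phi = exp(drop(X %*% params$beta_phi)),
    zoi = stats::plogis(drop(X %*% params$beta_zoi)),
    coi = stats::plogis(drop(X %*% params$beta_coi))
  )
}

#' Simulate responses from a ZOIB regression
#'
#' Draws one response per design-matrix row from the ZOIB distribution with
#' parameters given by [zoib_linpred()].
#'
#' @inheritParams zoib_linpred
#' @param seed optional integer seed for reproducibility.
#' @return numeric response vector in `[0, 1]`.
#' @export
zoib_simulate <- function(params, X, block = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lp <- zoib_linpred(params, X, block)
  rzoib(nrow(lp), lp$mu, lp$phi, lp$zoi, lp$coi)
}
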