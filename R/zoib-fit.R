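#' Negative log posterior of the ZOIB regression
#'
#' Sum of the negative ZOIB log likelihood over rows, plus a Laplace
#' penalty `sum(|beta|) / prior_scale` over all non-intercept regression
#' coefficients, a Gaussian penalty for the spatial random effect `u` given
#' `sigma_u`, and a weakly informative boundary-avoiding lognormal prior
#' on `sigma_u` (median 0.3, log-sd 1) that keeps the joint mode away from
#' the `sigma_u = 0` collapse.  Used as the MAP objective and (negated) as
#' the MCMC log target.
#'
#' @param params a [zoib_params()] object; `params$u` must cover the levels
#'   of `block` when a random effect is used.
#' @param y response vector of proportions in `[0, 1]`.
#' @param X design matrix, intercept in the first column.
#' @param block optional spatial block labels per row.
#' @param smooth_eps smoothing constant for the Laplace penalty in MAP
#'   optimization, `|b| ~ sqrt(b^2 + eps^2)`; set to 0 for the exact prior
#'   (used by the MCMC target).
#' @return a single number; `+Inf` when the likelihood degenerates.
#' @export
zoib_neglogpost <- function(params, y, X, block = NULL, smooth_eps = 1e-8) {
  stopifnot(inherits(params, "zoib_params"))
  dat <- zoib_prepare(y, X, block)
  theta <- params_to_theta(params, dat)
  zoib_nlp_theta(theta, dat,
                 prior_scale = params$prior_scale, smooth_eps = smooth_eps)
}

# Precompute everything the objective needs.  block is mapped to integer
# indices 1..B (B = 0 when no random effect).
zoib_prepare <- function(y, X, block = NULL) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("'y' and 'X' sizes differ", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("missing values in 'y' or 'X'", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("'y' must lie in [0, 1]", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  is0 <- y == 0
  is1 <- y == 1
  mid <- !is0 & !is1
  blk <- NULL
  levels <- character(0)
  if (!is.null(block)) {
    f <- factor(block)
    levels <- levels(f)
    blk <- as.integer(f)
  }
  list(y = y, X = X, p = ncol(X), n = length(y),
       is0 = is0, is1 = is1, mid = mid,
       block = blk, block_levels = levels, B = length(levels),
       ymid = y[mid], lymid = log(y[mid]), l1ymid = log1p(-y[mid]))
}

params_to_theta <- function(params, dat) {
  u <- rep(0, dat$B)
  if (dat$B > 0 && !is.null(params$u)) {
    m <- match(dat$block_levels, names(params$u))
    u[!is.na(m)] <- params$u[m[!is.na(m)]]
  }
  c(params$beta_mu, params$beta_phi, params$beta_zoi, params$beta_coi,
    if (dat$B > 0) c(u, log(params$sigma_u)))
}

theta_to_params <- function(theta, dat, prior_scale = 1) {
  p <- dat$p
  u <- NULL
  sigma_u <- 1
  if (dat$B > 0) {
    u <- theta[4 * p + seq_len(dat$B)]
    names(u) <- dat$block_levels
    sigma_u <- exp(theta[4 * p + dat$B + 1])
  }
  zoib_params(beta_mu = theta[seq_len(p)],
              beta_phi = theta[p + seq_len(p)],
              beta_zoi = theta[2 * p + seq_len(p)],
              beta_coi = theta[3 * p + seq_len(p)],
              u = u, sigma_u = sigma_u, prior_scale = prior_scale)
}

theta_names <- function(dat) {
  cn <- colnames(dat$X)
  nm <- c(paste0("mu:", cn), paste0("phi:", cn),
          paste0("zoi:", cn), paste0("coi:", cn))
  if (dat$B > 0) nm <- c(nm, paste0("u:", dat$block_levels), "log_sigma_u")
  nm
}

# Objective on the packed parameter vector.
zoib_nlp_theta <- function(theta, dat, prior_scale = 1, smooth_eps = 1e-8) {
  p <- dat$p
  b_mu <- theta[seq_len(p)]
  b_phi <- theta[p + seq_len(p)]
  b_zoi <- theta[2 * p + seq_len(p)]
  b_coi <- theta[3 * p + seq_len(p)]

  eta_mu <- drop(dat$X %*% b_mu)
  if (dat$B > 0) {
    u <- theta[4 * p + seq_len(dat$B)]
    eta_mu <- eta_mu + u[dat$block]
  }
  zoi <- stats::plogis(drop(dat$X %*% b_zoi))
  coi <- stats::plogis(drop(dat$X %*% b_coi))

  ll <- 0
  # boundary components
  bnd <- dat$is0 | dat$is1
  ll <- ll + sum(log(zoi[bnd])) + sum(log1p(-zoi[dat$mid]))
  ll <- ll + sum(log(coi[dat$is1])) + sum(log1p(-coi[dat$is0]))
  # Beta component on interior rows
  if (any(dat$mid)) {
    mu <- stats::plogis(eta_mu[dat$mid])
    phi <- exp(drop(dat$X[dat$mid, , drop = FALSE] %*% b_phi))
    a <- mu * phi
    b <- (1 - mu) * phi
    ll <- ll + sum((a - 1) * dat$lymid + (b - 1) * dat$l1ymid - lbeta(a, b))
  }
  if (!is.finite(ll)) return(Inf)

  # Laplace penalty on non-intercept coefficients of all four predictors
  slopes <- c(b_mu[-1], b_phi[-1], b_zoi[-1], b_coi[-1])
  pen <- if (smooth_eps > 0) {
    sum(sqrt(slopes^2 + smooth_eps^2)) / prior_scale
  } else {
    sum(abs(slopes)) / prior_scale
  }
  if (dat$B > 0) {
    s <- theta[4 * p + dat$B + 1]
    sig2 <- exp(2 * s)
    pen <- pen + 0.5 * sum(u^2) / sig2 + dat$B * s # N(0, sigma_u^2) on u
    # boundary-avoiding lognormal prior on sigma_u: without it the joint
    # mode collapses to sigma_u = 0 whenever the u are shrunk to zero
    pen <- pen + 0.5 * ((s - log(0.3)) / 1)^2
  }
  -ll + pen
}

# Analytic gradient of zoib_nlp_theta (checked against finite differences
# in the test suite).
zoib_nlp_grad <- function(theta, dat, prior_scale = 1, smooth_eps = 1e-8) {
  p <- dat$p
  b_mu <- theta[seq_len(p)]
  b_phi <- theta[p + seq_len(p)]
  b_zoi <- theta[2 * p + seq_len(p)]
  b_coi <- theta[3 * p + seq_len(p)]

  eta_mu <- drop(dat$X %*% b_mu)
  if (dat$B > 0) {
    u <- theta[4 * p + seq_len(dat$B)]
    eta_mu <- eta_mu + u[dat$block]
  }
  zoi <- stats::plogis(drop(dat$X %*% b_zoi))
  coi <- stats::plogis(drop(dat$X %*% b_coi))

  bnd <- dat$is0 | dat$is1
  g_eta_zoi <- (as.numeric(bnd) - zoi)                 # d loglik / d eta_zoi
  g_eta_coi <- numeric(dat$n)
  g_eta_coi[dat$is1] <- 1 - coi[dat$is1]
  g_eta_coi[dat$is0] <- -coi[dat$is0]

  g_eta_mu <- numeric(dat$n)
  g_eta_phi <- numeric(dat$n)
  if (any(dat$mid)) {
    Xm <- dat$X[dat$mid, , drop = FALSE]
    mu <- stats::plogis(eta_mu[dat$mid])
    phi <- exp(drop(Xm %*% b_phi))
    a <- mu * phi
    b <- (1 - mu) * phi
    da <- dat$lymid - digamma(a) + digamma(phi)        # d loglik / d a
    db <- dat$l1ymid - digamma(b) + digamma(phi)       # d loglik / d b
    g_eta_mu[dat$mid] <- phi * mu * (1 - mu) * (da - db)
    g_eta_phi[dat$mid] <- phi * (mu * da + (1 - mu) * db)
  }

  g_bmu <- drop(crossprod(dat$X, g_eta_mu))
  g_bphi <- drop(crossprod(dat$X, g_eta_phi))
  g_bzoi <- drop(crossprod(dat$X, g_eta_zoi))
  g_bcoi <- drop(crossprod(dat$X, g_eta_coi))

  pen_slope <- function(b) {
    g <- if (smooth_eps > 0) b / sqrt(b^2 + smooth_eps^2) else sign(b)
    c(0, g[-1]) / prior_scale
  }
  grad <- c(-g_bmu + pen_slope(b_mu), -g_bphi + pen_slope(b_phi),
            -g_bzoi + pen_slope(b_zoi), -g_bcoi + pen_slope(b_coi))

  if (dat$B > 0) {
    s <- theta[4 * p + dat$B + 1]
    sig2 <- exp(2 * s)
    g_u <- -rowsum_by(g_eta_mu, dat$block, dat$B) + u / sig2
    g_s <- -sum(u^2) / sig2 + dat$B + (s - log(0.3))
    grad <- c(grad, g_u, g_s)
  }
  grad
}

rowsum_by <- function(x, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit a zero-one inflated beta regression
#'
#' Fits the mixed-catch species-composition model: a Beta regression on the
#' interior proportions with logit mean link and log precision link,
#' combined with logit regressions for the boundary probability (`zoi`) and
#' the conditional one-probability (`coi`).  The same covariates enter all
#' four linear predictors; a spatial random effect (optional) enters the
#' mean predictor.  Non-intercept coefficients carry a Laplace prior of
#' scale `prior_scale`.  Estimation is by penalized maximum a posteriori
#' (`method = "map"`, BFGS with analytic gradients) or by MCMC
#' (`method = "mcmc"`, adaptive block-wise random-walk Metropolis started
#' from a jittered MAP estimate; see [rhat()] for convergence checking).
#'
#' With a random effect, the MAP profiles the block effects `u` with
#' `sigma_u` held at its prior median (0.3): the joint mode in
#' `(u, sigma_u)` is degenerate (it collapses to `sigma_u = 0` as the
#' number of blocks grows), so a data-driven estimate of `sigma_u` is
#' only available from `method = "mcmc"`, which integrates over `u`.
#'
#' @param formula model formula, e.g. `proportion_blue ~ sst + sss + chla`.
#'   The response must be a proportion in `[0, 1]`.
#' @param data data frame containing the variables.
#' @param block optional spatial block: the name of a column in `data` or a
#'   vector with one label per row.  Adds a Gaussian random intercept per
#'   block to the mean predictor.
#' @param prior_scale Laplace prior scale for non-intercept coefficients.
#' @param method `"map"` (default) or `"mcmc"`.
#' @param chains,iter,burn_in MCMC settings: number of chains, total
#'   iterations per chain, and initial iterations discarded.  Defaults
#'   follow the conventional 4 chains of 4000 iterations with the first
#'   2000 discarded.
#' @param seed integer seed controlling MCMC reproducibility (and MAP
#'   restarts, which are deterministic anyway).
#' @param standardize center and scale covariates before fitting
#'   (recommended; required for a common prior scale to be meaningful).
#'   Predictions transform back automatically.
#' @param control optional list: `maxit`, `reltol` for the optimizer,
#'   `accept_target`, `adapt_every` for the sampler.
#'
#' @return an object of class `"zoib"` with methods [print()],
#'   [summary()], [coef()], [predict()], [simulate()], [residuals()],
#'   [fitted()], [confint()] and [vcov()].
#' @examples
#' set.seed(7)
#' X <- cbind(1, x = rnorm(400))
#' truth <- zoib_params(beta_mu = c(0, 0.8), beta_phi = log(8),
#'                      beta_zoi = qlogis(0.2), beta_coi = qlogis(0.5))
#' d <- data.frame(y = zoib_simulate(truth, X), x = X[, 2])
#' fit <- zoib(y ~ x, data = d)
#' coef(fit)
#' @export
zoib <- function(formula, data, block = NULL, prior_scale = 1,
                 method = c("map", "mcmc"), chains = 4, iter = 4000,
                 burn_in = 2000, seed = NULL, standardize = TRUE,
                 control = list()) {
  method <- match.arg(method)
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  mt <- attr(mf, "terms")
  y <- unname(stats::model.response(mf))
  X <- stats::model.matrix(mt, mf)
  if (attr(mt, "intercept") != 1) {
    stop("the model must include an intercept", call. = FALSE)
  }

  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  names(center) <- names(scale) <- colnames(X)
  if (standardize && ncol(X) > 1) {
    for (j in 2:ncol(X)) {
      center[j] <- mean(X[, j])
      sj <- stats::sd(X[, j])
      scale[j] <- if (sj > 0) sj else 1
      X[, j] <- (X[, j] - center[j]) / scale[j]
    }
  }

  if (is.character(block) && length(block) == 1) {
    if (!block %in% names(data)) stop("block column '", block, "' not found",
                                      call. = FALSE)
    block <- data[[block]]
  }
  dat <- zoib_prepare(y, X, block)
  if (dat$n < 10 * dat$p) {
    warning("fewer than 10 rows per regression parameter; estimates may be unstable",
            call. = FALSE)
  }

  map <- zoib_fit_map(dat, prior_scale, control)
  fit <- list(call = cl, formula = formula, terms = mt,
              method = method, prior_scale = prior_scale,
              center = center, scale = scale,
              y = y, X = X, block = block, dat = dat,
              coefficients = theta_to_params(map$theta, dat, prior_scale),
              theta = map$theta, parameter_names = theta_names(dat),
              vcov = map$vcov, se = map$se, value = map$value,
              convergence = map$convergence, fixed = map$fixed,
              identifiable = map$identifiable, seed = seed)
  class(fit) <- "zoib"

  if (method == "mcmc") {
    draws <- zoib_fit_mcmc(dat, map, prior_scale, chains = chains,
                           iter = iter, burn_in = burn_in, seed = seed,
                           control = control)
    fit$draws <- draws
    fit$rhat <- rhat(draws)
    post <- posterior_matrix(draws)
    fit$theta <- colMeans(post)
    fit$coefficients <- theta_to_params(fit$theta, dat, prior_scale)
    fit$se <- apply(post, 2, stats::sd)
  }
  fit
}

# MAP estimation with guards for unidentifiable components.  Components
# whose empirical support is degenerate (no interior rows for the Beta
# part; no boundary rows for zoi; one-sided boundary rows for coi) have
# their coefficients fixed at empirical-logit intercepts and are flagged.
zoib_fit_map <- function(dat, prior_scale, control = list(), init = NULL) {
  p <- dat$p
  n0 <- sum(dat$is0); n1 <- sum(dat$is1); nmid <- sum(dat$mid)
  nb <- n0 + n1
  elogit <- function(k, n) stats::qlogis((k + 0.5) / (n + 1))

  theta0 <- numeric(4 * p + if (dat$B > 0) dat$B + 1 else 0)
  ymid_mean <- if (nmid > 0) mean(dat$ymid) else 0.5
  theta0[1] <- stats::qlogis(min(max(ymid_mean, 0.02), 0.98))
  theta0[p + 1] <- log(5)
  theta0[2 * p + 1] <- elogit(nb, dat$n)
  theta0[3 * p + 1] <- elogit(n1, max(nb, 1))
  if (dat$B > 0) theta0[4 * p + dat$B + 1] <- log(0.3)
  if (!is.null(init)) theta0 <- init

  free <- rep(TRUE, length(theta0))
  sigma_fixed <- FALSE
  if (dat$B > 0) {
    # the joint (u, sigma_u) mode degenerates toward sigma_u = 0 as the
    # number of blocks grows (B log sigma dominates any fixed prior), so
    # the MAP profiles u at sigma_u held at the prior median; sigma_u is
    # estimated by MCMC, which integrates over u
    free[4 * p + dat$B + 1] <- FALSE
    sigma_fixed <- TRUE
  }
  identifiable <- c(beta = TRUE, zoi = TRUE, coi = TRUE)
  if (nmid == 0) {            # all-boundary response: Beta part meaningless
    free[seq_len(2 * p)] <- FALSE
    if (dat$B > 0) free[4 * p + seq_len(dat$B + 1)] <- FALSE
    identifiable["beta"] <- FALSE
  }
  if (nb == 0) {              # no boundary values at all
    free[2 * p + seq_len(p)] <- FALSE
    free[3 * p + seq_len(p)] <- FALSE
    identifiable["zoi"] <- FALSE
    identifiable["coi"] <- FALSE
  } else if (n0 == 0 || n1 == 0) {
    free[3 * p + seq_len(p)] <- FALSE
    identifiable["coi"] <- FALSE
  }

  maxit <- control$maxit %||% 1000
  reltol <- control$reltol %||% 1e-12
  fn <- function(th_free) {
    th <- theta0; th[free] <- th_free
    zoib_nlp_theta(th, dat, prior_scale)
  }
  gr <- function(th_free) {
    th <- theta0; th[free] <- th_free
    zoib_nlp_grad(th, dat, prior_scale)[free]
  }

  opt <- stats::optim(theta0[free], fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  tries <- 0
  while (opt$convergence != 0 && tries < 3) {
    opt <- stats::optim(opt$par, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol))
    tries <- tries + 1
  }
  if (opt$convergence != 0) {
    cond <- structure(
      class = c("zoib_nonconvergence", "error", "condition"),
      list(message = paste0("MAP optimizer failed to converge (code ",
                            opt$convergence, ")"),
           call = sys.call(-1), state = opt))
    stop(cond)
  }

  theta <- theta0; theta[free] <- opt$par
  H <- stats::optimHess(opt$par, fn, gr)
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error") || anyNA(V) || any(diag(V) <= 0)) {
    # eigenvalue-thresholded pseudo-inverse for ill-conditioned modes
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    lam <- pmax(ev$values, max(abs(ev$values)) * 1e-10)
    V <- ev$vectors %*% (t(ev$vectors) / lam)
  }
  vcov <- matrix(0, length(theta), length(theta))
  vcov[free, free] <- V
  se <- sqrt(pmax(diag(vcov), 0))
  nm <- theta_names(dat)
  names(theta) <- names(se) <- nm
  dimnames(vcov) <- list(nm, nm)

  list(theta = theta, vcov = vcov, se = se, value = opt$value,
       convergence = opt$convergence, free = free, fixed = !free,
       sigma_fixed = sigma_fixed, identifiable = identifiable)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.zoib <- function(x, ...) {
  cat("Zero-one inflated beta regression (", x$method, ")\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\n")
  cat("n =", x$dat$n, " (", sum(x$dat$is0), "zeros,", sum(x$dat$is1),
      "ones )\n")
  cat("\nCoefficients (standardized covariate scale):\n")
  print(coef(x), digits = 4)
  if (x$dat$B > 0) {
    cat("\nSpatial random effect: ", x$dat$B, " blocks, sigma_u = ",
        format(x$coefficients$sigma_u, digits = 4), "\n", sep = "")
  }
  if (!is.null(x$rhat)) {
    cat("max split R-hat:", format(max(x$rhat, na.rm = TRUE), digits = 5), "\n")
  }
  invisible(x)
}

#' @export
coef.zoib <- function(object, ...) {
  p <- object$dat$p
  th <- object$theta[seq_len(4 * p)]
  th
}

#' @export
vcov.zoib <- function(object, ...) object$vcov

#' @export
fitted.zoib <- function(object, ...) {
  lp <- zoib_linpred(object$coefficients, object$X, object$block)
  zoib_mean(lp$mu, lp$zoi, lp$coi)
}

#' @export
residuals.zoib <- function(object, ...) object$y - fitted(object)

#' Predict species proportions from a fitted ZOIB regression
#'
#' @param object a fitted [zoib()] model.
#' @param newdata optional data frame of covariates (original, unscaled
#'   units); omitted means the training data.
#' @param type `"response"` for the expected proportion
#'   `zoi*coi + (1-zoi)*mu`, `"components"` for the per-row `(mu, phi,
#'   zoi, coi)` data frame.
#' @param block optional block labels for `newdata`; unseen blocks get a
#'   zero random effect.
#' @param ... unused.
#' @return numeric vector or data frame, one entry per row.
#' @export
predict.zoib <- function(object, newdata = NULL,
                         type = c("response", "components"),
                         block = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X
    block <- object$block
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail)
    X <- stats::model.matrix(tt, mf)
    for (j in seq_len(ncol(X))) {
      X[, j] <- (X[, j] - object$center[j]) / object$scale[j]
    }
    if (is.character(block) && length(block) == 1 && block %in% names(newdata)) {
      block <- newdata[[block]]
    }
  }
  lp <- zoib_linpred(object$coefficients, X, block)
  if (type == "components") lp else zoib_mean(lp$mu, lp$zoi, lp$coi)
}

#' @export
simulate.zoib <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lp <- zoib_linpred(object$coefficients, object$X, object$block)
  out <- as.data.frame(replicate(nsim, rzoib(nrow(lp), lp$mu, lp$phi,
                                             lp$zoi, lp$coi)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
confint.zoib <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  if (!is.null(object$draws)) {
    post <- posterior_matrix(object$draws)
    ci <- t(apply(post, 2, stats::quantile, probs = c(a, 1 - a)))
  } else {
    z <- stats::qnorm(1 - a)
    ci <- cbind(object$theta - z * object$se, object$theta + z * object$se)
  }
  colnames(ci) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.zoib <- function(object, ...) {
  est <- object$theta
  se <- object$se
  zval <- ifelse(se > 0, est / se, NA_real_)
  tab <- cbind(Estimate = est, `Std.Error` = se, z = zval,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  p <- object$dat$p
  out <- list(call = object$call, method = object$method,
              coefficients = tab[seq_len(4 * p), , drop = FALSE],
              sigma_u = object$coefficients$sigma_u,
              n = object$dat$n, n_zero = sum(object$dat$is0),
              n_one = sum(object$dat$is1), B = object$dat$B,
              rhat = object$rhat, identifiable = object$identifiable)
  class(out) <- "summary.zoib"
  out
}

#' @export
print.summary.zoib <- function(x, ...) {
  cat("Zero-one inflated beta regression (", x$method, ")\n", sep = "")
  cat("n =", x$n, "rows;", x$n_zero, "exact zeros,", x$n_one, "exact ones\n\n")
  stats::printCoefmat(x$coefficients, digits = 4, P.values = TRUE,
                      has.Pvalue = TRUE)
  if (x$B > 0) cat("\nsigma_u =", format(x$sigma_u, digits = 4),
                   "over", x$B, "spatial blocks\n")
  if (!is.null(x$rhat)) {
    cat("split R-hat: max", format(max(x$rhat, na.rm = TRUE), digits = 5), "\n")
  }
  if (!all(x$identifiable)) {
    cat("note: unidentifiable component(s) held fixed:",
        paste(names(x$identifiable)[!x$identifiable], collapse = ", "), "\n")
  }
  invisible(x)
}
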