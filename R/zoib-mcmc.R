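# Adaptive block-wise random-walk Metropolis for the ZOIB posterior.
#
# Chains start from the MAP estimate jittered by one standard error.  The
# parameter vector is updated in natural blocks -- the four regression
# coefficient blocks, and the random effect together with its scale --
# each with a multivariate normal proposal shaped by the corresponding
# inverse-Hessian sub-block.  During burn-in every block's step scale is
# tuned toward the block-optimal acceptance rate and its proposal shape is
# re-estimated from the chain history (Haario-style); adaptation is frozen
# after burn-in so the retained draws come from a fixed-kernel chain.
zoib_fit_mcmc <- function(dat, map, prior_scale, chains = 4, iter = 4000,
                          burn_in = 2000, seed = NULL, control = list()) {
  if (chains < 2) stop("at least 2 chains are required", call. = FALSE)
  if (iter - burn_in < 100) {
    stop("need at least 100 post-burn-in iterations", call. = FALSE)
  }
  free <- map$free
  theta0 <- map$theta
  p <- dat$p
  se0 <- map$se
  Vprop <- map$vcov
  if (isTRUE(map$sigma_fixed) && any(dat$mid)) {
    # MAP profiles u at fixed sigma_u; MCMC samples sigma_u properly
    is_ <- 4 * p + dat$B + 1
    free[is_] <- TRUE
    se0[is_] <- 0.5
    Vprop[is_, is_] <- 0.25
  }

  # parameter blocks (within the free subset)
  block_idx <- list(mu = seq_len(p), phi = p + seq_len(p),
                    zoi = 2 * p + seq_len(p), coi = 3 * p + seq_len(p))
  # the mean intercept trades off against the random-effect level, so it
  # joins the spatial block too (a parameter may sit in several blocks)
  if (dat$B > 0) block_idx$spatial <- c(1L, 4 * p + seq_len(dat$B + 1))
  block_idx <- lapply(block_idx, function(ii) ii[free[ii]])
  block_idx <- block_idx[vapply(block_idx, length, 0L) > 0]
  nb <- length(block_idx)

  chol_psd <- function(S) {
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE)
    lam <- pmax(ev$values, max(ev$values, 1e-12) * 1e-8)
    ev$vectors %*% diag(sqrt(lam), length(lam))
  }
  L0 <- lapply(block_idx, function(ii) {
    chol_psd(Vprop[ii, ii, drop = FALSE])
  })

  target <- function(th) {
    # exact Laplace prior in the MCMC target
    -zoib_nlp_theta(th, dat, prior_scale, smooth_eps = 0)
  }

  adapt_every <- control$adapt_every %||% 50
  accept_target <- control$accept_target %||% 0.3
  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, chains)

  draws <- array(NA_real_, dim = c(chains, iter, length(theta0)),
                 dimnames = list(NULL, NULL, names(theta0)))
  accept <- numeric(chains)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    cur <- theta0
    cur[free] <- cur[free] + se0[free] * stats::rnorm(sum(free))
    lp_cur <- target(cur)
    tries <- 0
    while (!is.finite(lp_cur) && tries < 20) {
      cur <- theta0
      cur[free] <- cur[free] + 0.1 * se0[free] * stats::rnorm(sum(free))
      lp_cur <- target(cur)
      tries <- tries + 1
    }
    if (!is.finite(lp_cur)) {
      stop("could not initialize chain ", ch, " at a finite posterior value",
           call. = FALSE)
    }
    L <- L0
    log_scale <- vapply(block_idx, function(ii) log(2.38 / sqrt(length(ii))),
                        0)
    n_acc <- 0
    n_prop <- 0
    win_acc <- numeric(nb)
    run_sum <- lapply(block_idx, function(ii) numeric(length(ii)))
    run_sq <- lapply(block_idx, function(ii) {
      matrix(0, length(ii), length(ii))
    })
    n_hist <- 0
    # the spatial subspace mixes slowest; give it extra sweeps
    n_sweeps <- ifelse(names(block_idx) == "spatial",
                       control$spatial_sweeps %||% 4, 1)
    for (t in seq_len(iter)) {
      for (b in seq_len(nb)) {
        ii <- block_idx[[b]]
        for (sw in seq_len(n_sweeps[b])) {
          prop <- cur
          prop[ii] <- prop[ii] +
            exp(log_scale[b]) * drop(L[[b]] %*% stats::rnorm(length(ii)))
          lp_prop <- target(prop)
          n_prop <- n_prop + 1
          if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
            cur <- prop
            lp_cur <- lp_prop
            n_acc <- n_acc + 1
            win_acc[b] <- win_acc[b] + 1
          }
        }
      }
      if (t <= burn_in) {
        for (b in seq_len(nb)) {
          ii <- block_idx[[b]]
          run_sum[[b]] <- run_sum[[b]] + cur[ii]
          run_sq[[b]] <- run_sq[[b]] + tcrossprod(cur[ii])
        }
        n_hist <- n_hist + 1
        if (t %% adapt_every == 0) {
          for (b in seq_len(nb)) {
            rate <- win_acc[b] / (adapt_every * n_sweeps[b])
            log_scale[b] <- log_scale[b] + (rate - accept_target) /
              sqrt(t / adapt_every)
            if (n_hist >= 200) {
              mu_h <- run_sum[[b]] / n_hist
              cov_h <- run_sq[[b]] / n_hist - tcrossprod(mu_h)
              cov_h <- cov_h +
                diag(1e-10 + 1e-4 * mean(diag(cov_h)), nrow(cov_h))
              L[[b]] <- chol_psd(cov_h)
            }
          }
          win_acc[] <- 0
        }
      }
      draws[ch, t, ] <- cur
    }
    accept[ch] <- n_acc / n_prop
  }
  if (all(accept == 0)) {
    stop("all proposals rejected in every chain; posterior may be degenerate",
         call. = FALSE)
  }

  structure(
    list(draws = draws, parameter_names = names(theta0), burn_in = burn_in,
         free = free,
         config = list(chains = chains, iter = iter, seed = seed),
         accept = accept),
    class = "zoib_draws")
}

#' @export
print.zoib_draws <- function(x, ...) {
  cat("ZOIB posterior draws:", dim(x$draws)[1], "chains x",
      dim(x$draws)[2], "iterations x", dim(x$draws)[3], "parameters\n")
  cat("burn-in:", x$burn_in, " acceptance rates:",
      paste(format(x$accept, digits = 3), collapse = " "), "\n")
  invisible(x)
}

# Post-burn-in draws flattened to (chain x iteration) rows.
posterior_matrix <- function(draws) {
  stopifnot(inherits(draws, "zoib_draws"))
  keep <- (draws$burn_in + 1):dim(draws$draws)[2]
  d <- draws$draws[, keep, , drop = FALSE]
  out <- matrix(aperm(d, c(2, 1, 3)), ncol = dim(d)[3])
  colnames(out) <- draws$parameter_names
  out
}

#' Split-chain Gelman--Rubin convergence diagnostic
#'
#' Computes the split R-hat statistic for each parameter: every chain's
#' post-burn-in draws are halved, and the potential scale reduction factor
#' `sqrt(V / W)` is formed from the within-half variance `W` and the
#' weighted total-variance estimate `V = (n-1)/n W + B/n`, where `B` is the
#' between-half variance of the means.  Values near 1 indicate that the
#' chains have mixed; the conventional gate is a maximum below 1.05.
#'
#' @param draws posterior draws: the `$draws` component of a
#'   `method = "mcmc"` [zoib()] fit, a 3-d array indexed
#'   `(chain, iteration, parameter)`, or a matrix with one column per chain
#'   for a single parameter.
#' @param burn_in iterations to discard from the start of each chain
#'   (already-discarded draws objects use their stored value).
#' @return named numeric vector of R-hat values; `NA` for parameters with
#'   zero within-chain variance (e.g. parameters held fixed).
#' @export
rhat <- function(draws, burn_in = 0) {
  if (inherits(draws, "zoib_draws")) {
    arr <- draws$draws
    burn_in <- draws$burn_in
  } else if (is.matrix(draws)) {
    # iterations x chains, single parameter
    arr <- array(t(draws), dim = c(ncol(draws), nrow(draws), 1),
                 dimnames = list(NULL, NULL, "par"))
  } else if (is.array(draws) && length(dim(draws)) == 3) {
    arr <- draws
  } else {
    stop("'draws' must be a zoib_draws object, a 3-d array or a matrix",
         call. = FALSE)
  }
  m <- dim(arr)[1]
  if (m < 2) stop("R-hat requires at least 2 chains", call. = FALSE)
  it <- (burn_in + 1):dim(arr)[2]
  if (length(it) < 4) stop("too few post-burn-in iterations", call. = FALSE)

  half <- floor(length(it) / 2)
  idx1 <- it[seq_len(half)]
  idx2 <- it[half + seq_len(half)]

  vapply(seq_len(dim(arr)[3]), function(k) {
    segs <- vector("list", 2 * m)
    for (ch in seq_len(m)) {
      segs[[2 * ch - 1]] <- arr[ch, idx1, k]
      segs[[2 * ch]] <- arr[ch, idx2, k]
    }
    n <- half
    means <- vapply(segs, mean, 0)
    vars <- vapply(segs, stats::var, 0)
    W <- mean(vars)
    if (!is.finite(W) || W == 0) return(NA_real_)
    B <- n * stats::var(means)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0) -> out
  names(out) <- dimnames(arr)[[3]]
  out
}

#' Posterior predictive check for a ZOIB fit
#'
#' Draws `n_rep` parameter vectors from the posterior (or, for MAP fits,
#' from the Gaussian approximation at the mode), simulates a full
#' replicated response for each, and compares summary statistics of the
#' observed response against the replicated envelope.  Summaries are the
#' fraction of exact zeros, the fraction of exact ones, the mean, and the
#' deciles of the interior (strictly between 0 and 1) values.
#'
#' @param object a fitted [zoib()] model.
#' @param n_rep number of replicated datasets (the conventional check uses
#'   100).
#' @param seed integer seed.
#' @return an object of class `"zoib_ppc"`: a list with the replicated
#'   response matrix `yrep` (`n_rep` rows), the observed summaries, the
#'   per-replicate summaries and their central 95% envelope.
#' @export
posterior_predictive <- function(object, n_rep = 100, seed = NULL) {
  stopifnot(inherits(object, "zoib"))
  if (!is.null(seed)) set.seed(seed)
  n <- object$dat$n

  thetas <- if (!is.null(object$draws)) {
    post <- posterior_matrix(object$draws)
    post[sample.int(nrow(post), n_rep, replace = n_rep > nrow(post)), ,
         drop = FALSE]
  } else {
    # Gaussian (Laplace) approximation around the MAP estimate
    free <- !object$fixed
    V <- object$vcov[free, free, drop = FALSE]
    ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), sum(free))
    base <- matrix(object$theta, n_rep, length(object$theta), byrow = TRUE)
    base[, free] <- base[, free] +
      t(L %*% matrix(stats::rnorm(sum(free) * n_rep), sum(free)))
    colnames(base) <- object$parameter_names
    base
  }

  summarize <- function(y) {
    interior <- y[y > 0 & y < 1]
    dec <- if (length(interior) >= 10) {
      stats::quantile(interior, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
    } else rep(NA_real_, 9)
    c(frac_zero = mean(y == 0), frac_one = mean(y == 1), mean = mean(y),
      stats::setNames(dec, paste0("q", seq(10, 90, by = 10))))
  }

  yrep <- matrix(NA_real_, n_rep, n)
  reps <- matrix(NA_real_, n_rep, 12)
  for (r in seq_len(n_rep)) {
    pars <- theta_to_params(thetas[r, ], object$dat, object$prior_scale)
    lp <- zoib_linpred(pars, object$X, object$block)
    yrep[r, ] <- rzoib(n, lp$mu, lp$phi, lp$zoi, lp$coi)
    reps[r, ] <- summarize(yrep[r, ])
  }
  obs <- summarize(object$y)
  colnames(reps) <- names(obs)
  env <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975),
               na.rm = TRUE)
  structure(list(yrep = yrep, observed = obs, replicated = reps,
                 envelope = env, n_rep = n_rep),
            class = "zoib_ppc")
}

#' @export
print.zoib_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$n_rep, " replicates)\n", sep = "")
  tab <- rbind(observed = x$observed, x$envelope)
  print(round(t(tab), 4))
  invisible(x)
}
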