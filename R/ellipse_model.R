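# Standard ellipse estimation in the standardized delta-space.
#
# The bivariate normal standard ellipse (the 1-sd Mahalanobis contour)
# encloses about 40% of the population (exactly 1 - exp(-1/2) for a
# bivariate normal); its area is SEA = pi * sqrt(det(Sigma)). SEAc applies
# the small-sample correction (n-1)/(n-2). SEAb is the posterior
# distribution of SEA under a normal-inverse-Wishart (NIW) model, sampled
# here with a Gibbs sampler that alternates mu | Sigma and Sigma | mu so
# that multi-chain convergence diagnostics (Gelman-Rubin R-hat) apply; a
# "direct" mode draws i.i.d. from the exact conjugate posterior and is
# used as an internal cross-check.

#' Vague normal-inverse-Wishart prior hyperparameters
#'
#' Prior: `Sigma ~ InvWishart(nu0, lambda0)`, `mu | Sigma ~ N(mu0,
#' Sigma/kappa0)`. The defaults are deliberately vague: prior mean at the
#' origin with negligible weight (`kappa0 = 1e-3`), minimal Wishart degrees
#' of freedom (`nu0 = 2` for two dimensions), and a near-zero inverse scale
#' `lambda0 = 1e-3 * I` (equivalently a Wishart scale of `1e3 * I` on the
#' precision), so the posterior is dominated by the data: the posterior
#' expectation of `Sigma` then approaches the sample covariance.
#'
#' @param mu0 Prior mean (length-2).
#' @param kappa0 Prior precision scale on the mean.
#' @param nu0 Inverse-Wishart degrees of freedom.
#' @param lambda0 Inverse-Wishart 2x2 scale matrix.
#' @return A list of class `niw_prior`.
#' @export
niw_prior <- function(mu0 = c(0, 0), kappa0 = 1e-3, nu0 = 2,
                      lambda0 = diag(2) * 1e-3) {
  stopifnot(length(mu0) == 2, kappa0 > 0, nu0 >= 2, is_spd2(lambda0))
  structure(list(mu0 = as.numeric(mu0), kappa0 = kappa0, nu0 = nu0,
                 lambda0 = lambda0), class = "niw_prior")
}

#' MCMC configuration for the ellipse posterior
#'
#' Defaults follow the common configuration for Bayesian ellipse fitting:
#' 3 chains of 20,000 iterations, thinning rate 10, burn-in 1,000 per
#' chain, retaining `(n_iter - burn_in) %/% thin` draws per chain (1,900
#' by default; 5,700 pooled).
#'
#' @param n_chains Number of chains (>= 2 recommended for diagnostics;
#'   single-chain runs are allowed but report no R-hat).
#' @param n_iter Iterations per chain.
#' @param thin Thinning rate (keep every `thin`-th post-burn-in draw).
#' @param burn_in Discarded initial iterations per chain.
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @param prior A [niw_prior()].
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 20000, thin = 10,
                        burn_in = 1000, seed = 1L, prior = niw_prior()) {
  stopifnot(n_chains >= 1, n_iter >= 1, thin >= 1, burn_in >= 0,
            burn_in < n_iter, inherits(prior, "niw_prior"))
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), burn_in = as.integer(burn_in),
                 seed = as.integer(seed), prior = prior),
            class = "mcmc_config")
}

#' Small-sample correction of the standard ellipse area
#'
#' @param sea Standard ellipse area.
#' @param n Sample size (>= 3).
#' @return `sea * (n - 1) / (n - 2)`.
#' @export
seac_correction <- function(sea, n) {
  if (any(n <= 2)) stop("insufficient sample: SEAc needs n >= 3", call. = FALSE)
  sea * (n - 1) / (n - 2)
}

#' Maximum-likelihood standard ellipse fit
#'
#' Fits the sample mean and covariance (n - 1 denominator) of a cloud of
#' points in the standardized delta-space and derives SEA and SEAc.
#'
#' @param points n x 2 matrix (or data.frame) of points.
#' @param group,year Optional labels carried into the fit.
#' @return A list of class `ellipse_fit` with `group`, `year`, `n`,
#'   `mean`, `cov`, `sea`, `seac`.
#' @export
fit_ml_ellipse <- function(points, group = NA_character_, year = NA_integer_) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2) {
    stop("points must be an n x 2 numeric matrix", call. = FALSE)
  }
  n <- nrow(pts)
  if (n < 3) stop("insufficient sample: ellipse fit needs n >= 3", call. = FALSE)
  m <- colMeans(pts)
  S <- stats::cov(pts)
  d <- det2(S)
  if (!is.finite(d) || d <= 1e-300) {
    stop("degenerate geometry: collinear points give a singular covariance",
         call. = FALSE)
  }
  sea <- pi * sqrt(d)
  structure(list(group = group, year = year, n = n, mean = unname(m),
                 cov = unname(S), sea = sea,
                 seac = seac_correction(sea, n)),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("Standard ellipse fit: %s / %s (n = %d)\n",
              x$group, x$year, x$n))
  cat(sprintf("  mean = (%.4f, %.4f)  SEA = %.4f  SEAc = %.4f\n",
              x$mean[1], x$mean[2], x$sea, x$seac))
  invisible(x)
}

# sufficient statistics reused by both samplers
.suffstats <- function(pts) {
  n <- nrow(pts)
  xbar <- colMeans(pts)
  S <- crossprod(sweep(pts, 2, xbar)) # scatter about the sample mean
  list(n = n, xbar = xbar, S = S)
}

# one Gibbs chain; returns a (keep x 6) matrix mu1,mu2,s11,s12,s22,seab
.gibbs_chain <- function(ss, cfg, chain_seed) {
  set.seed(chain_seed)
  pr <- cfg$prior
  n <- ss$n; xbar <- ss$xbar; S <- ss$S
  mu0 <- pr$mu0; k0 <- pr$kappa0; nu0 <- pr$nu0; L0 <- pr$lambda0
  kn <- k0 + n
  mn1 <- (k0 * mu0[1] + n * xbar[1]) / kn
  mn2 <- (k0 * mu0[2] + n * xbar[2]) / kn
  # overdispersed start: sample covariance inflated/deflated by a seeded
  # lognormal factor, so chains begin in visibly different states
  Sg <- (S / (n - 1)) * exp(stats::rnorm(1, 0, 0.4))
  keep <- (cfg$n_iter - cfg$burn_in) %/% cfg$thin
  out <- matrix(NA_real_, keep, 6)
  j <- 0L
  dfc <- nu0 + n + 1
  for (i in seq_len(cfg$n_iter)) {
    # mu | Sigma : N(mu_n, Sigma / kappa_n), via the 2x2 Cholesky factor
    a <- Sg[1, 1] / kn; b <- Sg[1, 2] / kn; cc <- Sg[2, 2] / kn
    l11 <- sqrt(a); l21 <- b / l11
    l22 <- sqrt(max(cc - l21 * l21, 1e-300))
    z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
    mu1 <- mn1 + l11 * z1
    mu2 <- mn2 + l21 * z1 + l22 * z2
    # Sigma | mu : InvWishart(nu0 + n + 1, Lambda0 + S_mu + k0 (mu-mu0)(mu-mu0)')
    d1 <- xbar[1] - mu1; d2 <- xbar[2] - mu2
    e1 <- mu1 - mu0[1]; e2 <- mu2 - mu0[2]
    A11 <- L0[1, 1] + S[1, 1] + n * d1 * d1 + k0 * e1 * e1
    A12 <- L0[1, 2] + S[1, 2] + n * d1 * d2 + k0 * e1 * e2
    A22 <- L0[2, 2] + S[2, 2] + n * d2 * d2 + k0 * e2 * e2
    detA <- A11 * A22 - A12 * A12
    Ainv <- matrix(c(A22, -A12, -A12, A11), 2, 2) / detA
    ok <- FALSE
    for (try in 1:10) {
      W <- stats::rWishart(1, dfc, Ainv)[, , 1]
      detW <- W[1, 1] * W[2, 2] - W[1, 2]^2
      if (is.finite(detW) && detW > 0 && W[1, 1] > 0) { ok <- TRUE; break }
    }
    if (!ok) stop("sampler error: persistent non-positive-definite draw",
                  call. = FALSE)
    Sg <- matrix(c(W[2, 2], -W[1, 2], -W[1, 2], W[1, 1]), 2, 2) / detW
    if (i > cfg$burn_in && (i - cfg$burn_in) %% cfg$thin == 0L) {
      j <- j + 1L
      dS <- Sg[1, 1] * Sg[2, 2] - Sg[1, 2]^2
      out[j, ] <- c(mu1, mu2, Sg[1, 1], Sg[1, 2], Sg[2, 2], pi * sqrt(dS))
    }
  }
  out
}

# i.i.d. draws from the exact conjugate NIW posterior (same keep count)
.direct_chain <- function(ss, cfg, chain_seed) {
  set.seed(chain_seed)
  pr <- cfg$prior
  n <- ss$n; xbar <- ss$xbar; S <- ss$S
  k0 <- pr$kappa0; kn <- k0 + n
  mun <- (k0 * pr$mu0 + n * xbar) / kn
  nun <- pr$nu0 + n
  dev <- xbar - pr$mu0
  Ln <- pr$lambda0 + S + (k0 * n / kn) * tcrossprod(dev)
  Lninv <- matrix(c(Ln[2, 2], -Ln[1, 2], -Ln[1, 2], Ln[1, 1]), 2, 2) / det2(Ln)
  keep <- (cfg$n_iter - cfg$burn_in) %/% cfg$thin
  out <- matrix(NA_real_, keep, 6)
  for (j in seq_len(keep)) {
    W <- stats::rWishart(1, nun, Lninv)[, , 1]
    detW <- W[1, 1] * W[2, 2] - W[1, 2]^2
    Sg <- matrix(c(W[2, 2], -W[1, 2], -W[1, 2], W[1, 1]), 2, 2) / detW
    a <- Sg[1, 1] / kn; b <- Sg[1, 2] / kn; cc <- Sg[2, 2] / kn
    l11 <- sqrt(a); l21 <- b / l11
    l22 <- sqrt(max(cc - l21 * l21, 1e-300))
    z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
    dS <- Sg[1, 1] * Sg[2, 2] - Sg[1, 2]^2
    out[j, ] <- c(mun[1] + l11 * z1, mun[2] + l21 * z1 + l22 * z2,
                  Sg[1, 1], Sg[1, 2], Sg[2, 2], pi * sqrt(dS))
  }
  out
}

# closed-form posterior expectation of Sigma under the conjugate NIW model
# (available as an analytic oracle for the samplers)
niw_posterior_mean_cov <- function(points, prior = niw_prior()) {
  ss <- .suffstats(as.matrix(points))
  k0 <- prior$kappa0; n <- ss$n
  dev <- ss$xbar - prior$mu0
  Ln <- prior$lambda0 + ss$S + (k0 * n / (k0 + n)) * tcrossprod(dev)
  nun <- prior$nu0 + n
  if (nun <= 3) stop("posterior mean of Sigma undefined for nu_n <= p + 1",
                     call. = FALSE)
  Ln / (nun - 3)
}

#' Sample the Bayesian standard ellipse posterior
#'
#' Draws from the posterior of (mean, covariance) of a bivariate normal
#' model under a vague normal-inverse-Wishart prior and derives the SEAb
#' area draw `pi * sqrt(det(Sigma))` for each retained sample. The default
#' `"gibbs"` method alternates the full conditionals mu | Sigma and
#' Sigma | mu from overdispersed chain starts, so R-hat diagnostics across
#' chains are meaningful; `"direct"` draws i.i.d. from the exact conjugate
#' posterior (same retained-draw accounting) and serves as a cross-check.
#'
#' With `n_chains >= 2`, Gelman-Rubin R-hat is computed for `log(SEAb)`
#' and both mean coordinates.
#'
#' @param points n x 2 matrix of (standardized) isotope coordinates, n >= 3.
#' @param config An [mcmc_config()].
#' @param group,year Optional labels.
#' @param method `"gibbs"` (default) or `"direct"`.
#' @return A list of class `posterior_sample`: `draws` is a data.frame with
#'   columns `chain, draw, mu1, mu2, s11, s12, s22, seab` (ordered by chain
#'   then draw index), `rhat` a named vector (NA for single-chain runs).
#' @export
sample_posterior <- function(points, config = mcmc_config(),
                             group = NA_character_, year = NA_integer_,
                             method = c("gibbs", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "mcmc_config"))
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2) {
    stop("points must be an n x 2 numeric matrix", call. = FALSE)
  }
  if (nrow(pts) < 3) {
    stop("insufficient sample: posterior needs n >= 3", call. = FALSE)
  }
  ss <- .suffstats(pts)
  if (det2(ss$S) <= 1e-300) {
    stop("degenerate geometry: collinear points", call. = FALSE)
  }
  chain_fun <- if (method == "gibbs") .gibbs_chain else .direct_chain
  keep <- (config$n_iter - config$burn_in) %/% config$thin
  if (keep < 1) stop("config retains no draws", call. = FALSE)
  chains <- lapply(seq_len(config$n_chains), function(k) {
    chain_fun(ss, config, mix_seed(config$seed, "chain", k))
  })
  draws <- do.call(rbind, lapply(seq_along(chains), function(k) {
    data.frame(chain = k, draw = seq_len(keep),
               mu1 = chains[[k]][, 1], mu2 = chains[[k]][, 2],
               s11 = chains[[k]][, 3], s12 = chains[[k]][, 4],
               s22 = chains[[k]][, 5], seab = chains[[k]][, 6])
  }))
  rhat <- c(log_seab = NA_real_, mu1 = NA_real_, mu2 = NA_real_)
  if (config$n_chains >= 2 && keep >= 10) {
    rhat["log_seab"] <- gelman_rubin(lapply(chains, function(m) log(m[, 6])))
    rhat["mu1"] <- gelman_rubin(lapply(chains, function(m) m[, 1]))
    rhat["mu2"] <- gelman_rubin(lapply(chains, function(m) m[, 2]))
  }
  structure(list(group = group, year = year, n = ss$n, method = method,
                 draws = draws, rhat = rhat, config = config),
            class = "posterior_sample")
}

#' Pooled SEAb area draws of a posterior sample
#'
#' @param posterior A [sample_posterior()] result.
#' @return Numeric vector of SEAb draws pooled across chains, ordered by
#'   chain then retained-draw index.
#' @export
seab_draws <- function(posterior) {
  stopifnot(inherits(posterior, "posterior_sample"))
  posterior$draws$seab
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-part variance form: with m chains of length n, within-chain
#' variance `W = mean_j var(chain_j)`, between-chain variance `B/n =
#' var_j(mean(chain_j))`, pooled estimate `V = ((n - 1)/n) W + B/n`, and
#' R-hat = `sqrt(V / W)`. Values near 1 indicate convergence; above 1.1 is
#' conventionally flagged.
#'
#' @param chains A list of >= 2 equal-length numeric vectors (length >= 10),
#'   or a matrix with one chain per column.
#' @return The scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2) {
    stop("need at least 2 chains", call. = FALSE)
  }
  lens <- vapply(chains, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("chains of unequal length", call. = FALSE)
  }
  n <- lens[1]
  if (n < 10) stop("chains too short (need length >= 10)", call. = FALSE)
  means <- vapply(chains, mean, numeric(1))
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B_over_n <- stats::var(means)
  V <- (n - 1) / n * W + B_over_n
  sqrt(V / W)
}

#' Parametric boundary of a covariance ellipse
#'
#' Points `center + scale * L (cos t, sin t)'` with `L` the lower Cholesky
#' factor of `cov`; at `scale = 1` the enclosed region is the standard
#' ellipse (the 1-sd Mahalanobis contour), which for a bivariate normal
#' contains a fraction `1 - exp(-1/2)` (about 39.35%) of the population.
#'
#' @param center Length-2 center.
#' @param cov 2x2 symmetric positive-definite matrix.
#' @param scale Radius multiplier (> 0).
#' @param n_points Number of boundary points (default 360).
#' @return An `n_points` x 2 matrix of ordered boundary coordinates.
#' @export
ellipse_boundary <- function(center, cov, scale = 1, n_points = 360) {
  stopifnot(length(center) == 2, scale > 0, n_points >= 3)
  if (!is_spd2(cov)) {
    stop("degenerate geometry: cov must be symmetric positive-definite",
         call. = FALSE)
  }
  L <- t(chol(cov))
  t <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  circ <- rbind(cos(t), sin(t))
  out <- t(center + scale * (L %*% circ))
  colnames(out) <- c("x", "y")
  out
}

#' Membership test for a covariance ellipse
#'
#' @param points n x 2 matrix of query points.
#' @param center Length-2 ellipse center.
#' @param cov 2x2 symmetric positive-definite matrix.
#' @param scale Radius multiplier; the scale-1 ellipse is the standard ellipse.
#' @return Logical vector: squared Mahalanobis distance `<= scale^2`.
#' @export
ellipse_contains <- function(points, center, cov, scale = 1) {
  if (!is_spd2(cov)) stop("cov must be symmetric positive-definite", call. = FALSE)
  d2 <- stats::mahalanobis(as.matrix(points), center, cov)
  d2 <= scale^2
}
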