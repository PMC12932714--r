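test_that("the ML ellipse matches the hand-computed triangle fixture", {
  f <- fit_ml_ellipse(tri_points(), "tri", 2014L)
  expect_equal(f$mean, c(1, 1) / 3)
  expect_equal(f$cov, matrix(c(1 / 3, -1 / 6, -1 / 6, 1 / 3), 2), tolerance = 1e-12)
  expect_equal(f$sea, pi / sqrt(12), tolerance = 1e-12)
  expect_equal(f$seac, 2 * f$sea) # n = 3 doubles the area
  expect_equal(f$seac, pi / sqrt(3), tolerance = 1e-12)
})

test_that("SEA is invariant under rigid motions and scales quadratically", {
  set.seed(31)
  pts <- rmvn2(40, c(-27, 10), matrix(c(2, 0.7, 0.7, 1.2), 2))
  sea0 <- fit_ml_ellipse(pts)$sea
  for (th in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(fit_ml_ellipse(pts %*% t(R))$sea, sea0, tolerance = 1e-10)
  }
  expect_equal(fit_ml_ellipse(sweep(pts, 2, c(100, -50), `+`))$sea, sea0,
               tolerance = 1e-10)
  expect_equal(fit_ml_ellipse(pts * 3)$sea, 9 * sea0, tolerance = 1e-10)
})

test_that("SEA of a large circular-normal sample approaches pi", {
  set.seed(99)
  pts <- matrix(rnorm(2 * 10000), ncol = 2)
  expect_equal(fit_ml_ellipse(pts)$sea, pi, tolerance = 0.05)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_ml_ellipse(tri_points()[1:2, ]), "insufficient sample")
  line <- cbind(1:5, 2 * (1:5) + 1)
  expect_error(fit_ml_ellipse(line), "degenerate geometry")
  expect_error(seac_correction(1, 2), "insufficient sample")
})

test_that("the SEAc correction is (n-1)/(n-2) and vanishes with n", {
  expect_equal(seac_correction(1, 3), 2)
  expect_equal(seac_correction(pi, 102), pi * 101 / 100)
  ns <- c(3, 5, 10, 50, 1000)
  ratios <- seac_correction(1, ns)
  expect_true(all(diff(ratios) < 0))
  expect_equal(seac_correction(1, 1e6), 1, tolerance = 1e-5)
})

test_that("retained-draw accounting holds for any configuration", {
  set.seed(8)
  pts <- rmvn2(20, c(0, 0), diag(2))
  grid <- expand.grid(n_iter = c(57, 100, 203), thin = c(1, 3, 10),
                      burn_in = c(0, 11, 50))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- mcmc_config(n_chains = 2, n_iter = g$n_iter, thin = g$thin,
                       burn_in = g$burn_in, seed = 4)
    expected <- (g$n_iter - g$burn_in) %/% g$thin
    if (expected < 1) next
    ps <- sample_posterior(pts, cfg, method = "direct")
    expect_equal(nrow(ps$draws), 2 * expected)
    expect_equal(max(ps$draws$draw), expected)
  }
})

test_that("identical seed and config give bit-identical chains", {
  set.seed(12)
  pts <- rmvn2(30, c(1, 2), matrix(c(1.5, 0.3, 0.3, 0.8), 2))
  cfg <- mcmc_config(n_chains = 3, n_iter = 800, thin = 4, burn_in = 100,
                     seed = 77)
  a <- sample_posterior(pts, cfg)
  b <- sample_posterior(pts, cfg)
  expect_identical(a$draws, b$draws)
  # and a different seed gives different draws
  cfg2 <- mcmc_config(n_chains = 3, n_iter = 800, thin = 4, burn_in = 100,
                      seed = 78)
  expect_false(identical(sample_posterior(pts, cfg2)$draws, a$draws))
})

test_that("the posterior recovers a known generating area", {
  Sigma <- matrix(c(2, 0.5, 0.5, 1.5), 2)
  true_area <- pi * sqrt(det(Sigma)) # 5.21
  medians <- vapply(1:3, function(s) {
    set.seed(100 + s)
    pts <- rmvn2(200, c(0, 0), Sigma)
    ps <- sample_posterior(pts, mcmc_config(n_chains = 2, n_iter = 3000,
                                            thin = 5, burn_in = 300,
                                            seed = s))
    median(seab_draws(ps))
  }, numeric(1))
  expect_true(all(abs(medians / true_area - 1) < 0.10))
})

test_that("posterior spread shrinks and centres as n grows", {
  Sigma <- matrix(c(1.4, -0.3, -0.3, 0.9), 2)
  true_area <- pi * sqrt(det(Sigma))
  stat <- function(n, s) {
    set.seed(500 + s)
    pts <- rmvn2(n, c(0, 0), Sigma)
    d <- seab_draws(sample_posterior(pts, mcmc_config(
      n_chains = 1, n_iter = 2500, thin = 5, burn_in = 500, seed = s)))
    c(iqr = unname(diff(quantile(d, c(0.25, 0.75)))),
      err = abs(log(median(d) / true_area)))
  }
  small <- vapply(1:3, function(s) stat(200, s), numeric(2))
  large <- vapply(1:3, function(s) stat(2000, s), numeric(2))
  expect_lt(mean(large["iqr", ]), mean(small["iqr", ]))
  expect_lt(mean(large["err", ]), mean(small["err", ]))
})

test_that("direct conjugate draws agree with the closed-form posterior mean", {
  set.seed(21)
  pts <- rmvn2(80, c(-1, 3), matrix(c(1.2, 0.4, 0.4, 2.1), 2))
  ps <- sample_posterior(pts, mcmc_config(n_chains = 1, n_iter = 40000,
                                          thin = 2, burn_in = 0, seed = 5),
                         method = "direct")
  oracle <- isoellipse:::niw_posterior_mean_cov(pts)
  sc <- sqrt(oracle[1, 1] * oracle[2, 2])
  expect_equal(mean(ps$draws$s11), oracle[1, 1], tolerance = 0.02)
  expect_equal(mean(ps$draws$s22), oracle[2, 2], tolerance = 0.02)
  expect_lt(abs(mean(ps$draws$s12) - oracle[1, 2]) / sc, 0.02)
})

test_that("Gelman-Rubin separates converged from diverged chains", {
  set.seed(40)
  conv <- lapply(1:3, function(i) rnorm(5000))
  expect_lt(gelman_rubin(conv), 1.05)
  div <- list(rnorm(100, 0, 0.01), rnorm(100, 100, 0.01))
  expect_gt(gelman_rubin(div), 50)
  expect_error(gelman_rubin(list(rnorm(50), rnorm(49))), "unequal length")
  expect_error(gelman_rubin(list(rnorm(50))), "at least 2 chains")
})

test_that("Gelman-Rubin matches an independent implementation of the PSRF", {
  # independent oracle: same between/within-variance form, written from
  # scratch on the chain matrix
  psrf_oracle <- function(mat) {
    n <- nrow(mat); m <- ncol(mat)
    W <- mean(apply(mat, 2, var))
    B <- n * var(colMeans(mat))
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  set.seed(61)
  mat <- cbind(rnorm(200, 0, 1), rnorm(200, 0.3, 1.2), rnorm(200, -0.2, 0.9))
  expect_equal(gelman_rubin(mat), psrf_oracle(mat), tolerance = 1e-6)
})

test_that("ellipse boundaries have the right shape and enclosed area", {
  b <- ellipse_boundary(c(0, 0), diag(2), scale = 1, n_points = 128)
  expect_equal(sqrt(rowSums(b^2)), rep(1, 128), tolerance = 1e-12)

  cov <- matrix(c(2, 0.6, 0.6, 1.1), 2)
  for (sc in c(1, 2.45)) {
    poly <- ellipse_boundary(c(3, -2), cov, scale = sc, n_points = 10000)
    expect_equal(shoelace(poly), pi * sc^2 * sqrt(det(cov)), tolerance = 1e-6)
  }
  expect_error(ellipse_boundary(c(0, 0), matrix(c(1, 1, 1, 1), 2)),
               "positive-definite")
})
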