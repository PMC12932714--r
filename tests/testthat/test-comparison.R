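test_that("prob_less is a strict paired proportion", {
  expect_equal(prob_less(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(prob_less(c(4, 5, 6), c(1, 2, 3)), 0)
  expect_equal(prob_less(c(1, 2, 3), c(1, 2, 3)), 0) # ties count as neither
  expect_error(prob_less(1:4, 1:5), "unequal length")
  expect_error(prob_less(numeric(0), numeric(0)), "empty")

  set.seed(314)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_equal(prob_less(a, b), 0.5, tolerance = 0.02)
})

test_that("prob_less is antisymmetric without ties", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- rlnorm(500); b <- rlnorm(500)
    expect_equal(prob_less(a, b), 1 - prob_less(b, a))
  }
})

test_that("SEAc ratios divide by the reference year", {
  fits <- Map(function(y, s) structure(list(year = y, seac = s),
                                       class = "ellipse_fit"),
              list(2014L, 2015L, 2016L), list(2.0, 3.7, 3.1))
  r <- seac_ratio(fits, 2014)
  expect_equal(unname(r), c(1, 1.85, 1.55))
  expect_equal(names(r), c("2014", "2015", "2016"))
  expect_equal(unname(seac_ratio(fits[1], 2014)), 1)
  expect_error(seac_ratio(fits, 2013), "reference year 2013 not present")
})

test_that("the KDE posterior mode finds known density modes", {
  expect_equal(posterior_mode(rep(4.2, 200)), 4.2)

  set.seed(11)
  mu <- 0; sg <- 0.5
  draws <- rlnorm(1e5, mu, sg)
  expect_equal(posterior_mode(draws), exp(mu - sg^2), tolerance = 0.05)

  set.seed(12)
  sym <- rnorm(2e5, 10, 2)
  expect_lt(abs(posterior_mode(sym) - median(sym)), 0.1 * sd(sym))
  expect_error(posterior_mode(rnorm(50)), "at least 100")
})

test_that("highest-density intervals have the right mass and nest", {
  set.seed(5)
  u <- runif(1e6)
  ci <- credible_intervals(u, 0.95)
  expect_equal(ci$hi - ci$lo, 0.95, tolerance = 0.005)

  nrm <- rnorm(2e5)
  hdi <- credible_intervals(nrm, c(0.5, 0.75, 0.95))
  eti <- credible_intervals(nrm, c(0.5, 0.75, 0.95), method = "eti")
  expect_equal(hdi$lo, eti$lo, tolerance = 0.05)
  expect_equal(hdi$hi, eti$hi, tolerance = 0.05)
  # nesting on an arbitrary skewed fixture
  sk <- rlnorm(5e4)
  ci <- credible_intervals(sk, c(0.5, 0.75, 0.95))
  expect_true(all(diff(ci$lo) <= 0) && all(diff(ci$hi) >= 0))
  expect_error(credible_intervals(nrm, 1.2), "inside \\(0, 1\\)")
})

# small helper: posterior draws for one synthetic year
.year_posterior <- function(area, year, n, seed, method = "gibbs",
                            n_iter = 3000, chains = 2) {
  s <- group_year_spec("g", "omnivore", year, c(0, 0), area,
                       eccentricity = 1.2, angle = 0.3, n = n)
  g <- generate_group_year(s, seed)
  list(fit = fit_ml_ellipse(g$points, "g", year),
       post = sample_posterior(g$points,
         mcmc_config(n_chains = chains, n_iter = n_iter, thin = 5,
                     burn_in = 300, seed = seed + 1), "g", year,
         method = method))
}

test_that("build_report recovers a strong area effect and the null", {
  yrs <- 2014:2016
  out <- Map(function(a, y, s) .year_posterior(a, y, 50, s),
             c(1, 4, 1), yrs, c(21, 22, 23))
  fits <- lapply(out, `[[`, "fit")
  posts <- lapply(out, `[[`, "post")
  rep <- build_report(posts, fits, 2014, group = "g")
  expect_equal(rep$per_year$seac_ratio[1], 1)
  pw <- rep$pairwise
  expect_gt(pw$p_a_less_b[pw$year_a == 2014 & pw$year_b == 2015], 0.9)
  expect_lt(pw$p_a_less_b[pw$year_a == 2015 & pw$year_b == 2016], 0.1)
  # intervals populated and nested
  expect_true(all(rep$per_year$hdi50_lo >= rep$per_year$hdi95_lo))
  expect_true(all(rep$per_year$hdi50_hi <= rep$per_year$hdi95_hi))
  expect_true(all(rep$per_year$seab_mode > 0))

  # identical data in every year: ratios exactly 1, probabilities mild
  s <- group_year_spec("g", "omnivore", 2014, c(0, 0), 2, n = 60)
  pts <- generate_group_year(s, 9)$points
  fits0 <- lapply(yrs, function(y) fit_ml_ellipse(pts, "g", y))
  posts0 <- lapply(seq_along(yrs), function(i) {
    sample_posterior(pts, mcmc_config(n_chains = 2, n_iter = 3000, thin = 5,
                                      burn_in = 300, seed = 40 + i),
                     "g", yrs[i])
  })
  rep0 <- build_report(posts0, fits0, 2014, group = "g")
  expect_equal(rep0$per_year$seac_ratio, rep(1, 3))
  expect_true(all(abs(rep0$pairwise$p_a_less_b - 0.5) < 0.1))
})

test_that("build_report flags a year with no posterior and keeps the rest", {
  out <- Map(function(a, y, s) .year_posterior(a, y, 30, s, n_iter = 1500),
             c(1, 1, 1), 2014:2016, c(31, 32, 33))
  fits <- lapply(out, `[[`, "fit")
  posts <- lapply(out[1:2], `[[`, "post")
  rep <- build_report(posts, fits, 2014, group = "g")
  expect_match(rep$gaps, "no posterior for year 2016")
  expect_equal(nrow(rep$pairwise), 1)
  expect_equal(nrow(rep$per_year), 3)
  expect_true(is.na(rep$per_year$seab_mode[rep$per_year$year == 2016]))
  expect_error(build_report(posts[1], fits[1], 2014), "at least 2 years")
})

test_that("detection probability grows with the true area ratio", {
  ratios <- c(1.25, 2, 5)
  mean_p <- vapply(ratios, function(r) {
    mean(vapply(1:5, function(s) {
      a <- .year_posterior(1, 2014, 50, 1000 * s, method = "direct",
                          n_iter = 2000, chains = 1)
      b <- .year_posterior(r, 2015, 50, 2000 * s, method = "direct",
                          n_iter = 2000, chains = 1)
      prob_less(seab_draws(a$post), seab_draws(b$post))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_p) > 0))
  expect_gt(mean_p[3], 0.95)
})
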