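# Shared fixtures built in code.

# random valid isotope records (consumers of several groups + baseline)
random_records <- function(n_consumer = 20, n_baseline = 5, years = 2014:2015,
                           seed = 1) {
  set.seed(seed)
  guilds <- setdiff(guild_levels(), "baseline")
  cons <- data.frame(
    record_id = sprintf("c%03d", seq_len(n_consumer)),
    group = sample(c("perch", "roach", "crayfish"), n_consumer, replace = TRUE),
    guild = sample(guilds, n_consumer, replace = TRUE),
    year = sample(years, n_consumer, replace = TRUE),
    d13C = rnorm(n_consumer, -27, 2),
    d15N = rnorm(n_consumer, 10, 1.5),
    stringsAsFactors = FALSE)
  base <- data.frame(
    record_id = sprintf("b%03d", seq_len(n_baseline * length(years))),
    group = "baseline", guild = "baseline",
    year = rep(years, each = n_baseline),
    d13C = rnorm(n_baseline * length(years), -29, 0.5),
    d15N = rnorm(n_baseline * length(years), 6, 0.5),
    stringsAsFactors = FALSE)
  rbind(cons, base)
}

# the hand-computable right-triangle fixture
tri_points <- function() rbind(c(0, 0), c(1, 0), c(0, 1))

# draws from a bivariate normal, independent of the package's generator
rmvn2 <- function(n, mean, Sigma) {
  z <- matrix(rnorm(2 * n), n, 2)
  sweep(z %*% chol(Sigma), 2, mean, `+`)
}

# shoelace polygon area (oracle for ellipse_boundary)
shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

quiet_units <- function(...) suppressWarnings(fit_units(...))
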