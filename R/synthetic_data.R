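# Synthetic datasets with the statistical structure the ellipse model
# assumes: each consumer group-year is a bivariate normal cluster in raw
# delta-space with a prescribed standard ellipse area, shape and
# orientation, plus a univariate-normal baseline guild per year. The
# default template mirrors a three-year reservoir study: five consumer
# groups (two fish, one crayfish, two zoobenthos guilds) with group totals
# 19/23/29/20/14 split as evenly as possible across the years, and
# between-year area trajectories spanning roughly x0.02 to x4.5.

#' Covariance matrix with prescribed ellipse area, shape and orientation
#'
#' Builds the 2x2 SPD matrix whose standard ellipse has area
#' `pi * sqrt(det)` equal to `area`, major/minor axis ratio equal to
#' `eccentricity` (so the eigenvalue ratio is `eccentricity^2`), and major
#' axis rotated by `angle` radians.
#'
#' @param area Target standard ellipse area (> 0).
#' @param eccentricity Major/minor axis ratio (>= 1).
#' @param angle Orientation of the major axis in radians.
#' @return A 2x2 symmetric positive-definite matrix.
#' @export
make_sigma <- function(area, eccentricity = 1, angle = 0) {
  stopifnot(is.numeric(area), area > 0, eccentricity >= 1)
  r <- area / pi
  l1 <- r * eccentricity
  l2 <- r / eccentricity
  ca <- cos(angle); sa <- sin(angle)
  R <- matrix(c(ca, sa, -sa, ca), 2, 2)
  R %*% diag(c(l1, l2)) %*% t(R)
}

#' Specification of one consumer group-year cluster
#'
#' @param group,guild,year Labels (guild one of the consumer guilds).
#' @param mean Length-2 cluster mean in raw delta units (d13C, d15N).
#' @param area Target standard ellipse area (> 0).
#' @param eccentricity Major/minor axis ratio (>= 1).
#' @param angle Orientation in radians.
#' @param n Sample size (>= 3).
#' @return A list of class `group_year_spec`.
#' @export
group_year_spec <- function(group, guild, year, mean, area,
                            eccentricity = 1, angle = 0, n) {
  stopifnot(guild %in% setdiff(guild_levels(), "baseline"),
            length(mean) == 2, area > 0, eccentricity >= 1, n >= 3)
  structure(list(group = group, guild = guild, year = as.integer(year),
                 mean = as.numeric(mean), area = area,
                 eccentricity = eccentricity, angle = angle,
                 n = as.integer(n)),
            class = "group_year_spec")
}

#' Specification of one year's baseline records
#'
#' Baseline d15N is univariate normal; d13C is uniform over a stated range
#' (baseline carbon never enters the standardization formulas, which use
#' consumer carbon and baseline nitrogen only).
#'
#' @param year Calendar year.
#' @param mean_d15N,sd_d15N Baseline nitrogen mean and sd (per mil).
#' @param n Number of baseline records (>= 1).
#' @param d13C_range Length-2 range for uniform baseline carbon.
#' @return A list of class `baseline_year_spec`.
#' @export
baseline_year_spec <- function(year, mean_d15N, sd_d15N = 0.5, n = 5,
                               d13C_range = c(-31, -27)) {
  stopifnot(sd_d15N >= 0, n >= 1, length(d13C_range) == 2,
            d13C_range[1] < d13C_range[2])
  structure(list(year = as.integer(year), mean_d15N = mean_d15N,
                 sd_d15N = sd_d15N, n = as.integer(n),
                 d13C_range = as.numeric(d13C_range)),
            class = "baseline_year_spec")
}

#' Full study specification
#'
#' @param consumers List of [group_year_spec()].
#' @param baselines List of [baseline_year_spec()]; every consumer year
#'   must have one.
#' @param seed Master seed; per-group-year seeds are derived from it by a
#'   stable string hash, so changing one cluster's spec leaves all other
#'   clusters' records bit-identical.
#' @return A list of class `study_spec`.
#' @export
study_spec <- function(consumers, baselines, seed = 1L) {
  stopifnot(length(consumers) > 0, length(baselines) > 0)
  cyears <- unique(vapply(consumers, function(s) s$year, integer(1)))
  byears <- vapply(baselines, function(s) s$year, integer(1))
  miss <- setdiff(cyears, byears)
  if (length(miss) > 0) {
    stop("missing baseline spec for consumer year(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(list(consumers = consumers, baselines = baselines,
                 seed = as.integer(seed)),
            class = "study_spec")
}

#' Generate one group-year cluster
#'
#' Draws `n` points `mean + L z` with `L` the lower Cholesky factor of
#' [make_sigma()] and `z` standard bivariate normal; fully reproducible
#' from `seed`.
#'
#' @param spec A [group_year_spec()].
#' @param seed Integer seed.
#' @return A list with `points` (n x 2 matrix) and `records` (data.frame
#'   in [iso_dataset()] column layout).
#' @export
generate_group_year <- function(spec, seed) {
  stopifnot(inherits(spec, "group_year_spec"))
  set.seed(seed)
  Sigma <- make_sigma(spec$area, spec$eccentricity, spec$angle)
  L <- t(chol(Sigma))
  z <- matrix(stats::rnorm(2 * spec$n), nrow = 2)
  pts <- t(spec$mean + L %*% z)
  colnames(pts) <- c("d13C", "d15N")
  id_stub <- gsub("[^A-Za-z0-9]+", "_", spec$group)
  records <- data.frame(
    record_id = sprintf("%s_%d_%03d", id_stub, spec$year, seq_len(spec$n)),
    group = spec$group, guild = spec$guild, year = spec$year,
    d13C = pts[, 1], d15N = pts[, 2], stringsAsFactors = FALSE)
  list(points = pts, records = records)
}

generate_baseline_year <- function(bspec, seed) {
  set.seed(seed)
  d15N <- stats::rnorm(bspec$n, bspec$mean_d15N, bspec$sd_d15N)
  d13C <- stats::runif(bspec$n, bspec$d13C_range[1], bspec$d13C_range[2])
  data.frame(
    record_id = sprintf("baseline_%d_%03d", bspec$year, seq_len(bspec$n)),
    group = "baseline", guild = "baseline", year = bspec$year,
    d13C = d13C, d15N = d15N, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study dataset
#'
#' @param spec A [study_spec()].
#' @return An [iso_dataset()] with consumer and baseline records for all
#'   years (provenance `"synthetic"`).
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  cons <- lapply(spec$consumers, function(s) {
    generate_group_year(s, mix_seed(spec$seed, "consumer", s$group, s$year))$records
  })
  base <- lapply(spec$baselines, function(b) {
    generate_baseline_year(b, mix_seed(spec$seed, "baseline", b$year))
  })
  iso_dataset(do.call(rbind, c(cons, base)), provenance = "synthetic")
}

#' Default study template: five consumer groups over three years
#'
#' A synthetic stand-in for a three-year reservoir food-web survey:
#' predatory fish (perch, total n = 19), omnivorous fish (roach, n = 23),
#' omnivorous crayfish (n = 29), predatory zoobenthos (n = 20) and
#' detritivorous zoobenthos (n = 14), with totals split as evenly as
#' possible across 2014-2016 and a mollusc-like baseline guild each year.
#' Between-year area trajectories reproduce the qualitative study pattern:
#' the predatory fish niche grows across years, the omnivorous fish niche
#' shrinks, the crayfish niche peaks in the drawdown year, and both
#' zoobenthos niches collapse after the first year.
#'
#' @param seed Master seed for [study_spec()].
#' @param n_scale Multiplier applied to every sample size (useful for
#'   large-n recovery checks).
#' @return A [study_spec()].
#' @export
default_study_spec <- function(seed = 1L, n_scale = 1) {
  years <- 2014:2016
  tmpl <- list(
    list(group = "perch", guild = "predator", mean = c(-27.0, 12.0),
         base_area = 2.0, ratios = c(1, 1.85, 4.46), ecc = 1.6,
         angle = 0.4, n = c(7, 6, 6)),
    list(group = "roach", guild = "omnivore", mean = c(-28.0, 10.0),
         base_area = 4.0, ratios = c(1, 0.27, 0.25), ecc = 1.4,
         angle = -0.3, n = c(8, 8, 7)),
    list(group = "crayfish", guild = "omnivore", mean = c(-26.5, 9.0),
         base_area = 1.2, ratios = c(1, 3.51, 1.55), ecc = 1.8,
         angle = 0.8, n = c(10, 10, 9)),
    list(group = "predatory_zoobenthos", guild = "predator",
         mean = c(-27.5, 10.5), base_area = 2.5, ratios = c(1, 0.08, 0.20),
         ecc = 1.5, angle = 0.2, n = c(7, 7, 6)),
    list(group = "detritivorous_zoobenthos", guild = "detritivore",
         mean = c(-28.5, 8.5), base_area = 2.0, ratios = c(1, 0.12, 0.02),
         ecc = 1.3, angle = -0.5, n = c(5, 5, 4)))
  consumers <- list()
  for (g in tmpl) {
    for (i in seq_along(years)) {
      consumers[[length(consumers) + 1]] <- group_year_spec(
        group = g$group, guild = g$guild, year = years[i], mean = g$mean,
        area = g$base_area * g$ratios[i], eccentricity = g$ecc,
        angle = g$angle, n = max(3L, as.integer(round(g$n[i] * n_scale))))
    }
  }
  baselines <- lapply(years, function(y) {
    baseline_year_spec(year = y, mean_d15N = 6.0, sd_d15N = 0.6, n = 6,
                       d13C_range = c(-31, -27))
  })
  study_spec(consumers, baselines, seed = seed)
}

#' Null study template: identical true ellipses every year
#'
#' One consumer group whose generating cluster is identical in every year,
#' used for calibration of the pairwise posterior probabilities (which
#' should then be approximately uniform over replicates).
#'
#' @param n_per_year Sample size per year.
#' @param years Calendar years (default two years).
#' @param area True standard ellipse area in every year.
#' @param eccentricity,angle Shared cluster shape.
#' @param seed Master seed.
#' @return A [study_spec()].
#' @export
null_study_spec <- function(n_per_year = 50, years = c(2014L, 2015L),
                            area = 2, eccentricity = 1.3, angle = 0.3,
                            seed = 1L) {
  consumers <- lapply(years, function(y) {
    group_year_spec(group = "null_group", guild = "omnivore", year = y,
                    mean = c(-27, 10), area = area,
                    eccentricity = eccentricity, angle = angle,
                    n = n_per_year)
  })
  baselines <- lapply(years, function(y) {
    baseline_year_spec(year = y, mean_d15N = 6.0, sd_d15N = 0.6, n = 5)
  })
  study_spec(consumers, baselines, seed = seed)
}
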