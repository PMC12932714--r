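# Baseline standardization of raw delta values into the delta-space used
# for all niche fits. Carbon is centred on the yearly consumer mean and
# scaled by the yearly consumer range; nitrogen is converted to trophic
# position by anchoring the baseline guild at position 2 and dividing the
# enrichment by a trophic discrimination factor (TDF, default 3.23 per mil
# per trophic step):
#
#   d13C_cor = (d13C_i - mean(d13C_consumers)) / range(d13C_consumers)
#   d15N_cor = (d15N_i - mean(d15N_baseline)) / TDF + 2
#
# Constants are computed per calendar year over all individual non-baseline
# records pooled across groups; the baseline mean may optionally be pooled
# across years.

#' Per-year standardization constants
#'
#' Computes the constants needed to standardize one year of data: the mean
#' and range (max - min) of `d13C` over all non-baseline individuals of
#' that year, and the mean `d15N` of the baseline guild.
#'
#' @param dataset An [iso_dataset()].
#' @param year Calendar year to compute constants for.
#' @param tdf Trophic discrimination factor in per mil per trophic step
#'   (default 3.23).
#' @param baseline_tp Trophic position assigned to the baseline (default 2).
#' @param pooled_baseline If `TRUE`, the baseline mean pools baseline
#'   records of all years instead of only `year`'s.
#'
#' @return A list of class `year_standardization` with fields `year`,
#'   `mean_d13C_consumers`, `range_d13C_consumers`, `baseline_mean_d15N`,
#'   `tdf`, `baseline_tp`.
#' @export
compute_year_constants <- function(dataset, year, tdf = 3.23,
                                   baseline_tp = 2, pooled_baseline = FALSE) {
  stopifnot(is.numeric(tdf), length(tdf) == 1, tdf > 0)
  df <- as.data.frame(dataset)
  cons <- df[df$guild != "baseline" & df$year == year, , drop = FALSE]
  if (nrow(cons) < 2) {
    stop("year ", year, ": need at least 2 consumer records to standardize",
         call. = FALSE)
  }
  rng <- max(cons$d13C) - min(cons$d13C)
  if (rng <= 0) {
    stop("degenerate standardization: zero d13C range among consumers in year ",
         year, call. = FALSE)
  }
  base <- if (pooled_baseline) {
    df[df$guild == "baseline", , drop = FALSE]
  } else {
    df[df$guild == "baseline" & df$year == year, , drop = FALSE]
  }
  if (nrow(base) == 0) {
    stop("missing baseline: no baseline-guild records for year ", year,
         call. = FALSE)
  }
  structure(list(year = as.integer(year),
                 mean_d13C_consumers = mean(cons$d13C),
                 range_d13C_consumers = rng,
                 baseline_mean_d15N = mean(base$d15N),
                 tdf = tdf, baseline_tp = baseline_tp,
                 pooled_baseline = pooled_baseline),
            class = "year_standardization")
}

#' Range-standardize carbon values
#'
#' @param d13C Numeric vector of raw per-mil values.
#' @param constants A `year_standardization` from [compute_year_constants()].
#' @return Dimensionless `(d13C - mean) / range` values.
#' @export
standardize_carbon <- function(d13C, constants) {
  stopifnot(inherits(constants, "year_standardization"))
  (d13C - constants$mean_d13C_consumers) / constants$range_d13C_consumers
}

#' Convert nitrogen values to trophic position
#'
#' @param d15N Numeric vector of raw per-mil values.
#' @param constants A `year_standardization` from [compute_year_constants()].
#' @return Trophic-position values `(d15N - baseline_mean) / tdf + baseline_tp`.
#' @export
standardize_nitrogen <- function(d15N, constants) {
  stopifnot(inherits(constants, "year_standardization"))
  (d15N - constants$baseline_mean_d15N) / constants$tdf + constants$baseline_tp
}

#' Standardize a whole dataset
#'
#' Applies the per-year carbon and nitrogen standardization to every
#' non-baseline record; baseline records are consumed for the constants
#' and excluded from the output. Within each year, the output `d13C_cor`
#' has mean 0 and range 1 over the consumer records by construction.
#'
#' @inheritParams compute_year_constants
#' @return A data.frame of class `iso_standardized` with columns
#'   `record_id,group,guild,year,d13C_cor,d15N_cor`, plus the per-year
#'   constants in attribute `constants`.
#' @export
standardize_dataset <- function(dataset, tdf = 3.23, baseline_tp = 2,
                                pooled_baseline = FALSE) {
  df <- as.data.frame(dataset)
  cons <- df[df$guild != "baseline", , drop = FALSE]
  years <- sort(unique(cons$year))
  consts <- lapply(years, function(y) {
    compute_year_constants(dataset, y, tdf = tdf, baseline_tp = baseline_tp,
                           pooled_baseline = pooled_baseline)
  })
  names(consts) <- as.character(years)
  out <- cons[c("record_id", "group", "guild", "year")]
  out$d13C_cor <- NA_real_
  out$d15N_cor <- NA_real_
  for (y in years) {
    k <- consts[[as.character(y)]]
    idx <- cons$year == y
    out$d13C_cor[idx] <- standardize_carbon(cons$d13C[idx], k)
    out$d15N_cor[idx] <- standardize_nitrogen(cons$d15N[idx], k)
  }
  rownames(out) <- NULL
  structure(out, constants = consts,
            class = c("iso_standardized", "data.frame"))
}

#' Write standardized records as delimited text
#'
#' @param standardized Output of [standardize_dataset()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_standardized <- function(standardized, path) {
  df <- as.data.frame(standardized)
  out <- data.frame(record_id = df$record_id, group = df$group,
                    guild = df$guild, year = as.character(df$year),
                    d13C_cor = fmt_num(df$d13C_cor),
                    d15N_cor = fmt_num(df$d15N_cor),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
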