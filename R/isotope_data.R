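# Data model, file I/O and validation for individual-level stable isotope
# records. A dataset is a plain data.frame (class "iso_dataset") with one
# row per analysed individual and columns
#   record_id, group, guild, year, d13C, d15N
# Guilds are fixed vocabulary; records with guild "baseline" anchor the
# nitrogen standardization and are never fitted as niche units themselves.

.guilds <- c("predator", "omnivore", "detritivore", "baseline")

#' Recognised trophic guild labels
#'
#' The guild vocabulary is fixed: consumers are `predator`, `omnivore` or
#' `detritivore`; primary consumers used to anchor trophic position carry
#' the label `baseline`. Baseline membership is data-driven (a column in
#' the input), not hard-coded to particular taxa.
#'
#' @return Character vector of the four allowed guild labels.
#' @export
guild_levels <- function() .guilds

validate_records <- function(df) {
  req <- c("record_id", "group", "guild", "year", "d13C", "d15N")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[req]
  df$record_id <- as.character(df$record_id)
  df$group <- as.character(df$group)
  df$guild <- as.character(df$guild)

  bad <- which(!(df$guild %in% .guilds))
  if (length(bad) > 0) {
    stop("validation error: unknown guild label(s) ",
         paste(sQuote(unique(df$guild[bad])), collapse = ", "),
         " at row(s) ", paste(bad, collapse = ", "),
         "; allowed labels: ", paste(.guilds, collapse = ", "),
         call. = FALSE)
  }

  yr <- df$year
  if (!is.numeric(yr)) stop("validation error: year must be numeric", call. = FALSE)
  bad <- which(!is.finite(yr) | yr <= 0 | yr != round(yr))
  if (length(bad) > 0) {
    stop("validation error: year must be a positive integer; offending row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df$year <- as.integer(round(yr))

  for (v in c("d13C", "d15N")) {
    x <- df[[v]]
    if (!is.numeric(x)) stop("parse error: ", v, " must be numeric", call. = FALSE)
    bad <- which(!is.finite(x))
    if (length(bad) > 0) {
      stop("validation error: non-finite ", v, " at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  dup <- which(duplicated(df$record_id))
  if (length(dup) > 0) {
    stop("validation error: duplicated record_id ",
         paste(sQuote(unique(df$record_id[dup])), collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Construct a validated isotope dataset
#'
#' @param records A data.frame with columns `record_id` (unique), `group`,
#'   `guild` (one of [guild_levels()]), `year` (positive integer), `d13C`
#'   and `d15N` (finite, per-mil vs VPDB / atmospheric N2).
#' @param provenance Free-text source tag carried as an attribute.
#'
#' @return The records as a data.frame of class `iso_dataset`.
#' @export
iso_dataset <- function(records, provenance = "") {
  df <- validate_records(as.data.frame(records))
  structure(df, provenance = as.character(provenance)[1],
            class = c("iso_dataset", "data.frame"))
}

#' Read an isotope dataset from delimited text
#'
#' Expects a header row naming the six fields
#' `record_id,group,guild,year,d13C,d15N`. Rows failing validation are
#' rejected with row-numbered error messages. A `decimal_mark = ","`
#' option accepts files written with decimal commas.
#'
#' @param path Path to the delimited text file.
#' @param delim Field delimiter (default comma).
#' @param decimal_mark Decimal mark used for numeric fields, `"."` or `","`.
#'
#' @return An [iso_dataset()] whose provenance records `path`.
#' @export
read_dataset <- function(path, delim = ",", decimal_mark = ".") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "", check.names = TRUE)
  req <- c("record_id", "group", "guild", "year", "d13C", "d15N")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  parse_num <- function(x, name) {
    x <- trimws(x)
    if (decimal_mark != ".") x <- gsub(decimal_mark, ".", x, fixed = TRUE)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out))
    if (length(bad) > 0) {
      stop("parse error: non-numeric ", name, " at data row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out
  }
  df <- data.frame(record_id = trimws(raw$record_id),
                   group = trimws(raw$group),
                   guild = trimws(raw$guild),
                   year = parse_num(raw$year, "year"),
                   d13C = parse_num(raw$d13C, "d13C"),
                   d15N = parse_num(raw$d15N, "d15N"),
                   stringsAsFactors = FALSE)
  iso_dataset(df, provenance = path)
}

#' Write an isotope dataset as delimited text
#'
#' Numeric fields are written with 17 significant digits so that
#' `read_dataset(write_dataset(d))` reproduces them to full double
#' precision; record order is preserved.
#'
#' @param dataset An [iso_dataset()] (or a data.frame with its columns).
#' @param path Output file path.
#'
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path) {
  df <- validate_records(as.data.frame(dataset))
  for (v in c("record_id", "group", "guild")) {
    if (any(grepl("[,\n\"]", df[[v]]))) {
      stop("cannot serialize: field ", v,
           " contains a delimiter, quote or newline", call. = FALSE)
    }
  }
  out <- data.frame(record_id = df$record_id, group = df$group,
                    guild = df$guild, year = as.character(df$year),
                    d13C = fmt_num(df$d13C), d15N = fmt_num(df$d15N),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Split a dataset into per-group per-year fit units
#'
#' One unit per non-baseline (group, year) combination with at least one
#' record. Units smaller than `min_n` are flagged `insufficient_n` rather
#' than silently dropped (the SEAc denominator n - 2 needs n >= 3); units
#' below `warn_n` trigger a small-sample warning, reflecting how small
#' guild samples inflate niche-area uncertainty.
#'
#' If standardized columns `d13C_cor`/`d15N_cor` are present they are used
#' as the point coordinates, otherwise the raw `d13C`/`d15N`.
#'
#' @param dataset An [iso_dataset()] or [standardize_dataset()] output.
#' @param min_n Hard minimum sample size for a fittable unit (default 3).
#' @param warn_n Soft threshold below which a warning is emitted (default 10).
#'
#' @return A list of class `iso_fit_units`; each element has `group`,
#'   `year`, `points` (n x 2 matrix), `n`, and `insufficient_n`.
#' @export
fit_units <- function(dataset, min_n = 3, warn_n = 10) {
  df <- as.data.frame(dataset)
  cols <- if (all(c("d13C_cor", "d15N_cor") %in% names(df))) {
    c("d13C_cor", "d15N_cor")
  } else {
    c("d13C", "d15N")
  }
  cons <- df[df$guild != "baseline", , drop = FALSE]
  if (nrow(cons) == 0) {
    return(structure(list(), class = "iso_fit_units"))
  }
  ord <- order(cons$group, cons$year)
  cons <- cons[ord, , drop = FALSE]
  key <- paste(cons$group, cons$year, sep = "\r")
  units <- lapply(split(seq_len(nrow(cons)), factor(key, levels = unique(key))),
                  function(idx) {
    rows <- cons[idx, , drop = FALSE]
    pts <- cbind(rows[[cols[1]]], rows[[cols[2]]])
    colnames(pts) <- cols
    list(group = rows$group[1], year = rows$year[1], points = pts,
         n = nrow(rows), insufficient_n = nrow(rows) < min_n)
  })
  names(units) <- vapply(units, function(u) paste(u$group, u$year, sep = ":"),
                         character(1))
  small <- vapply(units, function(u) u$n < warn_n, logical(1))
  if (any(small)) {
    warning("small fit unit(s) (n < ", warn_n, "): ",
            paste(names(units)[small], collapse = ", "), call. = FALSE)
  }
  structure(units, class = "iso_fit_units")
}
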