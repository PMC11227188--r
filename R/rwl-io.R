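#' Ring-width series
#'
#' A single tree/core measurement series in millimetres. Missing rings are
#' encoded as 0.0 so the series has no internal gaps; the year axis is
#' `first_year .. first_year + length(values) - 1` (calendar years CE,
#' northern-hemisphere convention: ring year = calendar year of formation).
#'
#' @param series_id Series identifier, at most 8 characters (Tucson field).
#' @param first_year Calendar year of the first ring (integer).
#' @param values Numeric vector of ring widths in mm, all >= 0.
#' @param component One of `"TOTAL"`, `"EARLYWOOD"`, `"LATEWOOD"`.
#' @return An object of class `ring_series`.
#' @export
ring_series <- function(series_id, first_year, values,
                        component = c("TOTAL", "EARLYWOOD", "LATEWOOD")) {
  component <- match.arg(component)
  series_id <- as.character(series_id)
  if (nchar(series_id) == 0L || nchar(series_id) > 8L)
    stop("series_id must be 1-8 characters, got '", series_id, "'")
  first_year <- as.integer(first_year)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("values must be non-empty")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite (missing rings are 0.0, not NA)")
  if (any(values < 0)) stop("ring widths must be >= 0 mm")
  structure(
    list(series_id = series_id, first_year = first_year,
         values = values, component = component),
    class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series> %s [%s] %d-%d (%d yr), mean %.3f mm\n",
              x$series_id, x$component, x$first_year, last_year(x),
              length(x$values), mean(x$values)))
  invisible(x)
}

#' Last calendar year of a series
#' @param x A `ring_series` or `index_series`.
#' @return Integer year.
#' @export
last_year <- function(x) {
  n <- length(if (!is.null(x$values)) x$values else x$indices)
  x$first_year + n - 1L
}

#' Years covered by a series
#' @param x A `ring_series` or `index_series`.
#' @return Integer vector of calendar years.
#' @export
series_years <- function(x) seq.int(x$first_year, last_year(x))

#' Collection of ring-width series
#'
#' @param series List of [ring_series] objects sharing one wood component.
#' @param site_id,species Free-text metadata.
#' @param component Wood component; defaults to the component of the series.
#' @return An object of class `series_collection`.
#' @export
series_collection <- function(series, site_id = "SITE", species = "",
                              component = NULL) {
  if (length(series) == 0L) stop("collection needs at least one series")
  comps <- vapply(series, function(s) s$component, character(1))
  if (is.null(component)) component <- comps[[1L]]
  if (!all(comps == component))
    stop("all series must share component ", component)
  ids <- vapply(series, function(s) s$series_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate series id: ", ids[duplicated(ids)][1L])
  names(series) <- ids
  structure(list(site_id = site_id, species = species,
                 component = component, series = series),
            class = "series_collection")
}

#' @export
print.series_collection <- function(x, ...) {
  yrs <- range(unlist(lapply(x$series, series_years)))
  cat(sprintf("<series_collection> site %s, %d series [%s], %d-%d\n",
              x$site_id, length(x$series), x$component, yrs[1], yrs[2]))
  invisible(x)
}

#' @export
length.series_collection <- function(x) length(x$series)

.rwl_terminators <- c("0.01" = 999L, "0.001" = -9999L)

#' Read a Tucson decadal (.rwl) ring-width file
#'
#' Parses the community-standard decadal layout: series id in columns 1-8,
#' a decade start year, then up to ten integer ring widths per line. The
#' precision dialect is detected from each series' terminator value
#' (`999` = hundredths of mm, `-9999` = thousandths of mm) and widths are
#' converted to mm; the terminator itself is never kept as a value.
#'
#' @param path Path to the file.
#' @param component Wood component to stamp on the series.
#' @param site_id,species Collection metadata.
#' @param precision Optional override, `0.01` or `0.001`, for files whose
#'   terminator does not follow the convention.
#' @return A [series_collection].
#' @export
read_rwl <- function(path, component = "TOTAL", site_id = "SITE",
                     species = "", precision = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(precision) && !precision %in% c(0.01, 0.001))
    stop("precision override must be 0.01 or 0.001")
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0L) stop("no series found in ", path)

  # accumulate raw integer fields per series id, in file order
  acc <- list()   # id -> list(start_year, years = decade starts, vals = int)
  order_ids <- character(0)
  for (ln in lines_keep) {
    raw <- lines[[ln]]
    id <- trimws(substr(raw, 1L, 8L))
    rest <- substr(raw, 9L, nchar(raw))
    toks <- strsplit(trimws(rest), "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.integer(toks))
    if (id == "" || length(vals) < 1L || anyNA(vals))
      stop("malformed .rwl line ", ln, ": '", raw, "'")
    yr <- vals[1L]
    dat <- vals[-1L]
    if (length(dat) > 10L)
      stop("malformed .rwl line ", ln, ": more than 10 values")
    if (is.null(acc[[id]])) {
      if (id %in% order_ids) stop("duplicate series id: ", id)
      order_ids <- c(order_ids, id)
      acc[[id]] <- list(next_year = yr, first_year = yr, vals = integer(0),
                        done = FALSE)
    } else {
      if (acc[[id]]$done)
        stop("duplicate series id (data after terminator): ", id)
      if (yr != acc[[id]]$next_year)
        stop("non-monotone or gapped decades for series ", id,
             " at line ", ln, " (expected year ", acc[[id]]$next_year,
             ", got ", yr, ")")
    }
    term <- which(dat %in% .rwl_terminators)
    if (length(term) > 0L) {
      t1 <- term[[1L]]
      acc[[id]]$vals <- c(acc[[id]]$vals, dat[seq_len(t1 - 1L)])
      acc[[id]]$done <- TRUE
      acc[[id]]$terminator <- dat[[t1]]
    } else {
      acc[[id]]$vals <- c(acc[[id]]$vals, dat)
      acc[[id]]$next_year <- yr + length(dat)
    }
  }

  series <- lapply(order_ids, function(id) {
    a <- acc[[id]]
    if (!isTRUE(a$done))
      stop("series ", id, " has no terminator (999 or -9999)")
    if (length(a$vals) == 0L) stop("series ", id, " has no values")
    mult <- if (!is.null(precision)) precision
            else if (a$terminator == -9999L) 0.001 else 0.01
    if (any(a$vals < 0))
      stop("negative ring width in series ", id)
    ring_series(id, a$first_year, a$vals * mult, component = component)
  })
  series_collection(series, site_id = site_id, species = species,
                    component = component)
}

#' Write a Tucson decadal (.rwl) ring-width file
#'
#' Inverse of [read_rwl]: decadal layout, series id left-justified in the
#' 8-character field, one value slot of width 6, terminator matching the
#' precision (`999` for 0.01 mm, `-9999` for 0.001 mm). `read_rwl()` after
#' `write_rwl()` is the identity on values and years, and re-writing a file
#' read from this writer reproduces it byte for byte.
#'
#' @param collection A [series_collection].
#' @param path Output path.
#' @param precision `0.01` (default) or `0.001` mm units.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(collection, path, precision = 0.01) {
  stopifnot(inherits(collection, "series_collection"))
  if (!precision %in% c(0.01, 0.001))
    stop("precision must be 0.01 or 0.001")
  term <- if (precision == 0.001) -9999L else 999L
  out <- character(0)
  for (s in collection$series) {
    if (nchar(s$series_id) > 8L) stop("series_id > 8 chars: ", s$series_id)
    if (any(s$values < 0)) stop("negative ring width in ", s$series_id)
    ints <- as.integer(round(s$values / precision))
    yrs <- series_years(s)
    slots <- c(ints, term)
    slot_yr <- c(yrs, max(yrs) + 1L)   # terminator occupies the next slot
    row <- (slot_yr %/% 10L)           # decade blocks
    for (d in unique(row)) {
      i <- which(row == d)
      out <- c(out, paste0(sprintf("%-8s", s$series_id),
                           sprintf("%4d", slot_yr[i[1L]]),
                           paste0(sprintf("%6d", slots[i]), collapse = "")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

.climate_vars <- c(Prec = "mm", EvT = "mm", Tmax = "°C",
                   Tmin = "°C", PDSI = "unitless", SPEI6 = "unitless")
.month_abb <- c("jan", "feb", "mar", "apr", "may", "jun",
                "jul", "aug", "sep", "oct", "nov", "dec")

#' Monthly climate table
#'
#' @param variable One of `Prec`, `EvT`, `Tmax`, `Tmin`, `PDSI`, `SPEI6`.
#' @param years Contiguous integer year vector (rows of `values`).
#' @param values Numeric matrix, one row per year, 12 columns (Jan..Dec);
#'   missing values as `NA`.
#' @return An object of class `climate_table`.
#' @export
climate_table <- function(variable, years, values) {
  variable <- match.arg(variable, names(.climate_vars))
  years <- as.integer(years)
  values <- as.matrix(values)
  if (ncol(values) != 12L) stop("climate values need 12 monthly columns")
  if (nrow(values) != length(years))
    stop("row count must equal number of years")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years must be contiguous")
  dimnames(values) <- list(years, .month_abb)
  structure(list(variable = variable, units = .climate_vars[[variable]],
                 years = years, values = values),
            class = "climate_table")
}

#' @export
print.climate_table <- function(x, ...) {
  cat(sprintf("<climate_table> %s (%s), %d-%d, %d missing cells\n",
              x$variable, x$units, min(x$years), max(x$years),
              sum(is.na(x$values))))
  invisible(x)
}

#' Read a monthly climate CSV (year, jan..dec)
#'
#' Years are sorted ascending on load; gaps in the year range are filled
#' with all-`NA` rows so the table is contiguous. Empty cells become `NA`
#' (never zero).
#'
#' @param path CSV path with header `year,jan,...,dec`.
#' @param variable Climate variable name (see [climate_table]).
#' @return A [climate_table].
#' @export
read_climate_csv <- function(path, variable) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE, check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("year", .month_abb)
  if (!identical(names(df)[seq_along(need)], need))
    stop("climate CSV header must be year,", paste(.month_abb, collapse = ","))
  conv <- function(col, j) {
    x <- df[[col]]
    x[x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop("non-numeric cell in ", path, " at row ", bad[1L] + 1L,
           ", column '", col, "'")
    out
  }
  yrs <- conv("year", 0L)
  if (anyNA(yrs)) stop("missing year value in ", path)
  yrs <- as.integer(yrs)
  if (anyDuplicated(yrs)) stop("duplicate year ", yrs[duplicated(yrs)][1L],
                               " in ", path)
  vals <- sapply(.month_abb, conv)
  vals <- matrix(as.numeric(vals), ncol = 12L)
  ord <- order(yrs)
  yrs <- yrs[ord]; vals <- vals[ord, , drop = FALSE]
  full <- seq.int(min(yrs), max(yrs))
  m <- matrix(NA_real_, length(full), 12L)
  m[match(yrs, full), ] <- vals
  climate_table(variable, full, m)
}

#' Write a monthly climate CSV
#' @param climate A [climate_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(climate, path) {
  stopifnot(inherits(climate, "climate_table"))
  df <- data.frame(year = climate$years, climate$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
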