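#' Detrending configuration
#'
#' Parameters of the standardization step. The spline is parameterized by
#' the wavelength (years) at which its amplitude frequency response equals
#' `cutoff_response`; the defaults (30 yr, 0.5) are the classic
#' 50%-frequency-cutoff spline used for site chronologies.
#'
#' @param spline_wavelength Wavelength in years at which the spline's
#'   frequency response equals `cutoff_response` (>= 2, default 30).
#' @param cutoff_response Amplitude response at the wavelength, in (0, 1)
#'   (default 0.5).
#' @param index_mode `"RATIO"` (dimensionless index, long-run mean ~ 1) or
#'   `"DIFFERENCE"` (residual in mm).
#' @param prewhiten Remove autocorrelation from indices (AR residuals)?
#'   Used for climate-correlation chronologies; resilience indices operate
#'   on growth levels and must not be prewhitened.
#' @param ar_max_order Maximum AR order tried during prewhitening.
#' @param biweight_c Tukey biweight tuning constant.
#' @param min_depth Minimum number of series required for a chronology year.
#' @param fitted_floor Clamp for the fitted curve before RATIO division (mm).
#' @return An object of class `detrend_config`.
#' @export
detrend_config <- function(spline_wavelength = 30, cutoff_response = 0.5,
                           index_mode = c("RATIO", "DIFFERENCE"),
                           prewhiten = FALSE, ar_max_order = 3L,
                           biweight_c = 9, min_depth = 1L,
                           fitted_floor = 0.001) {
  index_mode <- match.arg(index_mode)
  if (spline_wavelength < 2) stop("spline_wavelength must be >= 2 years")
  if (cutoff_response <= 0 || cutoff_response >= 1)
    stop("cutoff_response must be in (0, 1)")
  if (ar_max_order < 0) stop("ar_max_order must be >= 0")
  structure(list(spline_wavelength = spline_wavelength,
                 cutoff_response = cutoff_response,
                 index_mode = index_mode, prewhiten = prewhiten,
                 ar_max_order = as.integer(ar_max_order),
                 biweight_c = biweight_c, min_depth = as.integer(min_depth),
                 fitted_floor = fitted_floor),
            class = "detrend_config")
}

# Solve (R + lambda Q'Q) c = Q'y for the natural cubic smoothing spline on a
# uniform unit grid (Reinsch form). The system matrix is symmetric
# pentadiagonal with constant diagonals, so a banded Cholesky in O(n) does.
.reinsch_smooth <- function(y, lambda) {
  n <- length(y)
  m <- n - 2L
  d0 <- 2 / 3 + 6 * lambda
  d1 <- 1 / 6 - 4 * lambda
  d2 <- lambda
  b <- diff(y, differences = 2L)
  l0 <- numeric(m); l1 <- numeric(max(m - 1L, 0L)); l2 <- numeric(max(m - 2L, 0L))
  for (i in seq_len(m)) {
    a <- d0
    if (i > 1L) a <- a - l1[i - 1L]^2
    if (i > 2L) a <- a - l2[i - 2L]^2
    l0[i] <- sqrt(a)
    if (i < m) {
      t1 <- d1
      if (i > 1L) t1 <- t1 - l1[i - 1L] * l2[i - 1L]
      l1[i] <- t1 / l0[i]
    }
    if (i < m - 1L) l2[i] <- d2 / l0[i]
  }
  z <- numeric(m)
  for (i in seq_len(m)) {
    t1 <- b[i]
    if (i > 1L) t1 <- t1 - l1[i - 1L] * z[i - 1L]
    if (i > 2L) t1 <- t1 - l2[i - 2L] * z[i - 2L]
    z[i] <- t1 / l0[i]
  }
  cc <- numeric(m)
  for (i in rev(seq_len(m))) {
    t1 <- z[i]
    if (i < m) t1 <- t1 - l1[i] * cc[i + 1L]
    if (i < m - 1L) t1 <- t1 - l2[i] * cc[i + 2L]
    cc[i] <- t1 / l0[i]
  }
  # s = y - lambda * Q c ; Q c is the second difference of zero-padded c
  y - lambda * diff(diff(c(0, 0, cc, 0, 0)))
}

#' Cubic smoothing spline with a fixed frequency-response cutoff
#'
#' Fits the natural cubic smoothing spline whose amplitude frequency
#' response equals `cutoff_response` at period `wavelength` years. On a
#' uniform grid the spline's transfer function is
#' `A(w) = 1 / (1 + 12 lambda (1 - cos w)^2 / (2 + cos w))`, `w = 2 pi /
#' wavelength`, which fixes the stiffness `lambda` analytically
#' (Cook-Peters parameterization). Low frequencies pass essentially
#' unattenuated; variance at the cutoff wavelength is split equally between
#' curve and residual index.
#'
#' @param values Numeric vector (>= 4 finite values).
#' @param wavelength Cutoff wavelength in years (>= 2).
#' @param cutoff_response Amplitude response at the wavelength, in (0, 1).
#' @return Fitted curve, same length as `values`.
#' @export
fit_frequency_cutoff_spline <- function(values, wavelength = 30,
                                        cutoff_response = 0.5) {
  if (length(values) < 4L) stop("need at least 4 values to fit the spline")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite")
  if (wavelength < 2) stop("wavelength must be >= 2 years")
  if (cutoff_response <= 0 || cutoff_response >= 1)
    stop("cutoff_response must be in (0, 1)")
  if (all(values == values[1L])) return(rep(values[1L], length(values)))
  w <- 2 * pi / wavelength
  lambda <- (1 - cutoff_response) / cutoff_response *
    (2 + cos(w)) / (12 * (1 - cos(w))^2)
  .reinsch_smooth(as.numeric(values), lambda)
}

#' Standardize a ring-width series into a dimensionless index
#'
#' Divides (RATIO) or subtracts (DIFFERENCE) the frequency-cutoff spline
#' fit, removing the age/size growth trend. Fitted values at or below
#' `fitted_floor` are clamped before division; zero rings (missing rings)
#' yield index 0.
#'
#' @param series A [ring_series].
#' @param config A [detrend_config].
#' @return An object of class `index_series` with fields `series_id`,
#'   `first_year`, `indices` and the config snapshot.
#' @export
standardize <- function(series, config = detrend_config()) {
  stopifnot(inherits(series, "ring_series"))
  v <- series$values
  if (length(v) < 4L) stop("series too short to standardize (need >= 4)")
  if (all(v == 0)) stop("all-zero series cannot be standardized")
  fit <- fit_frequency_cutoff_spline(v, config$spline_wavelength,
                                     config$cutoff_response)
  idx <- if (config$index_mode == "RATIO") {
    v / pmax(fit, config$fitted_floor)
  } else {
    v - fit
  }
  out <- structure(list(series_id = series$series_id,
                        first_year = series$first_year,
                        indices = idx, component = series$component,
                        config = config),
                   class = "index_series")
  if (isTRUE(config$prewhiten)) out <- prewhiten_ar(out, config$ar_max_order)
  out
}

#' @export
print.index_series <- function(x, ...) {
  cat(sprintf("<index_series> %s %d-%d (%d yr), mean %.3f\n",
              x$series_id, x$first_year, last_year(x), length(x$indices),
              mean(x$indices, na.rm = TRUE)))
  invisible(x)
}

#' Remove autocorrelation from an index series
#'
#' Fits AR(p), p selected by AIC over 0..`max_order` (Yule-Walker), and
#' returns the residual series re-centred to mean 1 (RATIO mode) or 0
#' (DIFFERENCE mode). The first p years, which have no residual, are `NA`.
#' Selected order 0 (or a fit failure, with a warning) returns the input
#' unchanged.
#'
#' @param index An [standardize()] output (`index_series`).
#' @param max_order Maximum AR order (default 3).
#' @return An `index_series` of residuals, same length and years.
#' @export
prewhiten_ar <- function(index, max_order = 3L) {
  stopifnot(inherits(index, "index_series"))
  x <- index$indices
  ok <- is.finite(x)
  if (sum(ok) <= max_order + 10L)
    stop("series too short to prewhiten (need length > max_order + 10)")
  if (stats::var(x[ok]) == 0) return(index)
  centre <- if (!is.null(index$config) &&
                identical(index$config$index_mode, "DIFFERENCE")) 0 else 1
  fit <- tryCatch(
    stats::ar(x[ok], aic = TRUE, order.max = max_order,
              method = "yule-walker"),
    error = function(e) {
      warning("AR fit failed (", conditionMessage(e),
              "); returning series unchanged")
      NULL
    })
  if (is.null(fit) || fit$order == 0L) return(index)
  res <- fit$resid
  res <- res - mean(res, na.rm = TRUE) + centre
  out <- rep(NA_real_, length(x))
  out[ok] <- res
  index$indices <- out
  index$ar_order <- fit$order
  index
}

#' Tukey biweight robust mean
#'
#' Iterated biweight location estimate: weights `(1 - u^2)^2` for `|u| < 1`
#' with `u = (x - T)/(c * S)`, `S` the median absolute deviation about the
#' median, iterated from the median until the update is below 1e-8.
#' Degenerate cases: n <= 2 returns the arithmetic mean; `S = 0` returns
#' the median (the biweight limit, where off-median points get zero weight).
#'
#' @param values Numeric vector with at least one finite value.
#' @param c Tuning constant (default 9).
#' @return The robust mean (scalar).
#' @export
biweight_mean <- function(values, c = 9) {
  x <- values[is.finite(values)]
  if (length(x) == 0L) stop("biweight_mean needs at least one finite value")
  if (length(x) <= 2L) return(mean(x))
  med <- stats::median(x)
  s <- stats::median(abs(x - med))
  if (s == 0) return(med)
  t0 <- med
  for (it in seq_len(100L)) {
    u <- (x - t0) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    t1 <- sum(w * x) / sum(w)
    if (abs(t1 - t0) < 1e-8) return(t1)
    t0 <- t1
  }
  t0
}

#' Mean sensitivity of an index series
#'
#' Classical year-to-year variability statistic
#' `MS = mean(|2 (x[t+1] - x[t]) / (x[t+1] + x[t])|)` over consecutive
#' pairs. Pairs containing a zero (missing ring) or non-finite value, or
#' summing to zero, are excluded. Scale-invariant by construction.
#'
#' @param x Numeric vector, length >= 2.
#' @return MS (scalar, >= 0).
#' @export
mean_sensitivity <- function(x) {
  if (length(x) < 2L) stop("mean_sensitivity needs at least 2 values")
  a <- x[-length(x)]
  b <- x[-1L]
  use <- is.finite(a) & is.finite(b) & a != 0 & b != 0 & (a + b) != 0
  if (!any(use)) stop("no usable consecutive pairs for mean sensitivity")
  mean(abs(2 * (b[use] - a[use]) / (b[use] + a[use])))
}

# index values of a series on an explicit year axis (NA outside its span)
.on_years <- function(idx, years) {
  out <- rep(NA_real_, length(years))
  m <- match(series_years(idx), years)
  keep <- !is.na(m)
  out[m[keep]] <- idx$indices[keep]
  out
}

#' Mean interseries correlation (Rbar)
#'
#' Mean of all pairwise Pearson correlations between index series, each
#' computed on the pair's year overlap (optionally restricted to `period`).
#' Pairs with overlap below `min_overlap` years are excluded; years where
#' both members are zero (shared missing rings) are dropped from a pair.
#'
#' @param indices List of `index_series`.
#' @param period Optional `c(first, last)` year range restriction.
#' @param min_overlap Minimum pair overlap in years (default 20).
#' @return Rbar (scalar in `[-1, 1]`).
#' @export
interseries_rbar <- function(indices, period = NULL, min_overlap = 20L) {
  if (length(indices) < 2L) stop("Rbar needs at least 2 series")
  years <- range(unlist(lapply(indices, series_years)))
  years <- seq.int(years[1L], years[2L])
  if (!is.null(period)) years <- years[years >= period[1L] & years <= period[2L]]
  mat <- vapply(indices, .on_years, numeric(length(years)), years = years)
  rs <- c()
  for (i in seq_len(ncol(mat) - 1L)) {
    for (j in seq.int(i + 1L, ncol(mat))) {
      ok <- is.finite(mat[, i]) & is.finite(mat[, j]) &
        !(mat[, i] == 0 & mat[, j] == 0)
      if (sum(ok) < min_overlap) next
      if (stats::sd(mat[ok, i]) == 0 || stats::sd(mat[ok, j]) == 0) next
      rs <- c(rs, stats::cor(mat[ok, i], mat[ok, j]))
    }
  }
  if (length(rs) == 0L)
    stop("no series pair with overlap >= ", min_overlap, " years")
  mean(rs)
}

#' Expressed population signal (EPS)
#'
#' Wigley closed form `EPS = n rbar / (n rbar + (1 - rbar))`: how well a
#' finite-n chronology represents the population chronology. The
#' conventional quality bar is 0.85.
#'
#' @param rbar Mean interseries correlation, in `(-1, 1]`.
#' @param n Number of series (>= 1).
#' @return EPS in `[0, 1]` for `rbar >= 0`; strongly negative `rbar`
#'   (non-positive denominator) yields 0 with a warning.
#' @export
eps <- function(rbar, n) {
  if (n < 1) stop("n must be >= 1")
  if (rbar <= -1 || rbar > 1) stop("rbar must be in (-1, 1]")
  den <- n * rbar + (1 - rbar)
  if (den <= 0) {
    warning("EPS denominator non-positive (rbar = ", rbar, "); reporting 0")
    return(0)
  }
  n * rbar / den
}

#' Build a site chronology by robust averaging
#'
#' Per-year Tukey biweight mean over all index series covering that year;
#' years with fewer than `min_depth` series are excluded. Chronology
#' quality statistics (MS, Rbar, EPS, common period) are attached.
#'
#' @param indices List of `index_series` (>= 1).
#' @param min_depth Minimum sample depth per retained year (default 1).
#' @param biweight_c Biweight tuning constant.
#' @return An object of class `chronology` with `years`, `index`,
#'   `sample_depth` and `stats`.
#' @export
build_chronology <- function(indices, min_depth = 1L, biweight_c = 9) {
  if (length(indices) == 0L) stop("need at least one index series")
  yr <- range(unlist(lapply(indices, series_years)))
  years <- seq.int(yr[1L], yr[2L])
  mat <- vapply(indices, .on_years, numeric(length(years)), years = years)
  mat <- matrix(mat, nrow = length(years))
  depth <- rowSums(is.finite(mat))
  keep <- depth >= min_depth
  if (!any(keep)) stop("no year reaches sample depth ", min_depth,
                       " (empty overlap)")
  idx <- vapply(which(keep), function(i) {
    biweight_mean(mat[i, ], c = biweight_c)
  }, numeric(1))
  years_k <- years[keep]
  common <- years[depth >= 2L]
  n <- length(indices)
  rbar <- if (n >= 2L)
    tryCatch(interseries_rbar(indices), error = function(e) NA_real_)
    else NA_real_
  stats <- structure(list(
    ms = tryCatch(mean_sensitivity(idx), error = function(e) NA_real_),
    rbar = rbar,
    eps = if (is.finite(rbar)) eps(rbar, n) else NA_real_,
    common_period = if (length(common)) range(common) else c(NA_integer_, NA_integer_),
    n_series = n), class = "chronology_stats")
  structure(list(component = indices[[1L]]$component %||% "TOTAL",
                 years = years_k, index = idx,
                 sample_depth = depth[keep], stats = stats),
            class = "chronology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.chronology <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<chronology> [%s] %d-%d, %d series; MS %.3f, Rbar %s, EPS %s\n",
              x$component, min(x$years), max(x$years), s$n_series, s$ms,
              format(round(s$rbar, 3)), format(round(s$eps, 3))))
  invisible(x)
}

#' @export
as.data.frame.chronology <- function(x, ...) {
  data.frame(year = x$years, index = x$index, sample_depth = x$sample_depth)
}

#' Write / read a chronology CSV (year,index,sample_depth)
#' @param chronology A [build_chronology()] result.
#' @param path CSV path.
#' @return `path` (write) or a `chronology` without stats (read).
#' @export
write_chronology_csv <- function(chronology, path) {
  utils::write.csv(as.data.frame(chronology), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_chronology_csv
#' @export
read_chronology_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("year", "index", "sample_depth") %in% names(df)))
    stop("chronology CSV needs columns year,index,sample_depth")
  structure(list(component = "TOTAL", years = as.integer(df$year),
                 index = df$index, sample_depth = as.integer(df$sample_depth),
                 stats = NULL),
            class = "chronology")
}
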