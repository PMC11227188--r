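#' Drought event calendar
#'
#' Inclusive year ranges of severe drought events. The default calendar is
#' the set of documented severe droughts for central-eastern Mexico used
#' throughout: 1750-1755, 1785-1786, 1808-1811, 1819-1823, 1894-1899,
#' 1909-1910, 1951-1957, 2011-2012, 2020-2022.
#'
#' @param events Two-column matrix or data.frame of (start, end) years.
#' @return Data.frame of class `drought_calendar` with columns
#'   `start`, `end`, sorted and non-overlapping.
#' @export
drought_calendar <- function(events) {
  ev <- as.data.frame(events)
  names(ev) <- c("start", "end")
  ev$start <- as.integer(ev$start); ev$end <- as.integer(ev$end)
  if (any(ev$start > ev$end)) stop("event start must be <= end")
  ev <- ev[order(ev$start), , drop = FALSE]
  if (nrow(ev) > 1L && any(ev$start[-1L] <= ev$end[-nrow(ev)]))
    stop("drought events must not overlap")
  rownames(ev) <- NULL
  structure(ev, class = c("drought_calendar", "data.frame"))
}

#' @rdname drought_calendar
#' @export
default_drought_calendar <- function() {
  drought_calendar(rbind(
    c(1750, 1755), c(1785, 1786), c(1808, 1811), c(1819, 1823),
    c(1894, 1899), c(1909, 1910), c(1951, 1957), c(2011, 2012),
    c(2020, 2022)))
}

#' Read a drought calendar CSV (start,end)
#' @param path CSV path, or the string `"default"`.
#' @return A [drought_calendar].
#' @export
read_drought_calendar <- function(path) {
  if (identical(path, "default")) return(default_drought_calendar())
  df <- utils::read.csv(path)
  if (!all(c("start", "end") %in% names(df)))
    stop("calendar CSV needs columns start,end")
  drought_calendar(df[, c("start", "end")])
}

#' Resilience-analysis configuration
#'
#' @param pre_window Years averaged before the event year for the
#'   resistance denominator (default 2).
#' @param post_window Years averaged after the event year for the recovery
#'   numerator (default 2).
#' @param rs_denominator `"PRE_MEAN"` (2-yr pre mean; makes
#'   `Rs = Rt * Rc` exactly) or `"LAG1"` (the single year t-1, as the
#'   resilience formula is sometimes printed).
#' @param flank Years on each side of an event pooled into the `Pre5`
#'   reference level for the decline rate (default 5).
#' @param eval_range Year range over which per-tree indicators are
#'   evaluated (default 1750-2022).
#' @return An object of class `resilience_config`.
#' @export
resilience_config <- function(pre_window = 2L, post_window = 2L,
                              rs_denominator = c("PRE_MEAN", "LAG1"),
                              flank = 5L, eval_range = c(1750L, 2022L)) {
  rs_denominator <- match.arg(rs_denominator)
  if (pre_window < 1L || post_window < 1L || flank < 1L)
    stop("pre_window, post_window and flank must be >= 1")
  structure(list(pre_window = as.integer(pre_window),
                 post_window = as.integer(post_window),
                 rs_denominator = rs_denominator,
                 flank = as.integer(flank),
                 eval_range = as.integer(eval_range)),
            class = "resilience_config")
}

.series_value_at <- function(x, years, yrs_axis) {
  x$indices[match(years, yrs_axis)]
}

#' Resistance, recovery and resilience at one year
#'
#' Lloret-type ratios on growth levels:
#' `Rt = x_t / mean(x[t-pre..t-1])` (performance during vs before),
#' `Rc = mean(x[t+1..t+post]) / x_t` (after vs during),
#' `Rs = mean(x[t+1..t+post]) / denom` with `denom` the pre mean
#' (default; `Rs = Rt * Rc` exactly) or `x[t-1]`. Values below 1 mean the
#' event's effect prevails.
#'
#' @param series An `index_series` (non-prewhitened — these are level
#'   ratios).
#' @param t Calendar year evaluated.
#' @param config A [resilience_config].
#' @return Named numeric `c(Rt, Rc, Rs)`, or a zero-length `resilience_skip`
#'   object with attribute `reason` when the year is ineligible (window
#'   outside the span, or a zero/NA denominator).
#' @export
indices_at_year <- function(series, t, config = resilience_config()) {
  skip <- function(why) structure(numeric(0), reason = why,
                                  class = "resilience_skip")
  yrs <- series_years(series)
  need <- c(seq.int(t - config$pre_window, t - 1L), t,
            seq.int(t + 1L, t + config$post_window))
  if (any(!need %in% yrs))
    return(skip("window outside series span"))
  x <- .series_value_at(series, need, yrs)
  if (anyNA(x)) return(skip("missing index in window"))
  pre <- mean(x[seq_len(config$pre_window)])
  xt <- x[config$pre_window + 1L]
  post <- mean(x[seq.int(config$pre_window + 2L, length(x))])
  den <- if (config$rs_denominator == "PRE_MEAN") pre
         else x[config$pre_window]   # x_{t-1}
  if (pre <= 0 || xt <= 0 || den <= 0)
    return(skip("non-positive denominator"))
  c(Rt = xt / pre, Rc = post / xt, Rs = post / den)
}

#' Per-tree, per-year resilience indicators
#'
#' Evaluates [indices_at_year] for every tree and every eligible year of
#' `config$eval_range`, in deterministic (tree_id, year) order. Ineligible
#' years are skipped.
#'
#' @param trees List of `index_series`.
#' @param config A [resilience_config].
#' @return Data.frame `tree_id, year, Rt, Rc, Rs`.
#' @export
evaluate_resilience <- function(trees, config = resilience_config()) {
  if (length(trees) == 0L) stop("need at least one series")
  ids <- vapply(trees, function(s) s$series_id, character(1))
  trees <- trees[order(ids)]
  rows <- list()
  for (s in trees) {
    for (t in seq.int(config$eval_range[1L], config$eval_range[2L])) {
      v <- indices_at_year(s, t, config)
      if (length(v) == 0L) next
      rows[[length(rows) + 1L]] <-
        data.frame(tree_id = s$series_id, year = t,
                   Rt = v[["Rt"]], Rc = v[["Rc"]], Rs = v[["Rs"]],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(tree_id = character(0), year = integer(0),
                      Rt = numeric(0), Rc = numeric(0), Rs = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decline-phase statistics for one event
#'
#' The decline phase runs from the event start to the latest year
#' attaining the minimum index within the event (ties resolved to the
#' latest year). `Pre5` is the mean index over the `flank` years before
#' and after the event (both flanks pooled); flank years falling inside
#' another calendar event are dropped. The decline rate is
#' `DecU = (Pre5 - Min) / Dt`, `Dt` the decline-phase length in years.
#' Negative `DecU` (event minimum above the flank mean) is kept and
#' flagged, not floored.
#'
#' @param series An `index_series`.
#' @param event Length-2 vector `c(start, end)` (inclusive).
#' @param config A [resilience_config] (supplies `flank`).
#' @param calendar Optional [drought_calendar] used to exclude other
#'   events' years from the flanks.
#' @return One-row data.frame: `tree_id, event_start, event_end,
#'   decline_start_year, min_year, Pre5, Min, Dt, DecU, negative_decu`.
#' @export
detect_decline_phase <- function(series, event,
                                 config = resilience_config(),
                                 calendar = NULL) {
  start <- as.integer(event[[1L]]); end <- as.integer(event[[2L]])
  if (start > end) stop("event start must be <= end")
  yrs <- series_years(series)
  flank_yrs <- c(seq.int(start - config$flank, start - 1L),
                 seq.int(end + 1L, end + config$flank))
  miss <- setdiff(c(flank_yrs, start:end), yrs)
  if (length(miss))
    stop("event flank extends beyond series span; missing years: ",
         paste(miss, collapse = ", "))
  if (!is.null(calendar)) {
    other <- calendar[!(calendar$start == start & calendar$end == end), ,
                      drop = FALSE]
    in_other <- vapply(flank_yrs, function(y)
      any(y >= other$start & y <= other$end), logical(1))
    flank_yrs <- flank_yrs[!in_other]
    if (length(flank_yrs) == 0L)
      stop("all flank years fall inside other calendar events")
  }
  pre5 <- mean(.series_value_at(series, flank_yrs, yrs), na.rm = TRUE)
  ev_idx <- .series_value_at(series, start:end, yrs)
  min_val <- min(ev_idx, na.rm = TRUE)
  min_year <- max((start:end)[which(ev_idx == min_val)])  # latest minimum
  dt <- min_year - start + 1L
  decu <- (pre5 - min_val) / dt
  data.frame(tree_id = series$series_id, event_start = start,
             event_end = end, decline_start_year = start,
             min_year = min_year, Pre5 = pre5, Min = min_val,
             Dt = dt, DecU = decu, negative_decu = decu < 0,
             stringsAsFactors = FALSE)
}

#' Decline statistics for every tree and calendar event
#'
#' Events whose flanks extend beyond a tree's span are skipped for that
#' tree.
#'
#' @param trees List of `index_series`.
#' @param calendar A [drought_calendar].
#' @param config A [resilience_config].
#' @return Data.frame, one row per (tree, in-span event).
#' @export
decline_records <- function(trees, calendar = default_drought_calendar(),
                            config = resilience_config()) {
  rows <- list()
  ids <- vapply(trees, function(s) s$series_id, character(1))
  for (s in trees[order(ids)]) {
    for (k in seq_len(nrow(calendar))) {
      r <- tryCatch(
        detect_decline_phase(s, c(calendar$start[k], calendar$end[k]),
                             config, calendar),
        error = function(e) NULL)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0L)
    return(data.frame(tree_id = character(0), event_start = integer(0),
                      event_end = integer(0), decline_start_year = integer(0),
                      min_year = integer(0), Pre5 = numeric(0),
                      Min = numeric(0), Dt = integer(0), DecU = numeric(0),
                      negative_decu = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect multi-year low-growth periods in a chronology
#'
#' Maximal runs of at least `min_run` consecutive years whose index lies
#' below `mean - k * SD` of the full chronology (pointer-period
#' detection for consistently low growth).
#'
#' @param chronology A `chronology` (length >= 30).
#' @param k SD multiplier (default 1).
#' @param min_run Minimum run length in years (default 2).
#' @return Data.frame `start, end` (possibly zero rows).
#' @export
low_growth_periods <- function(chronology, k = 1, min_run = 2L) {
  stopifnot(inherits(chronology, "chronology"))
  x <- chronology$index
  if (length(x) < 30L) stop("chronology too short (< 30 years)")
  thr <- mean(x) - k * stats::sd(x)
  low <- x < thr
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = chronology$years[starts[keep]],
             end = chronology$years[ends[keep]])
}

#' Gaussian kernel density and skewness of an indicator sample
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth on a 512-point
#' grid spanning the data plus three bandwidths, plus the adjusted
#' Fisher-Pearson skewness `g1 * sqrt(n (n-1)) / (n - 2)`.
#'
#' @param values Numeric sample (n >= 5, non-degenerate).
#' @param indicator One of `"Rt"`, `"Rc"`, `"Rs"`, `"DecU"`.
#' @return Object of class `density_summary`: `indicator`, `grid`,
#'   `density`, `bandwidth`, `skewness`, `n`.
#' @export
density_summary <- function(values, indicator = c("Rt", "Rc", "Rs", "DecU")) {
  indicator <- match.arg(indicator)
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 5L) stop("density_summary needs n >= 5")
  if (stats::var(x) == 0) stop("zero-variance sample")
  d <- stats::density(x, bw = "nrd0", n = 512L, cut = 3)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  structure(list(indicator = indicator, grid = d$x, density = d$y,
                 bandwidth = d$bw, skewness = skew, n = n),
            class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat(sprintf("<density_summary> %s: n = %d, bw = %.4f, skewness = %.3f\n",
              x$indicator, x$n, x$bandwidth, x$skewness))
  invisible(x)
}
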