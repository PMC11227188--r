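#' Synthetic forest configuration
#'
#' Ground-truth parameters for the simulated stand. Growth is
#' multiplicative: a negative-exponential age curve times a lognormal
#' AR(1) deviation carrying a shared monthly-climate signal, times a
#' deterministic drought multiplier `(1 - delta)` during calendar events
#' that relaxes linearly back to 1 over `recovery_years` after each event
#' (the stress-memory carryover). Defaults emulate a slow-growing cloud-
#' forest latewood stand: ~300-year series, moderate persistence
#' (`ar_phi = 0.3`), 20% lognormal noise, a shared climate signal strong
#' enough to give interseries correlations near 0.4-0.6, and a 40% growth
#' reduction in severe drought years.
#'
#' @param n_trees Number of trees (default 15).
#' @param year_range `c(first, last)` calendar years (default 1700-2022).
#' @param age_trend `c(initial_mm, rate)`: width `initial * exp(-rate *
#'   age)` (default 1.5 mm, 0.004 / yr).
#' @param ar_phi AR(1) coefficient of the log-growth deviation, in
#'   `[0, 0.9]` (default 0.3).
#' @param noise_sd Lognormal sigma of per-tree noise (default 0.2).
#' @param climate_beta Sensitivity of log growth to the standardized
#'   growing-season (Jun-Sep) precipitation anomaly (default 0.2).
#' @param drought_calendar A [drought_calendar] (default: the historical
#'   calendar).
#' @param drought_delta Fractional growth reduction in event years,
#'   `0 <= delta < 1` (default 0.4).
#' @param recovery_years Years over which the post-event deficit relaxes
#'   linearly to zero (default 2; 0 = instant recovery).
#' @param seed Master seed; per-tree and per-variable streams are derived
#'   from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_trees = 15L, year_range = c(1700L, 2022L),
                              age_trend = c(1.5, 0.004), ar_phi = 0.3,
                              noise_sd = 0.2, climate_beta = 0.2,
                              drought_calendar = default_drought_calendar(),
                              drought_delta = 0.4, recovery_years = 2L,
                              seed = 1L) {
  if (drought_delta < 0 || drought_delta >= 1)
    stop("drought_delta must be in [0, 1)")
  if (ar_phi < 0 || ar_phi > 0.9) stop("ar_phi must be in [0, 0.9]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (recovery_years < 0L) stop("recovery_years must be >= 0")
  structure(list(n_trees = as.integer(n_trees),
                 year_range = as.integer(year_range),
                 age_trend = as.numeric(age_trend), ar_phi = ar_phi,
                 noise_sd = noise_sd, climate_beta = climate_beta,
                 drought_calendar = drought_calendar,
                 drought_delta = drought_delta,
                 recovery_years = as.integer(recovery_years),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# monthly climatology per variable: mean, seasonal amplitude, noise sd,
# and the anomaly applied in drought-calendar years
.climate_spec <- list(
  Prec  = list(mean = 90, amp = 60, sd = 25, drought = list(mult = 0.65)),
  EvT   = list(mean = 70, amp = 30, sd = 10, drought = list(mult = 1.10)),
  Tmax  = list(mean = 24, amp = 6,  sd = 1,  drought = list(add = 1.5)),
  Tmin  = list(mean = 10, amp = 5,  sd = 1,  drought = list(add = 1.0)),
  PDSI  = list(mean = 0,  amp = 0,  sd = 2,  drought = list(add = -2.5)),
  SPEI6 = list(mean = 0,  amp = 0,  sd = 1,  drought = list(add = -1.2)))

#' Simulate monthly climate tables
#'
#' One table per variable (Prec, EvT, Tmax, Tmin, PDSI, SPEI6): a
#' sinusoidal seasonal cycle peaking in July plus Gaussian noise;
#' drought-calendar years receive a precipitation deficit (-35%), an
#' evapotranspiration surplus, warmer temperatures and depressed drought
#' indices. Deterministic per seed.
#'
#' @param config A [simulation_config].
#' @param seed Seed (defaults to `config$seed`).
#' @return Named list of [climate_table] objects.
#' @export
simulate_climate <- function(config, seed = config$seed) {
  yrs <- seq.int(config$year_range[1L], config$year_range[2L])
  n <- length(yrs)
  cal <- config$drought_calendar
  in_drought <- vapply(yrs, function(y)
    any(y >= cal$start & y <= cal$end), logical(1))
  season <- sin(2 * pi * ((1:12) - 4) / 12)   # peaks in July
  out <- list()
  for (k in seq_along(.climate_spec)) {
    v <- names(.climate_spec)[k]
    sp <- .climate_spec[[k]]
    set.seed(seed + 7L * k)
    m <- matrix(rep(sp$mean + sp$amp * season, each = n), n, 12L) +
      matrix(stats::rnorm(n * 12L, 0, sp$sd), n, 12L)
    if (!is.null(sp$drought$mult)) m[in_drought, ] <- m[in_drought, ] * sp$drought$mult
    if (!is.null(sp$drought$add))  m[in_drought, ] <- m[in_drought, ] + sp$drought$add
    if (v %in% c("Prec", "EvT")) m <- pmax(m, 0)
    out[[v]] <- climate_table(v, yrs, m)
  }
  out
}

# per-year drought multiplier: (1 - delta) inside events, linear relaxation
# of the deficit over recovery_years after each event end
.drought_multipliers <- function(years, calendar, delta, recovery_years) {
  d <- rep(1, length(years))
  for (k in seq_len(nrow(calendar))) {
    ev <- years >= calendar$start[k] & years <= calendar$end[k]
    d[ev] <- 1 - delta
    if (recovery_years > 0L) {
      for (j in seq_len(recovery_years)) {
        i <- which(years == calendar$end[k] + j)
        if (length(i)) {
          rel <- 1 - delta * (1 - j / (recovery_years + 1))
          d[i] <- min(d[i], rel)   # an overlapping next event wins
        }
      }
    }
  }
  d
}

#' Simulate a ring-width forest with known ground truth
#'
#' Generates the shared climate, derives the standardized growing-season
#' (Jun-Sep) precipitation anomaly `z_t`, and grows each tree as
#' `width_t = agecurve_t * exp(u_t) * d_t` with
#' `u_t = phi * u_[t-1] + beta * z_t + eps_t`, `eps ~ N(0, sigma^2)`
#' independent per tree, and `d_t` the shared drought multiplier.
#' The drought reduction acts on the level (not the log-AR state), so
#' event-year resistance targets `1 - delta` exactly. Widths are floored
#' at 0.01 mm.
#'
#' @param config A [simulation_config].
#' @return Object of class `synthetic_forest`: `collection` (LATEWOOD
#'   [series_collection]), `climate` (list of [climate_table]), and
#'   `truth` (the config plus realized per-year multipliers `d`, the
#'   climate anomaly `z`, and the year axis).
#' @export
simulate_forest <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  yrs <- seq.int(config$year_range[1L], config$year_range[2L])
  n <- length(yrs)
  climate <- simulate_climate(config)
  gs <- rowMeans(climate$Prec$values[, 6:9, drop = FALSE])
  z <- as.numeric(scale(gs))
  d <- .drought_multipliers(yrs, config$drought_calendar,
                            config$drought_delta, config$recovery_years)
  age <- config$age_trend[1L] * exp(-config$age_trend[2L] * (seq_len(n) - 1L))
  series <- vector("list", config$n_trees)
  for (i in seq_len(config$n_trees)) {
    set.seed(config$seed + 1000L + i)
    eps <- stats::rnorm(n, 0, config$noise_sd)
    u <- numeric(n)
    u[1L] <- config$climate_beta * z[1L] + eps[1L]
    for (t in seq.int(2L, n))
      u[t] <- config$ar_phi * u[t - 1L] + config$climate_beta * z[t] + eps[t]
    w <- pmax(age * exp(u) * d, 0.01)
    series[[i]] <- ring_series(sprintf("SIM%02d", i), yrs[1L], w,
                               component = "LATEWOOD")
  }
  structure(list(
    collection = series_collection(series, site_id = "SYNTH",
                                   species = "synthetic",
                                   component = "LATEWOOD"),
    climate = climate,
    truth = c(unclass(config), list(d = d, z = z, years = yrs))),
    class = "synthetic_forest")
}

#' @export
print.synthetic_forest <- function(x, ...) {
  cat(sprintf("<synthetic_forest> %d trees, %d-%d, delta = %.2f, phi = %.2f\n",
              length(x$collection), x$truth$year_range[1L],
              x$truth$year_range[2L], x$truth$drought_delta, x$truth$ar_phi))
  invisible(x)
}
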