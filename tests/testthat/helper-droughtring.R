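# Independent oracles and fixture builders shared across the suite.

# Independent Tukey biweight oracle: minimizes the biweight rho objective
# directly (golden-section via optimize), no reuse of the package's
# weighted-mean iteration.
oracle_biweight <- function(x, c = 9) {
  s <- median(abs(x - median(x)))
  if (s == 0) return(median(x))
  rho <- function(t) {
    u <- (x - t) / (c * s)
    r <- ifelse(abs(u) < 1, 1 - (1 - u^2)^3, 1)
    sum(r)
  }
  # the objective is non-convex (far outliers carve local minima), so
  # locate the global basin by grid search, then refine locally
  grid <- seq(min(x), max(x), length.out = 20001L)
  g0 <- grid[which.min(vapply(grid, rho, numeric(1)))]
  h <- diff(range(x)) / 20000
  stats::optimize(rho, c(g0 - h, g0 + h), tol = 1e-10)$minimum
}

# wrap a bare index vector as an index_series without going through
# standardize()
make_index_series <- function(values, first_year = 1700L, id = "T1",
                              component = "LATEWOOD") {
  structure(list(series_id = id, first_year = as.integer(first_year),
                 indices = as.numeric(values), component = component,
                 config = NULL),
            class = "index_series")
}

make_chronology <- function(index, first_year = 1700L, depth = 1L) {
  yrs <- seq.int(first_year, first_year + length(index) - 1L)
  structure(list(component = "LATEWOOD", years = yrs,
                 index = as.numeric(index),
                 sample_depth = rep(as.integer(depth), length(index)),
                 stats = NULL),
            class = "chronology")
}

# least-squares sinusoid amplitude on the interior of a fitted curve,
# excluding wavelength/2 at each edge (the spectral oracle for the spline)
fitted_sine_amplitude <- function(fit, period) {
  n <- length(fit)
  edge <- ceiling(period / 2)
  i <- seq.int(edge + 1L, n - edge)
  X <- cbind(sin(2 * pi * i / period), cos(2 * pi * i / period))
  cf <- stats::coef(stats::lm(fit[i] ~ X - 1))
  sqrt(sum(cf^2))
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
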