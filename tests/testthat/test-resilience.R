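test_that("drought calendar: default events, validation", {
  cal <- default_drought_calendar()
  expect_equal(nrow(cal), 9L)
  expect_equal(cal$start[1], 1750L)
  expect_equal(cal$end[9], 2022L)
  expect_true(all(cal$start <= cal$end))
  expect_true(all(diff(cal$start) > 0))
  expect_error(drought_calendar(rbind(c(1900, 1890))), "<= end")
  expect_error(drought_calendar(rbind(c(1900, 1905), c(1903, 1910))),
               "overlap")
})

test_that("indices_at_year: hand cases and the Rs = Rt * Rc identity", {
  flat <- make_index_series(rep(1, 11), 2000)
  v <- indices_at_year(flat, 2005)
  expect_equal(unname(v), c(1, 1, 1))

  # pre (1, 1), x_t = 0.5, post (0.75, 0.75)
  s <- make_index_series(c(1, 1, 1, 1, 0.5, 0.75, 0.75, 1), 2000)
  v <- indices_at_year(s, 2004)
  expect_equal(v[["Rt"]], 0.5)
  expect_equal(v[["Rc"]], 1.5)
  expect_equal(v[["Rs"]], 0.75)

  # LAG1 mode divides by x_{t-1} instead of the pre mean
  s2 <- make_index_series(c(1, 0.8, 0.5, 0.75, 0.75), 2000)
  v2 <- indices_at_year(s2, 2002,
                        resilience_config(rs_denominator = "LAG1"))
  expect_equal(v2[["Rs"]], 0.75 / 0.8)

  # identity holds for arbitrary positive input under PRE_MEAN
  set.seed(21)
  for (i in 1:50) {
    x <- make_index_series(exp(rnorm(9, 0, 0.4)), 1990)
    vv <- indices_at_year(x, 1994)
    expect_equal(vv[["Rs"]], vv[["Rt"]] * vv[["Rc"]], tolerance = 1e-14)
  }

  # ineligible years are skipped with a reason
  out <- indices_at_year(flat, 2001)
  expect_length(out, 0)
  expect_match(attr(out, "reason"), "span")
  zer <- make_index_series(c(0, 0, 1, 1, 1), 2000)
  out2 <- indices_at_year(zer, 2002)
  expect_match(attr(out2, "reason"), "denominator")
})

test_that("evaluate_resilience enumerates eligible years deterministically", {
  full <- make_index_series(rep(1, 277), 1748)   # 1748-2024
  rec <- evaluate_resilience(list(full))
  expect_equal(nrow(rec), 273L)                  # 1750..2022 inclusive
  expect_equal(range(rec$year), c(1750L, 2022L))

  none <- make_index_series(rep(1, 20), 1900)    # outside eval range
  expect_equal(nrow(evaluate_resilience(
    list(none), resilience_config(eval_range = c(1700, 1800)))), 0L)

  a <- make_index_series(exp(rnorm(280, 0, 0.2)), 1745, "A")
  b <- a; b$series_id <- "B"
  rec2 <- evaluate_resilience(list(b, a))
  halves <- split(rec2[c("year", "Rt", "Rc", "Rs")], rec2$tree_id)
  expect_equal(halves$A, halves$B, ignore_attr = TRUE)
  expect_equal(rec2$tree_id, sort(rec2$tree_id))  # (tree_id, year) order
})

test_that("decline phase: hand fixtures, tie rule, flank errors", {
  # flanks all 1.0, event years {0.6, 0.8}, minimum at the start year
  x <- make_index_series(c(rep(1, 5), 0.6, 0.8, rep(1, 5)), 2000)
  d <- detect_decline_phase(x, c(2005, 2006))
  expect_equal(d$Pre5, 1.0)
  expect_equal(d$Min, 0.6)
  expect_equal(d$min_year, 2005L)
  expect_equal(d$Dt, 1L)
  expect_equal(d$DecU, 0.4)
  expect_false(d$negative_decu)

  # flat series: Pre5 = Min, DecU = 0
  flat <- make_index_series(rep(1, 20), 2000)
  expect_equal(detect_decline_phase(flat, c(2006, 2008))$DecU, 0)

  # tie at the minimum resolves to the LATEST year
  y <- make_index_series(c(rep(1, 5), 0.9, 0.4, 0.4, rep(1, 5)), 2000)
  dt <- detect_decline_phase(y, c(2005, 2007))
  expect_equal(dt$min_year, 2007L)
  expect_equal(dt$Dt, 3L)
  expect_equal(dt$DecU, (1 - 0.4) / 3)

  # flank beyond the span errors and lists the missing years
  expect_error(detect_decline_phase(x, c(2002, 2003)),
               "missing years: 1997, 1998, 1999")

  # negative DecU (event above flank level) is kept and flagged
  up <- make_index_series(c(rep(1, 5), 1.5, rep(1, 5)), 2000)
  du <- detect_decline_phase(up, c(2005, 2005))
  expect_lt(du$DecU, 0)
  expect_true(du$negative_decu)
})

test_that("flank years inside other calendar events are excluded from Pre5", {
  cal <- drought_calendar(rbind(c(2005, 2006), c(2008, 2009)))
  x <- make_index_series(c(rep(1, 5), 0.6, 0.6, 1, 5, 5, rep(1, 5)), 2000)
  # without the calendar, the 2008-2009 spike (5, 5) pollutes the flank
  d_raw <- detect_decline_phase(x, c(2005, 2006))
  d_cal <- detect_decline_phase(x, c(2005, 2006), calendar = cal)
  expect_gt(d_raw$Pre5, d_cal$Pre5)
  expect_equal(d_cal$Pre5, 1)        # 5 pre years + 2008-09 dropped, rest 1.0
})

test_that("decline_records skips out-of-span events and keeps the rest", {
  s <- make_index_series(exp(rnorm(200, 0, 0.2)), 1850, "T1")  # 1850-2049
  cal <- default_drought_calendar()
  rec <- decline_records(list(s), cal)
  # events needing flanks within 1850-2049: all from 1894 onward
  expect_equal(sort(unique(rec$event_start)),
               c(1894L, 1909L, 1951L, 2011L, 2020L))
  expect_true(all(rec$Dt >= 1))
  expect_true(all(rec$decline_start_year <= rec$min_year))
})

test_that("scaling invariance: ratios unchanged, DecU scales by k", {
  set.seed(77)
  x <- exp(rnorm(40, 0, 0.3))
  k <- 3.7
  s1 <- make_index_series(x, 2000)
  s2 <- make_index_series(k * x, 2000)
  v1 <- indices_at_year(s1, 2015); v2 <- indices_at_year(s2, 2015)
  expect_equal(v1, v2, tolerance = 1e-12)
  d1 <- detect_decline_phase(s1, c(2015, 2017))
  d2 <- detect_decline_phase(s2, c(2015, 2017))
  expect_equal(d2$DecU, k * d1$DecU, tolerance = 1e-12)
  expect_equal(d2$Dt, d1$Dt)
})

test_that("low-growth periods: imposed depression found, short runs ignored", {
  set.seed(12)
  base <- 1 + rnorm(120, 0, 0.05)
  ch <- make_chronology(base, 1900)
  expect_equal(nrow(low_growth_periods(ch, k = 3)), 0L)

  dep <- base; dep[41:44] <- dep[41:44] - 6 * sd(base)   # 1940-1943
  chd <- make_chronology(dep, 1900)
  runs <- low_growth_periods(chd, k = 2, min_run = 2)
  expect_equal(runs$start, 1940L)
  expect_equal(runs$end, 1943L)

  spike <- base; spike[60] <- spike[60] - 8 * sd(base)
  expect_equal(nrow(low_growth_periods(make_chronology(spike, 1900),
                                       k = 2, min_run = 2)), 0L)

  const <- make_chronology(rep(1, 50), 1900)
  expect_equal(nrow(low_growth_periods(const)), 0L)
  expect_error(low_growth_periods(make_chronology(rnorm(10), 1900)),
               "too short")
})

test_that("density summaries integrate to one and recover known skewness", {
  set.seed(2024)
  sym <- rnorm(10000)
  ds <- density_summary(sym, "Rt")
  expect_lt(abs(ds$skewness), 0.1)
  expect_equal(trapezoid(ds$grid, ds$density), 1, tolerance = 0.02)
  expect_true(all(ds$density >= 0))

  expo <- rexp(10000)
  de <- density_summary(expo, "DecU")
  expect_equal(de$skewness, 2, tolerance = 0.15)

  expect_error(density_summary(rep(1, 10), "Rs"), "zero-variance")
  expect_error(density_summary(c(1, 2, 3), "Rc"), "n >= 5")
})
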