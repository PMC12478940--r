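test_that("event binning uses half-open bins and conserves totals", {
  ev <- tibble::tibble(time_min = c(30, 90, 150))  # 0.5 h, 1.5 h, 2.5 h
  b <- bin_events(ev)
  expect_equal(b$count, c(2L, 1L))
  expect_equal(b$bin_start_h, c(0, 2))
  # no events: all-zero counts over the requested span
  b0 <- bin_events(tibble::tibble(time_min = numeric(0)), span_h = 12)
  expect_equal(sum(b0$count), 0L)
  expect_equal(nrow(b0), 6L)
  # 14-day span at 2 h -> 168 bins
  b14 <- bin_events(tibble::tibble(time_min = c(100, 200000)), span_h = 336)
  expect_equal(nrow(b14), 168L)
  # conservation for arbitrary widths
  set.seed(9)
  times <- runif(200, 0, 336 * 60)
  for (w in c(0.5, 2, 7)) {
    bb <- bin_events(tibble::tibble(time_min = times), bin_h = w, span_h = 340)
    expect_equal(sum(bb$count), 200L)
  }
})

test_that("the periodogram peaks at the true period of a clean sinusoid", {
  t <- seq(1, 335, by = 2)
  for (P in c(19, 24, 28.3)) {
    y <- 5 + 3 * cos(2 * pi * t / P + 1)
    pg <- lomb_scargle(data.frame(bin_mid_h = t, count = y))
    expect_lt(abs(pg$peak_period_h - P), 0.1 + 1e-9)
    expect_lt(pg$p_value, 1e-6)
  }
})

test_that("a constant series has zero power everywhere and p-value 1", {
  pg <- lomb_scargle(data.frame(bin_mid_h = seq(0, 100, 2), count = 4))
  expect_true(all(pg$power == 0))
  expect_equal(pg$p_value, 1)
  expect_error(lomb_scargle(data.frame(bin_mid_h = 1:5, count = 1:5)), "at least 8")
})

test_that("normalized power is invariant to count offset and positive scaling", {
  set.seed(14)
  t <- seq(1, 335, by = 2)
  y <- rpois(length(t), 3)
  p1 <- lomb_scargle(data.frame(bin_mid_h = t, count = y))$power
  p2 <- lomb_scargle(data.frame(bin_mid_h = t, count = y + 7))$power
  p3 <- lomb_scargle(data.frame(bin_mid_h = t, count = y * 3.5))$power
  expect_equal(p1, p2, tolerance = 1e-10)
  expect_equal(p1, p3, tolerance = 1e-10)
})

test_that("power agrees with an independent Lomb-Scargle implementation", {
  # scipy.signal.lombscargle normalizes by sum(y^2)/2 of the centred data;
  # our classical normalization divides by the sample variance, so
  # power_ours = power_scipy * (n - 1) / 2.
  set.seed(3)
  t <- sort(runif(40, 0, 300))
  y <- 2 + 1.5 * cos(2 * pi * t / 26) + rnorm(40, 0, 0.5)
  periods <- seq(15, 35, 0.5)
  mine <- lomb_scargle(data.frame(bin_mid_h = t, count = y), periods_h = periods)
  fx <- withr::local_tempfile(fileext = ".csv")
  fp <- withr::local_tempfile(fileext = ".csv")
  fo <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t = t, y = y), fx, row.names = FALSE)
  utils::write.csv(data.frame(period = periods), fp, row.names = FALSE)
  code <- paste(
    "import numpy as np, pandas as pd",
    "from scipy.signal import lombscargle",
    sprintf("d = pd.read_csv(%s)", shQuote(fx)),
    sprintf("periods = pd.read_csv(%s).period.values", shQuote(fp)),
    "t, y = d.t.values, d.y.values",
    "p = lombscargle(t, y - y.mean(), 2*np.pi/periods, normalize=True)",
    sprintf("pd.DataFrame({'power': p}).to_csv(%s, index=False)", shQuote(fo)),
    sep = "; ")
  status <- system2("python", c("-c", shQuote(code)))
  expect_equal(status, 0L)
  ref <- utils::read.csv(fo)$power * (length(y) - 1) / 2
  expect_equal(mine$periodogram$power, ref, tolerance = 1e-8)
})

test_that("estimate_rhythm recovers preset periods from event streams", {
  for (nm in c("iso31", "per_short")) {
    p <- rhythm_preset(nm)
    peaks <- vapply(1:5, function(s) {
      ev <- sample_eclosion_times(p, seed = 600 + s)
      estimate_rhythm(data.frame(time_min = ev * 60))$peak_period_h
    }, numeric(1))
    tol <- p$period_h^2 / p$duration_h  # one spectral resolution element
    expect_lt(abs(median(peaks) - p$period_h), tol)
  }
  expect_error(estimate_rhythm(tibble::tibble(time_min = numeric(0))), "no events")
})
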