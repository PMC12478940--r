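#' Bin event times into fixed-width time slices
#'
#' Aggregates event records into half-open bins
#' `[t0 + k*bin_h, t0 + (k+1)*bin_h)` of `bin_h` hours (default 2 h, the
#' standard actogram-style aggregation). Totals are conserved: every event
#' inside the requested span falls in exactly one bin.
#'
#' @param events Event tibble with a `time_min` column (minutes since
#'   experiment start), e.g. from [collect_events()].
#' @param bin_h Bin width in hours (default 2).
#' @param t0 Left edge of the first bin, hours (default 0).
#' @param span_h Total span covered, hours; default extends to the last
#'   event.
#' @return Tibble with `bin_start_h`, `bin_mid_h`, `count`; bin width kept
#'   in attribute `bin_h`.
#' @examples
#' ev <- tibble::tibble(time_min = c(30, 90, 150))
#' bin_events(ev)$count  # 2 events in [0,2), 1 in [2,4)
#' @export
bin_events <- function(events, bin_h = 2, t0 = 0, span_h = NULL) {
  stopifnot(is.data.frame(events), bin_h > 0)
  t_h <- sort(events$time_min) / 60
  if (is.null(span_h)) {
    span_h <- if (length(t_h)) max(t_h) - t0 + 1e-9 else bin_h
  }
  n_bins <- max(1L, ceiling(span_h / bin_h))
  edges <- t0 + bin_h * (0:n_bins)
  inside <- t_h >= edges[1L] & t_h < edges[n_bins + 1L]
  counts <- tabulate(findInterval(t_h[inside], edges), nbins = n_bins)
  out <- tibble(
    bin_start_h = edges[-(n_bins + 1L)],
    bin_mid_h = edges[-(n_bins + 1L)] + bin_h / 2,
    count = as.integer(counts)
  )
  attr(out, "bin_h") <- bin_h
  out
}

#' Classical normalized Lomb-Scargle periodogram
#'
#' Computes the Scargle least-squares spectral power of a counts-versus-time
#' series at each test period, normalized by the sample variance of the
#' (mean-subtracted) values, with the usual phase offset tau that makes the
#' sine and cosine terms orthogonal at each frequency. Power is invariant
#' under adding a constant to all counts and under positive rescaling. The
#' peak's significance is the standard analytic estimate for the maximum of
#' the periodogram, `p = 1 - (1 - exp(-z))^M`, with the number of
#' independent frequencies `M` approximated as series span divided by the
#' shortest test period — an approximation, documented as such.
#'
#' @param series Binned series from [bin_events()] (columns `bin_mid_h`,
#'   `count`), or any data frame with time/value columns named by
#'   `time_col`/`value_col`.
#' @param periods_h Grid of test periods in hours (default 14-34 h in 0.1 h
#'   steps, bracketing all circadian periods of interest).
#' @param time_col,value_col Column names (defaults `bin_mid_h`, `count`).
#' @return Object of class `ls_periodogram`: list with `periodogram`
#'   (tibble `period_h`, `power`), `peak_period_h`, `peak_power`,
#'   `p_value`, `n_obs`, `m_indep`. A constant (or near-empty) series gives
#'   flat zero power and `p_value = 1`.
#' @examples
#' t <- seq(1, 335, by = 2)
#' y <- 5 + 3 * cos(2 * pi * t / 24)
#' pg <- lomb_scargle(data.frame(bin_mid_h = t, count = y))
#' pg$peak_period_h  # 24
#' @export
lomb_scargle <- function(series, periods_h = seq(14, 34, by = 0.1),
                         time_col = "bin_mid_h", value_col = "count") {
  stopifnot(is.data.frame(series), all(periods_h > 0))
  t <- series[[time_col]]
  y <- as.numeric(series[[value_col]])
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  n <- length(y)
  if (n < 8L) abort("Lomb-Scargle needs at least 8 time points")
  span <- diff(range(t))
  m_indep <- max(1, span / min(periods_h))
  y <- y - mean(y)
  s2 <- var(y)
  if (!is.finite(s2) || s2 <= 0) {
    power <- rep(0, length(periods_h))
  } else {
    omega <- 2 * pi / periods_h
    power <- vapply(omega, function(w) {
      tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
      ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
      (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * s2)
    }, numeric(1))
  }
  peak_i <- which.max(power)
  z <- power[peak_i]
  p_value <- if (z <= 0) 1 else 1 - (1 - exp(-z))^m_indep
  structure(
    list(
      periodogram = tibble(period_h = periods_h, power = power),
      peak_period_h = periods_h[peak_i],
      peak_power = z,
      p_value = min(max(p_value, 0), 1),
      n_obs = n,
      m_indep = m_indep
    ),
    class = "ls_periodogram"
  )
}

#' Estimate the eclosion rhythm period from event records
#'
#' Convenience composition of [bin_events()] and [lomb_scargle()]: events
#' are aggregated into `bin_h`-hour slices spanning from the first to the
#' last event (the first bin edge snapped down to the bin grid — the weeks
#' before eclosion onset contain no rhythm information, only a step), and
#' the normalized Lomb-Scargle periodogram is evaluated on the default
#' 14-34 h grid, which brackets the circadian periods of wild-type and
#' *period*-mutant flies (about 19, 24 and 28 h).
#'
#' @param events Event tibble with `time_min`.
#' @param bin_h Bin width, hours (default 2).
#' @param period_range Length-2 numeric, hours (default `c(14, 34)`).
#' @param period_step Grid step, hours (default 0.1).
#' @return An `ls_periodogram` (see [lomb_scargle()]).
#' @export
estimate_rhythm <- function(events, bin_h = 2, period_range = c(14, 34),
                            period_step = 0.1) {
  stopifnot(is.data.frame(events), length(period_range) == 2L)
  if (!nrow(events)) abort("no events to analyse")
  t_h <- events$time_min / 60
  t0 <- floor(min(t_h) / bin_h) * bin_h
  series <- bin_events(events, bin_h = bin_h, t0 = t0,
                       span_h = max(t_h) - t0 + 1e-9)
  lomb_scargle(series, periods_h = seq(period_range[1L], period_range[2L],
                                       by = period_step))
}

#' @export
print.ls_periodogram <- function(x, ...) {
  cat("<ls_periodogram>\n")
  cat(sprintf("  peak period: %.2f h (power %.2f, p = %.3g)\n",
              x$peak_period_h, x$peak_power, x$p_value))
  cat(sprintf("  %d time points, %d test periods, M = %.1f\n",
              x$n_obs, nrow(x$periodogram), x$m_indep))
  invisible(x)
}

#' Tidy a Lomb-Scargle periodogram
#'
#' @param x An `ls_periodogram`.
#' @param ... Unused.
#' @return `tidy()`: tibble of `period_h`, `power` (one row per test
#'   period); `glance()`: one-row tibble with `peak_period_h`,
#'   `peak_power`, `p_value`, `n_obs`, `m_indep`.
#' @export
tidy.ls_periodogram <- function(x, ...) x$periodogram

#' @rdname tidy.ls_periodogram
#' @export
glance.ls_periodogram <- function(x, ...) {
  tibble(peak_period_h = x$peak_period_h, peak_power = x$peak_power,
         p_value = x$p_value, n_obs = x$n_obs, m_indep = x$m_indep)
}

#' Plot a Lomb-Scargle periodogram
#'
#' @param object An `ls_periodogram`.
#' @param ... Unused.
#' @return A ggplot: power against test period with the peak marked.
#' @export
autoplot.ls_periodogram <- function(object, ...) {
  ggplot2::ggplot(object$periodogram, ggplot2::aes(.data$period_h, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_period_h,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::annotate("text", x = object$peak_period_h, y = object$peak_power,
                      label = sprintf(" %.1f h", object$peak_period_h),
                      hjust = 0, vjust = 1) +
    ggplot2::labs(x = "period (h)", y = "normalized power")
}

#' Plot binned eclosion counts over time
#'
#' Bar-style view of event counts per time slice, the standard way of
#' displaying eclosion activity across a multi-day recording.
#'
#' @param series Binned series from [bin_events()].
#' @return A ggplot.
#' @export
plot_event_series <- function(series) {
  stopifnot(is.data.frame(series))
  ggplot2::ggplot(series, ggplot2::aes(.data$bin_mid_h / 24, .data$count)) +
    ggplot2::geom_col(width = (attr(series, "bin_h") %||% 2) / 24) +
    ggplot2::labs(x = "time (days)", y = "events per bin")
}
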