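#' Construct a one-day irradiance series
#'
#' Minute-resolution PAR trace for a single calendar day, as produced by a
#' logger recording every minute across a 05:00-19:30 window (at most 871
#' samples). Time is wall-clock local, stored as integer minutes since
#' midnight; no timezone arithmetic is done anywhere in the package.
#'
#' @param date calendar day, `"YYYY-MM-DD"` (used only as a key).
#' @param minute integer minutes since midnight, strictly increasing.
#' @param e_par PAR readings, \eqn{\mu}mol photons m\eqn{^{-2}}
#'   s\eqn{^{-1}}, non-negative.
#' @return object of class `irradiance_series` with a `samples` data.frame.
#' @export
irradiance_series <- function(date, minute, e_par) {
  if (length(minute) != length(e_par))
    stop("`minute` and `e_par` must have the same length")
  minute <- as.integer(minute)
  if (length(minute)) {
    if (is.unsorted(minute, strictly = TRUE))
      stop("`minute` must be strictly increasing")
    if (min(minute) < 0L || max(minute) > 1439L)
      stop("`minute` must lie within a single day (0..1439)")
  }
  if (length(minute) > 871L)
    stop("more than 871 samples for one day; check the logging window")
  if (any(!is.finite(e_par)) || any(e_par < 0))
    stop("`e_par` must be finite and non-negative")
  structure(list(date = as.character(date),
                 samples = data.frame(minute = minute,
                                      e_par = as.numeric(e_par))),
            class = "irradiance_series")
}

#' @export
print.irradiance_series <- function(x, ...) {
  n <- nrow(x$samples)
  cat("Irradiance series", x$date, sprintf("(%d samples", n))
  if (n) cat(sprintf(", %02d:%02d-%02d:%02d",
                     x$samples$minute[1] %/% 60, x$samples$minute[1] %% 60,
                     x$samples$minute[n] %/% 60, x$samples$minute[n] %% 60))
  cat(")\n")
  invisible(x)
}

#' Condense a 1-min irradiance series to a 10-min grid
#'
#' First a trailing 10-min moving average (the window ends at the labelled
#' minute; at the series start a shorter window uses whatever samples are
#' available), then only the values at clock minutes :00, :10, :20, :30,
#' :40, :50 are kept. A series too short to touch any grid minute is
#' condensed to a single value — the mean of all its samples — placed at
#' the next grid minute.
#'
#' @param series an [irradiance_series()].
#' @return object of class `condensed_series` (same shape, grid minutes
#'   only).
#' @export
condense_series <- function(series) {
  stopifnot(inherits(series, "irradiance_series"))
  m <- series$samples$minute
  e <- series$samples$e_par
  if (!length(m)) {
    return(structure(list(date = series$date,
                          samples = data.frame(minute = integer(),
                                               e_par = numeric())),
                     class = c("condensed_series")))
  }
  lo <- 10L * as.integer(ceiling(min(m) / 10))
  hi <- 10L * (max(m) %/% 10L)
  grid <- if (lo <= hi) seq.int(lo, hi, by = 10L) else integer()
  if (!length(grid)) {
    grid <- 10L * as.integer(ceiling(max(m) / 10))
    vals <- mean(e)
  } else {
    vals <- vapply(grid, function(t) {
      w <- m >= t - 9L & m <= t
      mean(e[w])
    }, numeric(1))
  }
  structure(list(date = series$date,
                 samples = data.frame(minute = as.integer(grid),
                                      e_par = vals)),
            class = "condensed_series")
}

#' Day length from a condensed series
#'
#' Minutes of daylight, defined as the time PAR is at least
#' 1 \eqn{\mu}mol photons m\eqn{^{-2}} s\eqn{^{-1}} on the condensed
#' 10-min grid: (number of grid samples >= 1) x 10 min.
#'
#' @param condensed a [condense_series()] result.
#' @return day length in minutes.
#' @export
day_length <- function(condensed) {
  stopifnot(inherits(condensed, "condensed_series"))
  10L * sum(condensed$samples$e_par >= 1)
}

#' Map an experiment day to the E_k estimate that covers it
#'
#' A 9-day run is split into periods, each covered by the saturation
#' irradiance fitted from one RLC day. The `standard` scheme is
#' P1 = days 1-3 (D1 E_k), P2 = days 4-5 (D5 E_k), P3 = days 6-9 (D9 E_k).
#' The `no_d5` scheme, for plants without a D5 measurement, uses D1 E_k for
#' days 1-4 and D9 E_k for days 5-9.
#'
#' @param day_index experiment day, 1..9.
#' @param ek_by_day named numeric; names among `"D1"`, `"D5"`, `"D9"`.
#' @param scheme `"standard"` or `"no_d5"`.
#' @return the mapped E_k (scalar).
#' @examples
#' assign_period_ek(2, c(D1 = 80, D5 = 90, D9 = 100))        # 80
#' assign_period_ek(4, c(D1 = 80, D9 = 100), scheme = "no_d5") # 80
#' @export
assign_period_ek <- function(day_index, ek_by_day,
                             scheme = c("standard", "no_d5")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(day_index) || day_index < 1 || day_index > 9)
    stop("`day_index` must be in 1..9")
  lab <- if (scheme == "standard") {
    if (day_index <= 3) "D1" else if (day_index <= 5) "D5" else "D9"
  } else {
    if (day_index <= 4) "D1" else "D9"
  }
  ek <- ek_by_day[lab]
  if (is.null(ek) || !lab %in% names(ek_by_day) || is.na(ek))
    stop("period scheme '", scheme, "' needs an E_k fit for ", lab,
         " (day ", day_index, "), which is missing")
  unname(ek)
}

#' Daily time in saturating irradiance
#'
#' Counts the minutes of a raw 1-min trace, inside an optional clock
#' window, whose PAR is at or above the plant's saturation irradiance
#' E_k. The window models the truncation of first/last experiment days
#' (irradiance starts at the plant's first RLC and ends at its final RLC);
#' a window extending beyond the logged span is clipped with a warning.
#'
#' @param series an [irradiance_series()] (raw 1-min resolution).
#' @param ek saturation irradiance (> 0).
#' @param window optional `c(start, end)` clock minutes; `NULL` for the
#'   full logged span.
#' @return H_sat for that day, in minutes (integer count).
#' @export
hsat_day <- function(series, ek, window = NULL) {
  stopifnot(inherits(series, "irradiance_series"))
  if (!is.finite(ek) || ek <= 0) stop("`ek` must be > 0")
  m <- series$samples$minute
  if (!length(m)) return(0L)
  if (is.null(window)) {
    window <- c(min(m), max(m))
  } else {
    stopifnot(length(window) == 2L, window[1] <= window[2])
    if (window[1] < min(m) || window[2] > max(m)) {
      warning("window [", window[1], ", ", window[2],
              "] extends beyond the logged span [", min(m), ", ", max(m),
              "]; clipping")
      window <- c(max(window[1], min(m)), min(window[2], max(m)))
    }
  }
  inside <- m >= window[1] & m <= window[2]
  sum(series$samples$e_par[inside] >= ek)
}

#' Mean H_sat across a run
#'
#' Averages daily H_sat values either as the mean of the period means
#' (each period of the scheme contributes equally, regardless of how many
#' days it spans — the default) or as the plain mean over all days
#' (`mode = "all_days"`). Periods with no in-scope days are dropped.
#'
#' @param daily_hsat numeric vector of daily H_sat, minutes; element `i`
#'   is experiment day `i`.
#' @param scheme period scheme, as in [assign_period_ek()].
#' @param mode `"period_means"` or `"all_days"`.
#' @return mean H_sat in minutes.
#' @examples
#' mean_hsat(c(300, 300, 300, 360, 360, 420, 420, 420, 420)) # 360
#' @export
mean_hsat <- function(daily_hsat, scheme = c("standard", "no_d5"),
                      mode = c("period_means", "all_days")) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (!length(daily_hsat)) stop("`daily_hsat` is empty")
  if (any(!is.finite(daily_hsat)) || any(daily_hsat < 0))
    stop("`daily_hsat` must be finite and non-negative")
  if (mode == "all_days") return(mean(daily_hsat))
  periods <- if (scheme == "standard") list(1:3, 4:5, 6:9) else
    list(1:4, 5:9)
  pm <- vapply(periods, function(d) {
    d <- d[d <= length(daily_hsat)]
    if (!length(d)) NA_real_ else mean(daily_hsat[d])
  }, numeric(1))
  mean(pm[!is.na(pm)])
}

#' Relative H_sat: percent of daylight spent in saturation
#'
#' Per-day ratio of H_sat to day length, expressed in percent and averaged
#' over days. Days with zero day length are excluded with a warning.
#'
#' @param daily_hsat daily H_sat minutes.
#' @param daily_day_length matching day lengths, minutes.
#' @return percent in `[0, 100]`.
#' @examples
#' rel_hsat(c(300, 330), c(600, 660)) # 50
#' @export
rel_hsat <- function(daily_hsat, daily_day_length) {
  if (length(daily_hsat) != length(daily_day_length))
    stop("`daily_hsat` and `daily_day_length` must match in length")
  bad <- daily_day_length <= 0
  if (any(bad)) {
    warning(sum(bad), " day(s) with zero day length excluded from rel-H_sat")
    daily_hsat <- daily_hsat[!bad]
    daily_day_length <- daily_day_length[!bad]
  }
  if (!length(daily_hsat)) stop("no days with positive day length")
  mean(100 * daily_hsat / daily_day_length)
}
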