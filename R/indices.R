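#' Diurnal saturated photosynthesis index
#'
#' DSPI summarizes daily photosynthetic production assuming the plant runs
#' at its maximum rate \eqn{P_{max}} for the whole time it spends in
#' saturating irradiance: daily value
#' \deqn{DSPI_d = P_{max}(\mathrm{period}(d)) \times 60 \times H_{sat}(d)
#'   \times 10^{-6} \quad [\mathrm{mol\ m^{-2}}],}
#' where \eqn{P_{max}} (\eqn{\mu}mol electrons m\eqn{^{-2}} s\eqn{^{-1}})
#' is converted from per-second to per-minute to match the units of
#' \eqn{H_{sat}} (minutes), and the \eqn{10^{-6}} converts \eqn{\mu}mol to
#' mol. The per-day \eqn{P_{max}} follows the same period map as the E_k
#' used for H_sat ([assign_period_ek()]). The final index is the mean of
#' the daily values (default) or the mean of period means.
#'
#' @param pmax_by_day named numeric, P_max per RLC day (`"D1"`, `"D5"`,
#'   `"D9"` as required by `scheme`).
#' @param daily_hsat daily H_sat minutes; element `i` is experiment day `i`.
#' @param scheme period scheme, as in [assign_period_ek()].
#' @param mode averaging of daily values, `"all_days"` (default) or
#'   `"period_means"`.
#' @return object of class `dspi_result`: list with `daily_dspi`
#'   (mol m\eqn{^{-2}} per day) and `dspi` (final index, mol
#'   m\eqn{^{-2}}).
#' @examples
#' dspi(c(D1 = 50, D5 = 50, D9 = 50), rep(400, 9))$dspi # 1.2
#' @export
dspi <- function(pmax_by_day, daily_hsat, scheme = c("standard", "no_d5"),
                 mode = c("all_days", "period_means")) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (any(!is.finite(daily_hsat)) || any(daily_hsat < 0))
    stop("`daily_hsat` must be finite and non-negative")
  if (any(!is.finite(pmax_by_day)) || any(pmax_by_day < 0))
    stop("`pmax_by_day` must be finite and non-negative")
  days <- seq_along(daily_hsat)
  daily <- vapply(days, function(d) {
    pm <- pmax_by_day[if (scheme == "standard") {
      if (d <= 3) "D1" else if (d <= 5) "D5" else "D9"
    } else {
      if (d <= 4) "D1" else "D9"
    }]
    if (is.na(pm)) stop("missing P_max for the period covering day ", d)
    unname(pm) * 60 * daily_hsat[d] * 1e-6
  }, numeric(1))
  final <- if (mode == "all_days") {
    mean(daily)
  } else {
    periods <- if (scheme == "standard") list(1:3, 4:5, 6:9) else
      list(1:4, 5:9)
    pm <- vapply(periods, function(d) {
      d <- d[d <= length(daily)]
      if (!length(d)) NA_real_ else mean(daily[d])
    }, numeric(1))
    mean(pm[!is.na(pm)])
  }
  structure(list(daily_dspi = daily, dspi = final), class = "dspi_result")
}

#' @export
print.dspi_result <- function(x, ...) {
  cat(sprintf("DSPI = %.3f mol m-2 (mean of %d daily values)\n",
              x$dspi, length(x$daily_dspi)))
  invisible(x)
}

#' Nine-day growth as percent wet-weight change
#'
#' \deqn{100 \times \frac{(w_f - m_p) - w_i}{w_i}}
#' where \eqn{w_i} and \eqn{w_f} are initial (D1) and final (D9) wet
#' weights and \eqn{m_p} is the wet mass of any epiphytic parasite removed
#' from the final weighing (0 when none was found). No steady- or
#' exponential-growth assumption is made.
#'
#' @param w_i initial wet weight, g (> 0).
#' @param w_f final wet weight, g.
#' @param parasite_mass parasite wet mass subtracted from `w_f`, g
#'   (default 0; must be < `w_f`).
#' @return percent growth (vectorized).
#' @examples
#' growth_percent(0.30, 0.45)        # 50
#' growth_percent(0.30, 0.46, 0.01)  # 50
#' @export
growth_percent <- function(w_i, w_f, parasite_mass = 0) {
  if (any(!is.finite(w_i)) || any(!is.finite(w_f)))
    stop("weights must be finite")
  if (any(w_i <= 0)) stop("`w_i` must be > 0")
  if (any(parasite_mass < 0)) stop("`parasite_mass` must be >= 0")
  if (any(parasite_mass >= w_f))
    stop("`parasite_mass` must be smaller than `w_f`")
  100 * ((w_f - parasite_mass) - w_i) / w_i
}
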