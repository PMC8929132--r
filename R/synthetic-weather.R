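#' Site climate description for the stochastic weather generator
#'
#' A `site_climate` bundles the monthly statistics that drive [gen_weather()]:
#' mean daily maximum and minimum temperatures by month, the day-to-day
#' temperature noise scale and its lag-1 autocorrelation, the per-month
#' probability that a day is wet, the mean depth of a wet day, and the
#' seasonal amplitude of clear-sky radiation.
#'
#' @param monthly_tmax_mean Numeric length-12, mean daily maximum temperature
#'   per calendar month (degrees C).
#' @param monthly_tmin_mean Numeric length-12, mean daily minimum temperature
#'   per calendar month (degrees C). Must be below `monthly_tmax_mean`
#'   element-wise.
#' @param temp_sd Day-to-day standard deviation of the shared temperature
#'   residual (degrees C).
#' @param rain_prob_wet Numeric length-12 in `[0, 1]`, probability that a day
#'   is wet, per month.
#' @param rain_mean_depth Numeric length-12, mean rainfall on a wet day (mm).
#' @param rad_clear_sky_amp Seasonal amplitude of clear-sky solar radiation
#'   about a 16 MJ m-2 d-1 midpoint (MJ m-2 d-1, must leave radiation
#'   positive all year).
#' @param ar1_rho Lag-1 autocorrelation of the temperature residual, in
#'   `[0, 1)`.
#' @param name Optional site label carried into generated weather.
#'
#' @return An object of class `site_climate`.
#' @seealso [site_preset()] for ready-made Great Plains style climates.
#' @export
site_climate <- function(monthly_tmax_mean, monthly_tmin_mean, temp_sd = 3,
                         rain_prob_wet, rain_mean_depth,
                         rad_clear_sky_amp = 8, ar1_rho = 0.6,
                         name = "site") {
  stopifnot(length(monthly_tmax_mean) == 12L, length(monthly_tmin_mean) == 12L,
            length(rain_prob_wet) == 12L, length(rain_mean_depth) == 12L)
  if (any(monthly_tmax_mean <= monthly_tmin_mean))
    stop("monthly_tmax_mean must exceed monthly_tmin_mean in every month")
  if (any(rain_prob_wet < 0 | rain_prob_wet > 1))
    stop("rain_prob_wet must lie in [0, 1]")
  if (any(rain_mean_depth < 0)) stop("rain_mean_depth must be >= 0")
  if (temp_sd < 0) stop("temp_sd must be >= 0")
  if (ar1_rho < 0 || ar1_rho >= 1) stop("ar1_rho must lie in [0, 1)")
  if (rad_clear_sky_amp < 0 || rad_clear_sky_amp >= 16)
    stop("rad_clear_sky_amp must lie in [0, 16) so radiation stays positive")
  structure(list(monthly_tmax_mean = as.numeric(monthly_tmax_mean),
                 monthly_tmin_mean = as.numeric(monthly_tmin_mean),
                 temp_sd = temp_sd,
                 rain_prob_wet = as.numeric(rain_prob_wet),
                 rain_mean_depth = as.numeric(rain_mean_depth),
                 rad_clear_sky_amp = rad_clear_sky_amp,
                 ar1_rho = ar1_rho, name = name),
            class = "site_climate")
}

#' Ready-made site climates spanning a west-to-east rainfall gradient
#'
#' Three presets emulate the Great Plains sorghum belt: `"dry_west"` (hot,
#' roughly 300 mm annual rain), `"intermediate"` (about 550 mm) and
#' `"wet_east"` (milder summer, about 850 mm). The gradient is what lets the
#' pipeline demonstrate that terminal water-stress seasons dominate in the
#' west and low-stress seasons in the east.
#'
#' @param which One of `"dry_west"`, `"intermediate"`, `"wet_east"`.
#' @return A [site_climate()] object.
#' @export
site_preset <- function(which = c("dry_west", "intermediate", "wet_east")) {
  which <- match.arg(which)
  switch(which,
    dry_west = site_climate(
      monthly_tmax_mean = c(6, 9, 14, 20, 25, 31, 34, 33, 30, 23, 13, 7),
      monthly_tmin_mean = c(-8, -6, -2, 4, 10, 16, 19, 18, 13, 7, -2, -7),
      temp_sd = 4,
      rain_prob_wet    = c(.10, .10, .14, .16, .20, .20, .18, .16, .14, .12, .10, .10),
      rain_mean_depth  = c(2.5, 2.5, 4, 5, 7, 8, 8, 7, 5, 4, 3, 2.5),
      rad_clear_sky_amp = 9, ar1_rho = 0.65, name = "dry_west"),
    intermediate = site_climate(
      monthly_tmax_mean = c(5, 8, 14, 20, 25, 30, 33, 32, 29, 22, 12, 6),
      monthly_tmin_mean = c(-7, -5, 0, 6, 12, 17, 20, 19, 15, 8, 0, -5),
      temp_sd = 3.5,
      rain_prob_wet    = c(.15, .16, .20, .24, .30, .28, .24, .24, .22, .18, .16, .14),
      rain_mean_depth  = c(3.5, 4, 5.5, 7, 9, 10, 9, 8.5, 7, 6, 4.5, 3.5),
      rad_clear_sky_amp = 9, ar1_rho = 0.6, name = "intermediate"),
    wet_east = site_climate(
      monthly_tmax_mean = c(4, 7, 13, 19, 24, 29, 31, 31, 28, 22, 12, 6),
      monthly_tmin_mean = c(-6, -4, 1, 7, 13, 18, 20, 19, 15, 9, 1, -4),
      temp_sd = 3,
      rain_prob_wet    = c(.22, .24, .30, .34, .38, .36, .30, .30, .28, .26, .24, .22),
      rain_mean_depth  = c(4.5, 5, 7, 8.5, 10.5, 11, 10, 9.5, 8.5, 7.5, 5.5, 4.5),
      rad_clear_sky_amp = 8, ar1_rho = 0.55, name = "wet_east"))
}

month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

# Linear interpolation of 12 monthly values to day-of-year (mid-month knots,
# wrapped), so daily climatological means vary smoothly. 365-day years; leap
# days are not generated.
interp_monthly <- function(monthly, doy) {
  mids <- cumsum(month_days) - month_days / 2
  knots_x <- c(mids[12] - 365, mids, mids[1] + 365)
  knots_y <- c(monthly[12], monthly, monthly[1])
  stats::approx(knots_x, knots_y, xout = doy, rule = 2)$y
}

#' Generate daily weather for one site
#'
#' Daily maximum and minimum temperature are the monthly climatological means
#' interpolated to day-of-year plus a shared AR(1) Gaussian residual (lag-1
#' correlation `ar1_rho`, marginal standard deviation `temp_sd`) plus a
#' smaller independent disturbance on each bound; Tmin is clamped at least
#' 0.2 C below Tmax. Rain occurrence is an independent Bernoulli draw per day
#' with the month's wet probability; wet-day depth is exponential with the
#' month's mean. Radiation is a clear-sky seasonal sinusoid (peak at the
#' summer solstice) reduced by 25% on wet days.
#'
#' @param site A [site_climate()].
#' @param start_year First calendar year to generate.
#' @param n_years Number of consecutive 365-day years.
#' @param seed Integer seed; the whole series is reproducible from it.
#' @return A tibble with columns `date`, `year`, `doy`, `tmax`, `tmin`,
#'   `rain`, `radn` (ISO dates, degrees C, mm, MJ m-2 d-1).
#' @examples
#' w <- gen_weather(site_preset("dry_west"), 2001, 2, seed = 1)
#' all(w$tmax >= w$tmin)
#' @export
gen_weather <- function(site, start_year, n_years, seed) {
  stopifnot(inherits(site, "site_climate"))
  if (n_years < 1) stop("n_years must be >= 1")
  n <- 365L * as.integer(n_years)
  doy <- rep(seq_len(365L), n_years)
  year <- rep(start_year + seq_len(n_years) - 1L, each = 365L)
  month <- findInterval(doy, cumsum(c(0L, month_days[-12])) + 1L)

  withr::with_seed(seed, {
    # shared AR(1) residual with stationary marginal sd = temp_sd
    innov <- stats::rnorm(n, 0, site$temp_sd * sqrt(1 - site$ar1_rho^2))
    e <- numeric(n)
    e[1] <- stats::rnorm(1, 0, site$temp_sd)
    for (i in 2:n) e[i] <- site$ar1_rho * e[i - 1] + innov[i]
    u_max <- stats::rnorm(n, 0, site$temp_sd / 2)
    u_min <- stats::rnorm(n, 0, site$temp_sd / 2)
    wet <- stats::runif(n) < site$rain_prob_wet[month]
    depth <- stats::rexp(n, 1) * site$rain_mean_depth[month]
  })

  tmax <- interp_monthly(site$monthly_tmax_mean, doy) + e + u_max
  tmin <- interp_monthly(site$monthly_tmin_mean, doy) + e + u_min
  tmin <- pmin(tmin, tmax - 0.2)
  rain <- ifelse(wet, depth, 0)
  radn <- (16 + site$rad_clear_sky_amp * cos(2 * pi * (doy - 172) / 365)) *
    ifelse(wet, 0.75, 1)

  tibble::tibble(
    date = as.Date(paste0(year, "-01-01")) + (doy - 1L),
    year = year, doy = doy,
    tmax = tmax, tmin = tmin, rain = rain, radn = radn)
}

#' Read or write weather as CSV
#'
#' The on-disk form is a plain comma-separated file with header
#' `date,tmax,tmin,rain,radn` (ISO dates, degrees C, mm, MJ m-2 d-1) — the
#' same column semantics as an APSIM-style met file in comma dialect.
#'
#' @param weather A weather tibble as produced by [gen_weather()].
#' @param path File path.
#' @return `read_weather_csv` returns a weather tibble with `year` and `doy`
#'   recomputed from `date`.
#' @export
write_weather_csv <- function(weather, path) {
  readr::write_csv(weather[, c("date", "tmax", "tmin", "rain", "radn")], path)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("date", "tmax", "tmin", "rain", "radn") %in% names(w)))
  w$date <- as.Date(w$date)
  w$year <- as.integer(format(w$date, "%Y"))
  w$doy <- as.integer(format(w$date, "%j"))
  tibble::as_tibble(w[, c("date", "year", "doy", "tmax", "tmin", "rain", "radn")])
}
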