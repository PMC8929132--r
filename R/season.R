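#' Heat-stress seed-set factor (GT)
#'
#' Seed set is sensitive in the thermal-time window from 50 degree-days
#' before anthesis to 100 degree-days after. The stressed fraction `f` is the
#' share of the window — weighted by daily thermal time — that falls on days
#' whose maximum temperature exceeds the threshold (32 C by default); the
#' factor returned is `1 - f`, so 1 means no heat stress and 0 a fully
#' stressed window.
#'
#' @param daily_tmax Daily maximum temperature series from emergence
#'   (degrees C).
#' @param daily_tt Daily thermal-time series aligned with `daily_tmax`
#'   (degree-days).
#' @param cv A [cultivar_params()] providing `tt_anthesis`, the threshold and
#'   the window extents.
#' @param weighting `"tt"` weights each window day by its thermal time (the
#'   default); `"days"` counts days equally.
#' @return Seed-set factor in `[0, 1]`.
#' @export
gt_seed_set_factor <- function(daily_tmax, daily_tt, cv,
                               weighting = c("tt", "days")) {
  weighting <- match.arg(weighting)
  stopifnot(length(daily_tmax) == length(daily_tt))
  cum_tt <- cumsum(daily_tt)
  if (max(cum_tt) < cv$tt_anthesis + cv$heat_window_after)
    stop("season too short: thermal time never reaches the end of the seed-set window")
  in_window <- cum_tt >= cv$tt_anthesis - cv$heat_window_before &
    cum_tt <= cv$tt_anthesis + cv$heat_window_after
  if (!any(in_window)) stop("seed-set window is empty")
  w <- if (weighting == "tt") daily_tt[in_window] else
    rep(1, sum(in_window))
  if (sum(w) <= 0) stop("seed-set window carries no thermal time")
  hot <- daily_tmax[in_window] > cv$heat_threshold
  1 - sum(w[hot]) / sum(w)
}

#' Simulate one sorghum season
#'
#' Runs the daily model from sowing to physiological maturity: thermal-time
#' phenology, logistic canopy, layered soil water bucket, the relative
#' transpiration index RT (supply/demand capped at 1) limiting daily biomass
#' gain, and the heat seed-set factor GT. Yield is the smaller of the
#' sink (grain number from the crop growth rate around flowering, times
#' potential grain weight) and the source (`harvest_frac` of post-anthesis
#' biomass gain), multiplied by the GT factor.
#'
#' @param weather Weather tibble from [gen_weather()] (or
#'   [read_weather_csv()]) covering sowing through maturity.
#' @param profile A [soil_profile()].
#' @param cv A [cultivar_params()].
#' @param sowing_date A `Date` (or string) present in `weather`.
#' @param density Plant density (plants m-2).
#' @param init_fraction Fraction of plant-available water present at sowing
#'   (default 0.5, half of the holding capacity).
#' @param no3_init Accepted for config compatibility; nitrogen is not
#'   simulated and the value is ignored.
#' @param max_days Maximum season length in days (default 210); a crop that
#'   has not reached maturity by then — e.g. thermal time stalling into
#'   winter — fails as an incomplete season rather than dragging across it.
#' @return A list of class `season_result`: phenology dates
#'   (`emergence_day`, `anthesis_day`, `maturity_day`), a `daily` tibble from
#'   emergence to maturity (`date, tt, cum_tt, rt, gt, supply, demand,
#'   biomass`), `yield` (kg ha-1), `gt_factor`, `grain_number` (m-2) and
#'   `biomass` (g m-2).
#' @export
simulate_season <- function(weather, profile, cv, sowing_date, density,
                            init_fraction = 0.5, no3_init = NULL,
                            max_days = 210) {
  if (density <= 0) stop("density must be positive")
  sowing_date <- as.Date(sowing_date)
  i_sow <- match(sowing_date, weather$date)
  if (is.na(i_sow)) stop("sowing_date not found in weather series")
  n_days <- nrow(weather)
  soil_water <- init_soil_water(profile, init_fraction)
  max_depth <- min(profile$max_root_depth, profile$depth)

  tt_sow <- 0          # thermal time since sowing (pre-emergence clock)
  cum_tt <- 0          # thermal time since emergence
  emerged <- FALSE
  biomass <- 0
  i_emerge <- i_anth <- i_mat <- NA_integer_
  rec <- list()
  window_gain <- c()   # daily biomass gains inside the flowering window
  post_anth_gain <- 0

  i_last <- min(n_days, i_sow + max_days - 1L)
  for (i in i_sow:i_last) {
    tt <- daily_thermal_time(weather$tmin[i], weather$tmax[i], cv)
    if (!emerged) {
      tt_sow <- tt_sow + tt
      # bare-soil water balance before emergence
      sb <- step_water_balance(soil_water, weather$rain[i], profile$u_evap,
                               0, profile, 0)
      soil_water <- sb$soil_water
      if (tt_sow >= cv$tt_emerge) {
        emerged <- TRUE
        i_emerge <- i
      }
      next
    }
    cum_tt <- cum_tt + tt
    root_depth <- min(max_depth, profile$root_front_velocity * cum_tt)
    lai <- leaf_area_index(cum_tt, density, cv)
    cover <- 1 - exp(-0.55 * lai)
    demand <- water_demand(weather$radn[i], lai, weather$tmax[i],
                           weather$tmin[i], cv)
    # infiltration and soil evaporation first, then uptake from what remains,
    # so the transpiration cap is consistent with the water actually present
    sb1 <- step_water_balance(soil_water, weather$rain[i],
                              profile$u_evap * (1 - cover), 0, profile,
                              root_depth)
    supply <- water_supply(sb1$soil_water, profile, root_depth)
    rt <- rt_index(supply, demand)
    transp <- min(supply, demand)
    sb <- step_water_balance(sb1$soil_water, 0, 0, transp, profile,
                             root_depth)
    soil_water <- sb$soil_water
    gain <- cv$rue * weather$radn[i] * cover * rt
    biomass <- biomass + gain

    in_window <- cum_tt >= cv$tt_anthesis - cv$heat_window_before &
      cum_tt <= cv$tt_anthesis + cv$heat_window_after
    if (in_window) window_gain <- c(window_gain, gain)
    if (is.na(i_anth) && cum_tt >= cv$tt_anthesis) i_anth <- i
    if (!is.na(i_anth)) post_anth_gain <- post_anth_gain + gain
    gt_daily <- if (in_window && weather$tmax[i] > cv$heat_threshold) 0 else 1

    rec[[length(rec) + 1]] <- c(i = i, tt = tt, cum_tt = cum_tt, rt = rt,
                                gt = gt_daily, supply = supply,
                                demand = demand, biomass = biomass)
    if (cum_tt >= cv$tt_maturity) {
      i_mat <- i
      break
    }
  }
  if (is.na(i_mat))
    stop("season incomplete: weather series ends before maturity thermal time accumulates")

  d <- tibble::as_tibble(as.data.frame(do.call(rbind, rec)))
  d$date <- weather$date[d$i]
  d <- d[, c("date", "tt", "cum_tt", "rt", "gt", "supply", "demand", "biomass")]

  # recorded days run from the day after emergence through maturity
  gt_factor <- gt_seed_set_factor(weather$tmax[(i_emerge + 1):i_mat], d$tt, cv)
  grain_number <- cv$grain_no_coeff * mean(window_gain)
  sink_g <- grain_number * cv$grain_wt_max / 1000          # mg -> g
  source_g <- cv$harvest_frac * post_anth_gain
  yield <- min(sink_g, source_g) * gt_factor * 10          # g m-2 -> kg ha-1

  structure(list(
    emergence_day = weather$date[i_emerge],
    anthesis_day = weather$date[i_anth],
    maturity_day = weather$date[i_mat],
    daily = d, yield = yield, gt_factor = gt_factor,
    grain_number = grain_number, biomass = biomass,
    cultivar = cv$name, density = density), class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat("sorghum season:", x$cultivar, "at", format(x$density), "plants m-2\n")
  cat("  emergence ", format(x$emergence_day), " anthesis ",
      format(x$anthesis_day), " maturity ", format(x$maturity_day), "\n")
  cat(sprintf("  yield %.0f kg/ha, GT factor %.3f, mean RT %.3f\n",
              x$yield, x$gt_factor, mean(x$daily$rt)))
  invisible(x)
}
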