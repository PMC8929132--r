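#' Daily thermal time from a broken-stick temperature response
#'
#' Development is driven by daily mean temperature `(tmin + tmax) / 2` with a
#' piecewise-linear response: zero at or below `t_base`, rising linearly to
#' `t_opt - t_base` at `t_opt`, falling linearly back to zero at `t_max`.
#'
#' @param tmin,tmax Daily minimum and maximum temperature (degrees C);
#'   vectorized, `tmin <= tmax` required.
#' @param cv A [cultivar_params()].
#' @return Thermal time (degree-days), in `[0, t_opt - t_base]`.
#' @export
daily_thermal_time <- function(tmin, tmax, cv) {
  if (any(tmin > tmax)) stop("tmin must not exceed tmax")
  tmean <- (tmin + tmax) / 2
  up <- pmax(0, pmin(tmean - cv$t_base, cv$t_opt - cv$t_base))
  down_frac <- pmax(0, pmin(1, (cv$t_max - tmean) / (cv$t_max - cv$t_opt)))
  ifelse(tmean <= cv$t_opt, up, (cv$t_opt - cv$t_base) * down_frac)
}

#' Canopy leaf area index as a logistic in thermal time
#'
#' @param cum_tt Cumulative thermal time from emergence (degree-days).
#' @param density Plant density (plants m-2); LAI scales linearly with
#'   `density / ref_density`.
#' @param cv A [cultivar_params()].
#' @return LAI (m2 m-2). No senescence is modelled: past maturity the
#'   logistic plateau is returned.
#' @export
leaf_area_index <- function(cum_tt, density, cv) {
  if (any(density <= 0)) stop("density must be positive")
  if (any(cum_tt < 0)) stop("cum_tt must be >= 0")
  cv$lai_max * (density / cv$ref_density) /
    (1 + exp(-cv$lai_slope * (cum_tt - cv$lai_midpoint)))
}

#' Saturation vapour pressure (kPa) at temperature t (degrees C)
#' @noRd
svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

#' Canopy transpiration demand
#'
#' Demand is the water needed to realize the radiation-limited growth at the
#' day's atmospheric dryness:
#' `demand = rue * radn * (1 - exp(-0.55 * LAI)) * vpd / te_coeff`, with
#' daytime vapour-pressure deficit `vpd = 0.75 * (svp(tmax) - svp(tmin))`.
#'
#' @param radn Incident solar radiation (MJ m-2 d-1), non-negative.
#' @param lai Leaf area index (m2 m-2).
#' @param tmax,tmin Daily temperature extremes (degrees C).
#' @param cv A [cultivar_params()].
#' @return Demand (mm d-1), zero for a bare or VPD-free day.
#' @export
water_demand <- function(radn, lai, tmax, tmin, cv) {
  if (any(radn < 0)) stop("radiation must be >= 0")
  vpd <- pmax(0, 0.75 * (svp(tmax) - svp(tmin)))
  gain <- cv$rue * radn * (1 - exp(-0.55 * lai))
  gain * vpd / cv$te_coeff
}
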