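#' Potential root water supply
#'
#' Supply is the water the root system can extract today:
#' `sum over rooted layers of kl * (water - ll * thickness)`, with a layer
#' only partially explored by the root front contributing in proportion to
#' its rooted fraction.
#'
#' @param soil_water Per-layer water content (mm), one value per profile
#'   layer.
#' @param profile A [soil_profile()].
#' @param root_depth Current rooting depth (mm), `>= 0`.
#' @return Supply (mm d-1), non-negative and non-decreasing in `root_depth`.
#' @export
water_supply <- function(soil_water, profile, root_depth) {
  if (root_depth < 0) stop("root_depth must be >= 0")
  ly <- profile$layers
  stopifnot(length(soil_water) == nrow(ly))
  top <- cumsum(c(0, ly$thickness))[seq_len(nrow(ly))]
  rooted_frac <- pmin(1, pmax(0, (root_depth - top) / ly$thickness))
  extractable <- pmax(0, soil_water - ly$ll * ly$thickness)
  sum(ly$kl * extractable * rooted_frac)
}

#' Relative transpiration (RT) stress index
#'
#' The daily water supply to demand ratio capped at 1; 1 denotes no stress,
#' 0 complete stress. When demand is zero the crop is unstressed by
#' convention.
#'
#' @param supply,demand Non-negative fluxes (mm d-1); vectorized.
#' @return Index in `[0, 1]`.
#' @export
rt_index <- function(supply, demand) {
  if (any(supply < 0) || any(demand < 0)) stop("supply and demand must be >= 0")
  ifelse(demand == 0, 1, pmin(1, supply / demand))
}

#' Advance the layered soil water bucket one day
#'
#' The order of operations is: rain infiltrates the top layer and cascades
#' downward, each layer filling to its drained upper limit, with surplus
#' below the bottom layer leaving as drainage; transpiration is then removed
#' from rooted layers in proportion to each layer's contribution to the
#' extractable supply (the crop drinks before the soil surface dries);
#' finally soil evaporation is taken from the top layer, capped by the water
#' remaining above that layer's lower limit. The caller must cap
#' transpiration at the supply (see [rt_index()]); requesting more is an
#' error. Because infiltration precedes uptake, a cap computed on the
#' pre-step state is always honoured.
#'
#' @param soil_water Per-layer water content (mm).
#' @param rain Rainfall (mm), `>= 0`.
#' @param soil_evap_demand Potential soil evaporation (mm), `>= 0`.
#' @param transpiration Crop water uptake (mm), `>= 0`, at most the supply at
#'   `root_depth`.
#' @param profile A [soil_profile()].
#' @param root_depth Rooting depth (mm) used to distribute uptake.
#' @return A list with `soil_water` (updated contents), `drainage`, `evap`
#'   (actual soil evaporation), `transpiration` and `closure` — the mass
#'   balance residual `delta_storage - (rain - drainage - evap -
#'   transpiration)`, which is zero to machine precision.
#' @export
step_water_balance <- function(soil_water, rain, soil_evap_demand,
                               transpiration, profile, root_depth) {
  if (rain < 0 || soil_evap_demand < 0 || transpiration < 0)
    stop("all fluxes must be >= 0")
  ly <- profile$layers
  stopifnot(length(soil_water) == nrow(ly))
  w0 <- soil_water
  cap <- ly$dul * ly$thickness
  floor_w <- ly$ll * ly$thickness

  # infiltration cascade, top down
  inflow <- rain
  for (i in seq_len(nrow(ly))) {
    room <- cap[i] - soil_water[i]
    take <- min(inflow, max(0, room))
    soil_water[i] <- soil_water[i] + take
    inflow <- inflow - take
  }
  drainage <- inflow

  # root uptake, proportional to each layer's share of extractable supply
  if (transpiration > 0) {
    top <- cumsum(c(0, ly$thickness))[seq_len(nrow(ly))]
    rooted_frac <- pmin(pmax((root_depth - top) / ly$thickness, 0), 1)
    avail <- ly$kl * pmax(0, soil_water - floor_w) * rooted_frac
    total <- sum(avail)
    if (transpiration > total + 1e-9)
      stop("transpiration exceeds extractable supply; cap it with rt_index")
    if (total > 0)
      soil_water <- soil_water - min(transpiration, total) * avail / total
  }

  # stage-one soil evaporation from the top layer, from what remains
  evap <- min(soil_evap_demand, max(0, soil_water[1] - floor_w[1]))
  soil_water[1] <- soil_water[1] - evap

  closure <- sum(soil_water - w0) - (rain - drainage - evap - transpiration)
  list(soil_water = soil_water, drainage = drainage, evap = evap,
       transpiration = transpiration, closure = closure)
}
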