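#' Cultivar parameter set for the daily sorghum model
#'
#' Groups the phenology, canopy, growth and seed-set parameters of one
#' hybrid. Thermal time is accumulated on daily mean temperature with a
#' broken-stick response between the cardinal temperatures; canopy size is a
#' logistic in thermal time scaled linearly by plant density; growth is the
#' minimum of a radiation-limited gain (radiation-use efficiency) and a
#' water-limited gain (transpiration efficiency); grain number is set by the
#' crop growth rate around flowering and trimmed by the heat seed-set factor.
#'
#' @param tt_emerge Thermal time sowing to emergence (degree-days).
#' @param tt_anthesis,tt_maturity Thermal time emergence to anthesis and to
#'   physiological maturity (degree-days); `tt_anthesis < tt_maturity`.
#' @param t_base,t_opt,t_max Cardinal temperatures (degrees C), increasing.
#'   Defaults 11/30/42 are conventional for grain sorghum.
#' @param lai_max Leaf area index plateau at the reference density
#'   (m2 m-2).
#' @param lai_midpoint Thermal time at which LAI reaches half of `lai_max`
#'   (degree-days).
#' @param lai_slope Logistic steepness (per degree-day).
#' @param ref_density Plant density at which `lai_max` applies (plants m-2);
#'   LAI scales linearly with `density / ref_density`.
#' @param rue Radiation-use efficiency (g biomass per MJ intercepted).
#' @param te_coeff Transpiration-efficiency coefficient
#'   (g m-2 kPa mm-1): biomass = transpiration * te_coeff / VPD.
#' @param grain_no_coeff Grains set per unit mean crop growth rate around
#'   flowering (grains per g m-2 d-1).
#' @param grain_wt_max Potential single-grain weight (mg).
#' @param harvest_frac Fraction of post-anthesis biomass gain available to
#'   fill grain (source limit on yield).
#' @param heat_threshold Daily maximum temperature above which a seed-set day
#'   counts as heat stressed (degrees C, default 32).
#' @param heat_window_before,heat_window_after Extent of the heat-sensitive
#'   seed-set window before and after anthesis (degree-days; defaults 50 and
#'   100).
#' @param name Cultivar label.
#' @return An object of class `cultivar_params`.
#' @export
cultivar_params <- function(tt_emerge = 60, tt_anthesis = 700,
                            tt_maturity = 1250,
                            t_base = 11, t_opt = 30, t_max = 42,
                            lai_max = 4, lai_midpoint = 400, lai_slope = 0.012,
                            ref_density = 28, rue = 1.25, te_coeff = 9,
                            grain_no_coeff = 1600, grain_wt_max = 25,
                            harvest_frac = 0.95,
                            heat_threshold = 32, heat_window_before = 50,
                            heat_window_after = 100, name = "hybrid") {
  if (!(t_base < t_opt && t_opt < t_max))
    stop("cardinal temperatures must satisfy t_base < t_opt < t_max")
  if (!(tt_emerge < tt_anthesis && tt_anthesis < tt_maturity))
    stop("thermal-time milestones must satisfy tt_emerge < tt_anthesis < tt_maturity")
  vals <- c(tt_emerge, tt_anthesis, tt_maturity, lai_max, lai_midpoint,
            lai_slope, ref_density, rue, te_coeff, grain_no_coeff,
            grain_wt_max, harvest_frac, heat_window_before, heat_window_after)
  if (any(vals <= 0)) stop("cultivar parameters must be positive")
  structure(as.list(environment()), class = "cultivar_params")
}

#' Bundled cultivar presets
#'
#' Two hybrids differing only in phenology (relative maturity about one unit
#' apart): `"hybrid_1"`, the reference cultivar used to classify trial
#' site-years, and the slightly later `"hybrid_2"`.
#'
#' @param which `"hybrid_1"` or `"hybrid_2"`.
#' @return A [cultivar_params()].
#' @export
cultivar_preset <- function(which = c("hybrid_1", "hybrid_2")) {
  which <- match.arg(which)
  switch(which,
    hybrid_1 = cultivar_params(tt_anthesis = 700, tt_maturity = 1250,
                               name = "hybrid_1"),
    hybrid_2 = cultivar_params(tt_anthesis = 730, tt_maturity = 1290,
                               name = "hybrid_2"))
}

#' Layered soil profile
#'
#' A cascading-bucket description of the root zone: for each layer its
#' thickness, volumetric lower limit (`ll`) and drained upper limit (`dul`),
#' and the daily extractable fraction `kl`. Plant-available water capacity is
#' `sum((dul - ll) * thickness)`.
#'
#' @param layers A data frame with columns `thickness` (mm), `ll` and `dul`
#'   (mm mm-1, `0 <= ll < dul <= 1`) and `kl` (d-1, in `(0, 1]`).
#' @param u_evap Stage-one soil evaporation limit (mm d-1) applied to the top
#'   layer.
#' @param root_front_velocity Root depth gain per degree-day (mm / degree-day).
#' @param max_root_depth Genetic maximum rooting depth (mm).
#' @param name Profile label.
#' @return An object of class `soil_profile` with `pawc` (mm) and `depth`
#'   (mm) attached.
#' @export
soil_profile <- function(layers, u_evap = 1.5, root_front_velocity = 1.2,
                         max_root_depth = 1800, name = "soil") {
  layers <- as.data.frame(layers)
  stopifnot(all(c("thickness", "ll", "dul", "kl") %in% names(layers)))
  if (any(layers$ll < 0 | layers$ll >= layers$dul | layers$dul > 1))
    stop("each layer needs 0 <= ll < dul <= 1")
  if (any(layers$kl <= 0 | layers$kl > 1)) stop("kl must lie in (0, 1]")
  if (any(layers$thickness <= 0)) stop("layer thickness must be positive")
  pawc <- sum((layers$dul - layers$ll) * layers$thickness)
  structure(list(layers = layers, u_evap = u_evap,
                 root_front_velocity = root_front_velocity,
                 max_root_depth = max_root_depth,
                 depth = sum(layers$thickness), pawc = pawc, name = name),
            class = "soil_profile")
}

#' Soil presets paired with the site climates
#'
#' `"deep_loam"` (about 180 mm plant-available water over 1.5 m) suits the
#' wetter east; `"shallow_loam"` (about 100 mm over 0.9 m) suits the drier
#' west where profiles are lighter and shallower.
#'
#' @param which `"deep_loam"` or `"shallow_loam"`.
#' @return A [soil_profile()].
#' @export
soil_preset <- function(which = c("deep_loam", "shallow_loam")) {
  which <- match.arg(which)
  switch(which,
    deep_loam = soil_profile(data.frame(
      thickness = c(150, 150, 300, 300, 300, 300),
      ll  = c(.14, .15, .16, .16, .17, .17),
      dul = c(.30, .30, .29, .28, .28, .27),
      kl  = c(.10, .10, .08, .06, .04, .03)), name = "deep_loam"),
    shallow_loam = soil_profile(data.frame(
      thickness = c(150, 150, 300, 300),
      ll  = c(.13, .14, .15, .16),
      dul = c(.27, .27, .26, .25),
      kl  = c(.10, .09, .07, .05)), name = "shallow_loam"))
}

#' Initialize per-layer soil water
#'
#' @param profile A [soil_profile()].
#' @param fraction_full Fraction of plant-available capacity present in every
#'   layer at sowing (default 0.5, i.e. half of the holding capacity).
#' @return Numeric vector of per-layer water contents (mm).
#' @export
init_soil_water <- function(profile, fraction_full = 0.5) {
  stopifnot(fraction_full >= 0, fraction_full <= 1)
  with(profile$layers, (ll + fraction_full * (dul - ll)) * thickness)
}
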