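#' Environment category group (ECG) labels
#'
#' The four yield-relevant environment categories obtained by crossing the
#' water and heat stress patterns: `NO_STRESS`, `HEAT`, `WATER`,
#' `HEAT_AND_WATER`.
#'
#' @return Character vector of the four levels, in canonical order.
#' @export
ecg_levels <- function() c("NO_STRESS", "HEAT", "WATER", "HEAT_AND_WATER")

#' Regroup water and heat stress patterns into the four ECG categories
#'
#' A season whose water pattern belongs to the non-stress set and whose heat
#' pattern belongs to the low-heat set is `NO_STRESS`; non-stress water with
#' stressful heat is `HEAT`; stressful water with low heat is `WATER`; and
#' both stressful is `HEAT_AND_WATER`. The default membership sets — the
#' single low-deficit water pattern (WSP 2 of 4) and the single low heat
#' pattern (HSP 1 of 3) — reproduce the regrouping used when four water and
#' three heat patterns are fitted; both sets are data-driven in general and
#' should be chosen from simulated-yield contrasts between clusters.
#'
#' @param wsp,hsp Integer cluster labels (vectorized, equal length).
#' @param nonstress_wsp Integer set of water patterns counted as non-stress.
#' @param low_hsp Integer set of heat patterns counted as low heat.
#' @param k_wsp,k_hsp Numbers of water and heat patterns, for label
#'   validation.
#' @return Factor with levels [ecg_levels()].
#' @export
regroup_ecg <- function(wsp, hsp, nonstress_wsp = 2L, low_hsp = 1L,
                        k_wsp = 4L, k_hsp = 3L) {
  stopifnot(length(wsp) == length(hsp))
  if (any(wsp < 1 | wsp > k_wsp)) stop("wsp label outside 1..k_wsp")
  if (any(hsp < 1 | hsp > k_hsp)) stop("hsp label outside 1..k_hsp")
  water_ok <- wsp %in% nonstress_wsp
  heat_ok <- hsp %in% low_hsp
  out <- ifelse(water_ok & heat_ok, "NO_STRESS",
         ifelse(water_ok, "HEAT",
         ifelse(heat_ok, "WATER", "HEAT_AND_WATER")))
  factor(out, levels = ecg_levels())
}

#' Pick data-driven ECG membership sets from per-cluster yields
#'
#' Chooses the non-stress water set and low-heat set as the clusters whose
#' mean simulated yield is within `frac` of the best cluster's mean — the
#' "significant impact on yield" rule expressed as a fixed contrast.
#'
#' @param yields Numeric vector of simulated yields.
#' @param wsp,hsp Cluster labels aligned with `yields`.
#' @param frac Yield fraction of the best cluster above which a cluster
#'   counts as unstressed (default 0.9).
#' @return List with integer sets `nonstress_wsp` and `low_hsp`.
#' @export
choose_ecg_sets <- function(yields, wsp, hsp, frac = 0.9) {
  pick <- function(labels) {
    m <- tapply(yields, labels, mean)
    as.integer(names(m)[m >= frac * max(m)])
  }
  list(nonstress_wsp = pick(wsp), low_hsp = pick(hsp))
}
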