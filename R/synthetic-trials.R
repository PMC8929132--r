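#' Canonical water-stress trajectory prototypes
#'
#' Four idealized seasonal relative-transpiration trajectories on the
#' 100 degree-day bin grid, named for the stress dynamics they portray:
#' `flowering_stress` (deficit around flowering with later recovery),
#' `low_stress` (index near 1 all season), `terminal_stress` (deficit rising
#' through grain filling with no recovery) and `terminal_recovery` (terminal
#' deficit relieved by late rain). They serve as ground truth for
#' cluster-recovery tests and as a readable reference for naming fitted
#' centroids.
#'
#' @param n_bins Number of 100 degree-day bins (default 14, a medium-maturity
#'   season of about 1400 degree-days).
#' @return A named list of four numeric vectors in `[0, 1]`.
#' @export
wsp_prototypes <- function(n_bins = 14) {
  stopifnot(n_bins >= 6)
  x <- seq_len(n_bins)
  mid <- n_bins * 0.55                      # flowering sits past mid-season
  flowering <- 1 - 0.75 * exp(-((x - mid) / (n_bins / 7))^2)
  low <- rep(0.97, n_bins)
  ramp <- pmin(1, pmax(0, (x - n_bins * 0.45) / (n_bins * 0.45)))
  terminal <- 1 - 0.85 * ramp
  recovery <- terminal
  tail_ix <- x > n_bins - 2
  recovery[tail_ix] <- recovery[tail_ix] + 0.55
  lapply(list(flowering_stress = flowering, low_stress = low,
              terminal_stress = terminal, terminal_recovery = recovery),
         function(v) pmin(1, pmax(0, v)))
}

#' Generate labelled noisy copies of trajectory prototypes
#'
#' Builds a trajectory matrix with known cluster structure: `n_per_cluster`
#' copies of each prototype plus i.i.d. Gaussian per-bin noise, clipped back
#' to `[0, 1]`. Used to test cluster discovery and classification.
#'
#' @param prototypes List of equal-length numeric vectors in `[0, 1]`.
#' @param n_per_cluster Copies per prototype.
#' @param noise_sd Per-bin Gaussian noise standard deviation (index units).
#' @param seed Integer seed.
#' @return A list with `x` (matrix, `length(prototypes) * n_per_cluster`
#'   rows), `truth` (integer prototype index per row) and `prototypes`.
#' @export
gen_stress_prototypes <- function(prototypes, n_per_cluster, noise_sd, seed) {
  if (length(prototypes) == 0) stop("prototype list must be non-empty")
  lens <- lengths(prototypes)
  if (length(unique(lens)) != 1) stop("all prototypes must have equal length")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  rng <- range(unlist(prototypes))
  if (rng[1] < 0 || rng[2] > 1) stop("prototype values must lie in [0, 1]")
  p <- length(prototypes)
  base <- do.call(rbind, prototypes[rep(seq_len(p), each = n_per_cluster)])
  noise <- withr::with_seed(seed,
    matrix(stats::rnorm(length(base), 0, noise_sd), nrow = nrow(base)))
  x <- pmin(pmax(base + noise, 0), 1)   # matrix first so dims survive
  rownames(x) <- NULL
  list(x = x, truth = rep(seq_len(p), each = n_per_cluster),
       prototypes = prototypes)
}

#' Variance structure for the synthetic trial-table generator
#'
#' @param sigma2_site Between-site yield variance ((kg/ha)^2).
#' @param sigma2_ecg_within_site Variance of the environment-category effect
#'   nested in site ((kg/ha)^2).
#' @param sigma2_hybrid Between-hybrid variance ((kg/ha)^2).
#' @param sigma2_resid Residual variance ((kg/ha)^2).
#' @param grand_mean Overall mean yield (kg/ha).
#' @return An object of class `trial_variance`.
#' @export
trial_variance <- function(sigma2_site, sigma2_ecg_within_site, sigma2_hybrid,
                           sigma2_resid, grand_mean = 6000) {
  v <- c(sigma2_site, sigma2_ecg_within_site, sigma2_hybrid, sigma2_resid)
  if (any(v < 0)) stop("variance components must be >= 0")
  structure(list(sigma2_site = sigma2_site,
                 sigma2_ecg_within_site = sigma2_ecg_within_site,
                 sigma2_hybrid = sigma2_hybrid,
                 sigma2_resid = sigma2_resid,
                 grand_mean = grand_mean),
            class = "trial_variance")
}

#' Simulate an unbalanced multi-site hybrid trial table
#'
#' Yields follow an additive random-effects model:
#' `yield = grand_mean + site + ECG(site) + hybrid + residual`, each effect
#' drawn from its variance in `tv`. Every site-year is assigned one of
#' `n_ecg` environment categories (balanced cycling within site, so the
#' nested effect is estimable), and the ECG effect is drawn once per
#' site-by-category cell. A `missing_frac` share of records is then deleted
#' at random, emulating the unbalance of public performance-test archives.
#'
#' @param n_sites,n_years Numbers of sites and of years per site.
#' @param hybrids Character vector of hybrid names.
#' @param tv A [trial_variance()].
#' @param missing_frac Fraction of records deleted, in `[0, 0.5]`.
#' @param seed Integer seed.
#' @param n_ecg Number of environment categories cycled across years.
#' @param ecg_labels Optional factor-like vector of length
#'   `n_sites * n_years` (site-major order) overriding the cycled category
#'   assignment, e.g. categories obtained from classifying simulated seasons.
#' @param site_names Optional site labels (length `n_sites`) replacing the
#'   default `S01, S02, ...`.
#' @param years Optional explicit year vector (length `n_years`).
#' @return A tibble `site, year, ecg, hybrid, yield_kg_ha` with the true
#'   effects attached as attributes `site_effects`, `ecg_effects`,
#'   `hybrid_effects` for recovery tests.
#' @export
gen_trial_table <- function(n_sites, n_years, hybrids, tv, missing_frac = 0,
                            seed = 1, n_ecg = 4, ecg_labels = NULL,
                            site_names = NULL, years = NULL) {
  stopifnot(inherits(tv, "trial_variance"))
  if (missing_frac < 0 || missing_frac > 0.5)
    stop("missing_frac must lie in [0, 0.5]")
  sites <- if (is.null(site_names)) sprintf("S%02d", seq_len(n_sites)) else {
    stopifnot(length(site_names) == n_sites)
    site_names
  }
  if (is.null(years)) years <- 2000L + seq_len(n_years)
  stopifnot(length(years) == n_years)
  grid <- tidyr::expand_grid(site = sites, year = years)
  if (is.null(ecg_labels)) {
    grid$ecg <- paste0("ECG", rep_len(seq_len(n_ecg), n_years))[
      match(grid$year, years)]
  } else {
    stopifnot(length(ecg_labels) == nrow(grid))
    grid$ecg <- as.character(ecg_labels)
  }
  full <- tidyr::expand_grid(grid, hybrid = hybrids)

  withr::with_seed(seed, {
    site_eff <- stats::setNames(
      stats::rnorm(n_sites, 0, sqrt(tv$sigma2_site)), sites)
    cells <- unique(full[, c("site", "ecg")])
    ecg_eff <- stats::setNames(
      stats::rnorm(nrow(cells), 0, sqrt(tv$sigma2_ecg_within_site)),
      paste(cells$site, cells$ecg, sep = ":"))
    hyb_eff <- stats::setNames(
      stats::rnorm(length(hybrids), 0, sqrt(tv$sigma2_hybrid)), hybrids)
    resid <- stats::rnorm(nrow(full), 0, sqrt(tv$sigma2_resid))
    keep <- stats::runif(nrow(full)) >= missing_frac
  })

  full$yield_kg_ha <- tv$grand_mean + site_eff[full$site] +
    ecg_eff[paste(full$site, full$ecg, sep = ":")] +
    hyb_eff[full$hybrid] + resid
  out <- full[keep, ]
  attr(out, "site_effects") <- site_eff
  attr(out, "ecg_effects") <- ecg_eff
  attr(out, "hybrid_effects") <- hyb_eff
  out
}
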