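#' Default pipeline configuration
#'
#' One document drives the whole characterization: sites (climate and soil
#' preset per site), the year range, the scenario grid (sowing dates,
#' management = density paired with a nominal N rate, cultivars), initial
#' conditions, the trajectory grid, and clustering settings. Defaults follow
#' regional sorghum practice: sowing May 15, June 1, June 15 and July 1;
#' high management 138 kg N/ha at 28 plants m-2 and low management
#' 69 kg N/ha at 14 plants m-2; initial soil water at half of holding
#' capacity. Nitrogen rates are carried as labels only — the simulator
#' represents the two managements through their densities.
#'
#' @param n_years Years of weather per site (default 20).
#' @return A nested list; any element can be overridden before running, or
#'   via a YAML file with [read_config()].
#' @export
default_config <- function(n_years = 20) {
  list(
    sites = list(
      list(name = "dry_west", climate = "dry_west", soil = "shallow_loam"),
      list(name = "intermediate", climate = "intermediate", soil = "deep_loam"),
      list(name = "wet_east", climate = "wet_east", soil = "deep_loam")),
    start_year = 1991, n_years = n_years,
    sowing_dates = c("05-15", "06-01", "06-15", "07-01"),
    managements = list(
      list(name = "high", density = 28, n_rate = 138),
      list(name = "low", density = 14, n_rate = 69)),
    cultivars = c("hybrid_1", "hybrid_2"),
    init_fraction = 0.5, no3_init = 50,
    n_bins = 12,
    clustering = list(k_range = 2:6, k_wsp = NULL, k_hsp = NULL, n_init = 25),
    reference_cultivar = "hybrid_1",
    trial_sowing = "06-01", trial_management = "high",
    ecg_yield_frac = 0.9)
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [default_config()];
#' everything else keeps its default.
#'
#' @param path YAML file path.
#' @return Config list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  if (!is.null(user$clustering))
    for (nm in setdiff(names(default_config()$clustering),
                       names(user$clustering)))
      cfg$clustering[[nm]] <- default_config()$clustering[[nm]]
  cfg
}

#' Build the scenario grid from a configuration
#'
#' @param config Config list.
#' @return Tibble with one row per site x year x sowing date x management x
#'   cultivar combination.
#' @export
scenario_grid <- function(config) {
  years <- config$start_year + seq_len(config$n_years) - 1L
  g <- tidyr::expand_grid(
    site = vapply(config$sites, `[[`, character(1), "name"),
    year = years,
    sowing = config$sowing_dates,
    mgmt = vapply(config$managements, `[[`, character(1), "name"),
    cultivar = config$cultivars)
  if (nrow(g) == 0) stop("scenario grid is empty")
  g
}

site_weather <- function(config, seed) {
  ws <- lapply(seq_along(config$sites), function(i) {
    s <- config$sites[[i]]
    clim <- if (inherits(s$climate, "site_climate")) s$climate else
      site_preset(s$climate)
    gen_weather(clim, config$start_year, config$n_years,
                seed = (seed + 101L * i) %% .Machine$integer.max)
  })
  names(ws) <- vapply(config$sites, `[[`, character(1), "name")
  ws
}

site_soils <- function(config) {
  so <- lapply(config$sites, function(s)
    if (inherits(s$soil, "soil_profile")) s$soil else soil_preset(s$soil))
  names(so) <- vapply(config$sites, `[[`, character(1), "name")
  so
}

# Relabel clusters 1..k by descending membership so reports are stable
# across seeds; centroid/label/size fields are permuted consistently.
relabel_by_frequency <- function(model) {
  ord <- order(model$sizes, decreasing = TRUE)
  new_of_old <- match(seq_len(model$k), ord)
  model$labels <- new_of_old[model$labels]
  model$centroids <- model$centroids[ord, , drop = FALSE]
  model$sizes <- model$sizes[ord]
  model
}

#' Characterize the target population of environments
#'
#' The end-to-end discovery stage: generate (or accept) weather for every
#' site, simulate every scenario-grid season, bin the daily RT and GT series
#' on the 100 degree-day grid, cluster the two trajectory matrices
#' independently into water (WSP) and heat (HSP) stress patterns, and report
#' per-site pattern frequencies and per-cluster simulated yields. Seasons
#' that fail (weather runs out before maturity) are excluded and counted,
#' never silently dropped. Cluster ids are assigned by descending frequency.
#'
#' @param config Configuration list (see [default_config()]).
#' @param seed Integer seed controlling weather generation and clustering.
#' @param outdir Optional directory; when given, all artifacts (trajectory
#'   matrices, cluster models, frequency tables, yield summaries, manifest)
#'   are written there as plain CSV/JSON.
#' @param weather Optional named list of weather tibbles per site,
#'   overriding generation (e.g. from [read_weather_csv()]).
#' @return A list of class `characterization`: `meta` (per-season labels and
#'   yields), `wsp`/`hsp` (`cluster_model`s), `wsp_select`/`hsp_select`
#'   (index votes when k was chosen by vote), `wsp_freq`/`hsp_freq`,
#'   `yield_by_wsp`/`yield_by_hsp`, `n_failed`, `n_bins`, `config`, `seed`.
#' @export
run_characterization <- function(config = default_config(), seed = 1,
                                 outdir = NULL, weather = NULL) {
  grid <- scenario_grid(config)
  if (is.null(weather)) weather <- site_weather(config, seed)
  soils <- site_soils(config)
  cvs <- lapply(stats::setNames(nm = config$cultivars), cultivar_preset)
  dens <- stats::setNames(
    vapply(config$managements, `[[`, numeric(1), "density"),
    vapply(config$managements, `[[`, character(1), "name"))

  seasons <- vector("list", nrow(grid))
  ok <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- tryCatch(
      simulate_season(weather[[g$site]], soils[[g$site]], cvs[[g$cultivar]],
                      paste0(g$year, "-", g$sowing), dens[[g$mgmt]],
                      config$init_fraction, config$no3_init),
      error = function(e) NULL)
    if (!is.null(res)) {
      seasons[[i]] <- res
      ok[i] <- TRUE
    }
  }
  n_failed <- sum(!ok)
  if (n_failed > 0)
    message(n_failed, " of ", nrow(grid),
            " seasons failed to reach maturity and were excluded")
  meta <- grid[ok, ]
  seasons <- seasons[ok]
  meta$yield <- vapply(seasons, `[[`, numeric(1), "yield")
  meta$gt_factor <- vapply(seasons, `[[`, numeric(1), "gt_factor")

  rt_mat <- build_trajectory_matrix(seasons, "rt", config$n_bins, meta)
  gt_mat <- build_trajectory_matrix(seasons, "gt", config$n_bins, meta)

  fit_or_select <- function(tm, k_fixed) {
    if (!is.null(k_fixed))
      return(list(model = fit_kmeans(tm, k_fixed, seed,
                                     config$clustering$n_init),
                  select = NULL))
    sel <- select_k(tm, config$clustering$k_range, seed,
                    config$clustering$n_init)
    list(model = sel$models[[as.character(sel$k)]], select = sel)
  }
  w <- fit_or_select(rt_mat, config$clustering$k_wsp)
  h <- fit_or_select(gt_mat, config$clustering$k_hsp)
  wsp <- relabel_by_frequency(w$model)
  hsp <- relabel_by_frequency(h$model)

  out <- structure(list(
    meta = meta, rt_matrix = rt_mat, gt_matrix = gt_mat,
    wsp = wsp, hsp = hsp,
    wsp_select = w$select, hsp_select = h$select,
    wsp_freq = cluster_frequencies(wsp, meta, "site"),
    hsp_freq = cluster_frequencies(hsp, meta, "site"),
    yield_by_wsp = yield_by_cluster(meta$yield, wsp$labels, "WSP"),
    yield_by_hsp = yield_by_cluster(meta$yield, hsp$labels, "HSP"),
    n_failed = n_failed, n_bins = config$n_bins,
    config = config, seed = seed), class = "characterization")
  if (!is.null(outdir)) write_characterization(out, outdir)
  out
}

yield_by_cluster <- function(yields, labels, prefix) {
  tibble::tibble(cluster = paste0(prefix, sort(unique(labels))),
                 n = as.integer(table(labels)),
                 mean_yield = as.numeric(tapply(yields, labels, mean)),
                 sd_yield = as.numeric(tapply(yields, labels, stats::sd)))
}

#' Classify trial site-years and analyse observed yields by ECG
#'
#' The testing stage: simulate the reference cultivar once per trial
#' site-year (at the trial management), classify its RT and GT trajectories
#' into the trained WSP/HSP by minimum sum of squared differences, regroup
#' into the four ECG categories, then (i) estimate the random-effect
#' variance components of observed yield with site and ECG-nested-in-site,
#' and (ii) complete the hybrid x site-year yield matrix by rank-2 SVD
#' imputation and draw the hybrid x ECG biplot. Site-years without weather
#' coverage are excluded with a message. The ECG membership sets are chosen
#' from the characterization's per-cluster simulated yields (clusters within
#' `ecg_yield_frac` of the best cluster count as unstressed).
#'
#' @param config Configuration list.
#' @param trial_table Tibble `site, year, hybrid, yield_kg_ha`; sites must
#'   be config sites and years lie inside the weather span.
#' @param char A `characterization` from [run_characterization()].
#' @param seed Integer seed (weather regeneration only; classification is
#'   deterministic).
#' @param outdir Optional output directory.
#' @param weather Optional named list of site weather (defaults to
#'   regenerating the characterization weather from `seed`).
#' @return A list of class `ecg_analysis`: `trials` (trial table augmented
#'   with `wsp`, `hsp`, `ecg`), `site_year` (one row per classified
#'   site-year), `varcomp`, `biplot`, `imputed` (completed hybrid x
#'   site-year matrix), `ecg_sets`, `n_excluded`. An empty trial table
#'   returns empty components without error.
#' @export
run_testing <- function(config, trial_table, char, seed = 1, outdir = NULL,
                        weather = NULL) {
  stopifnot(inherits(char, "characterization"))
  trial_table <- tibble::as_tibble(trial_table)
  if (nrow(trial_table) == 0) {
    out <- structure(list(trials = trial_table, site_year = tibble::tibble(),
                          varcomp = NULL, biplot = NULL, imputed = NULL,
                          ecg_sets = NULL, n_excluded = 0L),
                     class = "ecg_analysis")
    return(out)
  }
  stopifnot(all(c("site", "year", "hybrid", "yield_kg_ha") %in%
                  names(trial_table)))
  if (is.null(weather)) weather <- site_weather(config, seed)
  soils <- site_soils(config)
  cv <- cultivar_preset(config$reference_cultivar)
  dens <- vapply(config$managements, `[[`, numeric(1), "density")[
    match(config$trial_management,
          vapply(config$managements, `[[`, character(1), "name"))]

  sy <- unique(trial_table[, c("site", "year")])
  sy <- sy[order(sy$site, sy$year), ]
  keep <- logical(nrow(sy))
  wsp_lab <- hsp_lab <- integer(nrow(sy))
  for (i in seq_len(nrow(sy))) {
    w <- weather[[sy$site[i]]]
    if (is.null(w)) next
    s <- tryCatch(
      simulate_season(w, soils[[sy$site[i]]], cv,
                      paste0(sy$year[i], "-", config$trial_sowing), dens,
                      config$init_fraction),
      error = function(e) NULL)
    if (is.null(s)) next
    keep[i] <- TRUE
    rt <- bin_trajectory(s$daily$rt, s$daily$tt, 100, char$n_bins)
    gt <- bin_trajectory(s$daily$gt, s$daily$tt, 100, char$n_bins)
    wsp_lab[i] <- classify_trajectory(rt, char$wsp)
    hsp_lab[i] <- classify_trajectory(gt, char$hsp)
  }
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(n_excluded, " site-years lacked weather or a complete season ",
            "and were excluded")
  sy <- sy[keep, ]
  sy$wsp <- wsp_lab[keep]
  sy$hsp <- hsp_lab[keep]
  sets <- choose_ecg_sets(char$meta$yield, char$wsp$labels, char$hsp$labels,
                          config$ecg_yield_frac)
  sy$ecg <- regroup_ecg(sy$wsp, sy$hsp, sets$nonstress_wsp, sets$low_hsp,
                        k_wsp = char$wsp$k, k_hsp = char$hsp$k)

  trials <- dplyr::inner_join(trial_table, sy, by = c("site", "year"))
  varcomp <- variance_components(trials)

  # hybrid x site-year matrix, gaps filled at rank 2, then ECG means
  trials$env <- paste(trials$site, trials$year, sep = "_")
  wide <- trials |>
    dplyr::group_by(.data$hybrid, .data$env) |>
    dplyr::summarise(y = mean(.data$yield_kg_ha), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "env", values_from = "y")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$hybrid
  # kg/ha scale: a 2 kg/ha fill-in tolerance is far below agronomic noise
  imputed <- impute_gaps(m, rank = 2, tol = 2, max_iter = 20000)
  env_ecg <- sy$ecg[match(colnames(m), paste(sy$site, sy$year, sep = "_"))]
  by_ecg <- vapply(split(seq_len(ncol(imputed)), env_ecg, drop = TRUE),
                   function(ix) rowMeans(imputed[, ix, drop = FALSE]),
                   numeric(nrow(imputed)))
  biplot <- if (nrow(imputed) >= 3 && ncol(by_ecg) >= 2)
    ecg_biplot(by_ecg) else NULL

  out <- structure(list(trials = trials[, setdiff(names(trials), "env")],
                        site_year = sy, varcomp = varcomp, biplot = biplot,
                        imputed = imputed, hybrid_by_ecg = by_ecg,
                        ecg_sets = sets, n_excluded = n_excluded),
                   class = "ecg_analysis")
  if (!is.null(outdir)) write_ecg_analysis(out, outdir)
  out
}

#' Run the whole study at desk scale
#'
#' A self-contained demonstration: characterize the TPE on the three site
#' presets, build a synthetic six-hybrid trial table whose environment
#' effects are wired to the ECG classification of its site-years (so the
#' categories genuinely drive yield), and run the testing stage on it.
#' With `outdir` set, every artifact is written deterministically (fixed
#' seed, sorted rows), so re-running with the same config and seed
#' reproduces the files byte for byte (the manifest, which carries
#' timestamps, is the one exception).
#'
#' @param outdir Optional output directory.
#' @param seed Integer seed for the full run.
#' @param config Configuration; default is [default_config()] trimmed to
#'   `n_years = 8` so the demo stays fast.
#' @return List with `characterization`, `trials`, `analysis`.
#' @export
run_demo <- function(outdir = NULL, seed = 1, config = NULL) {
  if (is.null(config)) {
    config <- default_config(n_years = 8)
    config$cultivars <- "hybrid_1"
    config$clustering$k_wsp <- 4
    config$clustering$k_hsp <- 3
  }
  char <- run_characterization(config, seed,
                               outdir = if (is.null(outdir)) NULL else
                                 file.path(outdir, "characterization"))

  # classified reference scenario labels per site-year drive the trial ECG
  ref <- char$meta$sowing == config$trial_sowing &
    char$meta$mgmt == config$trial_management &
    char$meta$cultivar == config$reference_cultivar
  sets <- choose_ecg_sets(char$meta$yield, char$wsp$labels, char$hsp$labels,
                          config$ecg_yield_frac)
  ref_ecg <- regroup_ecg(char$wsp$labels[ref], char$hsp$labels[ref],
                         sets$nonstress_wsp, sets$low_hsp,
                         k_wsp = char$wsp$k, k_hsp = char$hsp$k)
  ref_meta <- char$meta[ref, ]
  site_names <- vapply(config$sites, `[[`, character(1), "name")
  years <- config$start_year + seq_len(config$n_years) - 1L
  grid_sy <- tidyr::expand_grid(site = site_names, year = years)
  ecg_labels <- as.character(ref_ecg)[
    match(paste(grid_sy$site, grid_sy$year),
          paste(ref_meta$site, ref_meta$year))]
  ecg_labels[is.na(ecg_labels)] <- "NO_STRESS"  # unclassifiable site-years

  tv <- trial_variance(sigma2_site = 4e5, sigma2_ecg_within_site = 6e5,
                       sigma2_hybrid = 1e5, sigma2_resid = 2e5)
  hybrids <- c("84G62", "hybrid_2", "85G01", "85G03", "85G46", "hybrid_1")
  trials <- gen_trial_table(length(site_names), config$n_years, hybrids, tv,
                            missing_frac = 0.2, seed = seed + 17L,
                            ecg_labels = ecg_labels,
                            site_names = site_names, years = years)
  trials <- trials[, c("site", "year", "hybrid", "yield_kg_ha")]
  analysis <- run_testing(config, trials, char, seed,
                          outdir = if (is.null(outdir)) NULL else
                            file.path(outdir, "testing"))
  list(characterization = char, trials = trials, analysis = analysis)
}
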