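#' Persist and reload a fitted cluster model
#'
#' Stored as JSON (k, centroids, sizes, inertia, variance explained, seed)
#' so classification of new seasons is reproducible across runs.
#'
#' @param model A `cluster_model`.
#' @param path JSON file path.
#' @return `read_cluster_model` returns the restored `cluster_model`
#'   (without training labels).
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  jsonlite::write_json(
    list(k = model$k, centroids = model$centroids, sizes = model$sizes,
         inertia = model$inertia,
         variance_explained = model$variance_explained, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = j$k, centroids = as.matrix(j$centroids),
                 labels = NULL, inertia = j$inertia,
                 variance_explained = j$variance_explained,
                 sizes = j$sizes, seed = j$seed), class = "cluster_model")
}

trajectory_csv <- function(tm, path) {
  df <- cbind(as.data.frame(tm$meta), as.data.frame(tm$x))
  readr::write_csv(df, path)
  invisible(path)
}

manifest <- function(outdir, config, seed, files) {
  list(config_hash = rlang::hash(config), seed = seed,
       written_at = format(Sys.time(), tz = "UTC"),
       package_version = as.character(utils::packageVersion("sorghumTPE")),
       files = files)
}

write_characterization <- function(char, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    rt_trajectories = "rt_trajectories.csv",
    gt_trajectories = "gt_trajectories.csv",
    wsp_model = "wsp_model.json", hsp_model = "hsp_model.json",
    wsp_frequencies = "wsp_frequencies.csv",
    hsp_frequencies = "hsp_frequencies.csv",
    yield_by_wsp = "yield_by_wsp.csv", yield_by_hsp = "yield_by_hsp.csv",
    seasons = "seasons.csv")
  trajectory_csv(char$rt_matrix, file.path(outdir, files["rt_trajectories"]))
  trajectory_csv(char$gt_matrix, file.path(outdir, files["gt_trajectories"]))
  write_cluster_model(char$wsp, file.path(outdir, files["wsp_model"]))
  write_cluster_model(char$hsp, file.path(outdir, files["hsp_model"]))
  readr::write_csv(char$wsp_freq, file.path(outdir, files["wsp_frequencies"]))
  readr::write_csv(char$hsp_freq, file.path(outdir, files["hsp_frequencies"]))
  readr::write_csv(char$yield_by_wsp, file.path(outdir, files["yield_by_wsp"]))
  readr::write_csv(char$yield_by_hsp, file.path(outdir, files["yield_by_hsp"]))
  seasons <- dplyr::mutate(char$meta,
                           wsp = char$wsp$labels, hsp = char$hsp$labels)
  seasons <- dplyr::arrange(seasons, .data$site, .data$year, .data$sowing,
                            .data$mgmt, .data$cultivar)
  readr::write_csv(seasons, file.path(outdir, files["seasons"]))
  jsonlite::write_json(manifest(outdir, char$config, char$seed, files),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

write_ecg_analysis <- function(an, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dplyr::arrange(an$site_year, .data$site, .data$year),
                   file.path(outdir, "site_year_classification.csv"))
  readr::write_csv(dplyr::arrange(an$trials, .data$site, .data$year,
                                  .data$hybrid),
                   file.path(outdir, "trials_with_ecg.csv"))
  if (!is.null(an$varcomp))
    jsonlite::write_json(
      list(components = as.list(an$varcomp$components),
           percentages = as.list(an$varcomp$percentages),
           method = an$varcomp$method, flags = an$varcomp$flags),
      file.path(outdir, "variance_components.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(an$biplot)) {
    sc <- tibble::tibble(hybrid = rownames(an$biplot$scores),
                         PC1 = an$biplot$scores[, 1],
                         PC2 = an$biplot$scores[, 2])
    ld <- tibble::tibble(ecg = rownames(an$biplot$loadings),
                         PC1 = an$biplot$loadings[, 1],
                         PC2 = an$biplot$loadings[, 2])
    readr::write_csv(sc, file.path(outdir, "biplot_scores.csv"))
    readr::write_csv(ld, file.path(outdir, "biplot_loadings.csv"))
  }
  invisible(outdir)
}
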