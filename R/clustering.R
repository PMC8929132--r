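#' Cluster stress trajectories with k-means
#'
#' Euclidean k-means (via [stats::kmeans()]) with `n_init` random restarts,
#' deterministic for a fixed seed. Trajectory bins share units and scale, so
#' no standardization is applied. The fraction of total variance captured by
#' the clustering is `1 - within-SS / total-SS` about the grand mean; for a
#' degenerate matrix whose rows are all identical (total SS zero) it is
#' defined as 0 and a non-empty split is returned with zero inertia.
#'
#' @param x A trajectory matrix: either the numeric matrix itself or a
#'   `trajectory_matrix` from [build_trajectory_matrix()].
#' @param k Number of clusters, `2 <= k <= nrow(x)`.
#' @param seed Integer seed.
#' @param n_init Number of random restarts (default 25).
#' @return A list of class `cluster_model`: `k`, `centroids` (k x bins),
#'   `labels`, `inertia` (total within-cluster SS), `variance_explained`,
#'   `sizes`, `seed`.
#' @export
fit_kmeans <- function(x, k, seed, n_init = 25) {
  x <- trajectory_x(x)
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(x)) stop("k cannot exceed the number of rows")
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    # fewer distinct rows than clusters: kmeans cannot seed k centers.
    # Convention: split arbitrarily but leave no cluster empty; all
    # centroids coincide with the duplicated rows, inertia contributed
    # only by genuine spread (zero when rows are identical).
    labels <- c(seq_len(k - 1), rep(k, nrow(x) - k + 1))
    centroids <- do.call(rbind, lapply(seq_len(k), function(j)
      colMeans(x[labels == j, , drop = FALSE])))
    within <- sum(vapply(seq_len(k), function(j) {
      xs <- x[labels == j, , drop = FALSE]
      sum(sweep(xs, 2, colMeans(xs))^2)
    }, numeric(1)))
    totss <- sum(sweep(x, 2, colMeans(x))^2)
    ve <- if (totss > 0) 1 - within / totss else 0
    return(structure(list(k = k, centroids = centroids, labels = labels,
                          inertia = within, variance_explained = ve,
                          sizes = tabulate(labels, k), seed = seed),
                     class = "cluster_model"))
  }
  km <- withr::with_seed(seed,
    stats::kmeans(x, centers = k, nstart = n_init, iter.max = 200))
  ve <- if (km$totss > 0) 1 - km$tot.withinss / km$totss else 0
  structure(list(k = k, centroids = unname(km$centers),
                 labels = as.integer(km$cluster), inertia = km$tot.withinss,
                 variance_explained = ve, sizes = km$size, seed = seed),
            class = "cluster_model")
}

trajectory_x <- function(x) {
  if (inherits(x, "trajectory_matrix")) x <- x$x
  x <- as.matrix(x)
  if (anyNA(x)) stop("trajectory matrix must have no missing values")
  x
}

# Calinski-Harabasz pseudo-F: between-group over within-group dispersion
calinski_harabasz <- function(x, labels, k) {
  n <- nrow(x)
  grand <- colMeans(x)
  within <- 0
  between <- 0
  for (j in unique(labels)) {
    xs <- x[labels == j, , drop = FALSE]
    cj <- colMeans(xs)
    within <- within + sum(sweep(xs, 2, cj)^2)
    between <- between + nrow(xs) * sum((cj - grand)^2)
  }
  if (within == 0) return(Inf)
  (between / (k - 1)) / (within / (n - k))
}

# Davies-Bouldin index: mean over clusters of the worst ratio of summed
# within-cluster scatter to centroid separation (smaller is better)
davies_bouldin <- function(x, labels, centroids) {
  k <- nrow(centroids)
  s <- vapply(seq_len(k), function(j) {
    xs <- x[labels == j, , drop = FALSE]
    mean(sqrt(rowSums(sweep(xs, 2, centroids[j, ])^2)))
  }, numeric(1))
  db <- vapply(seq_len(k), function(j) {
    r <- vapply(setdiff(seq_len(k), j), function(l) {
      d <- sqrt(sum((centroids[j, ] - centroids[l, ])^2))
      if (d == 0) Inf else (s[j] + s[l]) / d
    }, numeric(1))
    max(r)
  }, numeric(1))
  mean(db)
}

#' Choose the number of stress patterns by internal-validity vote
#'
#' Fits k-means for every candidate `k` and scores each solution with three
#' internal validity indices: mean silhouette width (maximized),
#' Calinski-Harabasz pseudo-F (maximized) and Davies-Bouldin (minimized).
#' Each index votes for its best `k`; the majority wins, and ties are broken
#' toward the smaller `k`.
#'
#' @param x Trajectory matrix (matrix or `trajectory_matrix`).
#' @param k_range Candidate cluster counts (default `2:8`).
#' @param seed Integer seed shared by all fits.
#' @param n_init Restarts per fit.
#' @return A list: `k` (chosen), `votes` (per-index best k),
#'   `index_table` (tibble of all index values), `models` (fitted
#'   `cluster_model` per candidate, named by k).
#' @export
select_k <- function(x, k_range = 2:8, seed = 1, n_init = 25) {
  x <- trajectory_x(x)
  if (length(k_range) == 0) stop("k_range must be non-empty")
  if (nrow(x) <= max(k_range)) stop("need more rows than max(k_range)")
  d <- stats::dist(x)
  models <- lapply(k_range, function(k) fit_kmeans(x, k, seed, n_init))
  names(models) <- as.character(k_range)
  idx <- lapply(models, function(m) {
    sil <- mean(cluster::silhouette(m$labels, d)[, "sil_width"])
    c(silhouette = sil,
      calinski_harabasz = calinski_harabasz(x, m$labels, m$k),
      davies_bouldin = davies_bouldin(x, m$labels, m$centroids))
  })
  tab <- tibble::tibble(
    k = k_range,
    silhouette = vapply(idx, `[[`, numeric(1), "silhouette"),
    calinski_harabasz = vapply(idx, `[[`, numeric(1), "calinski_harabasz"),
    davies_bouldin = vapply(idx, `[[`, numeric(1), "davies_bouldin"))
  votes <- c(silhouette = k_range[which.max(tab$silhouette)],
             calinski_harabasz = k_range[which.max(tab$calinski_harabasz)],
             davies_bouldin = k_range[which.min(tab$davies_bouldin)])
  counts <- table(votes)
  winners <- as.integer(names(counts)[counts == max(counts)])
  list(k = min(winners), votes = votes, index_table = tab, models = models)
}

#' Classify a trajectory into a fitted stress pattern
#'
#' Assigns the cluster whose centroid minimizes the sum of squared
#' differences to the trajectory; ties go to the lowest cluster id.
#'
#' @param traj Bin vector (or a matrix of trajectories, one per row).
#' @param model A `cluster_model` from [fit_kmeans()].
#' @return Integer cluster label(s).
#' @export
classify_trajectory <- function(traj, model) {
  stopifnot(inherits(model, "cluster_model"))
  tm <- if (is.matrix(traj)) traj else matrix(traj, nrow = 1)
  if (ncol(tm) != ncol(model$centroids))
    stop("trajectory length does not match centroid length")
  # squared distances via the expansion |t|^2 - 2 t.c + |c|^2
  cross <- tm %*% t(model$centroids)
  d2 <- outer(rowSums(tm^2), rep(1, model$k)) - 2 * cross +
    outer(rep(1, nrow(tm)), rowSums(model$centroids^2))
  apply(d2, 1, which.min)   # which.min takes the first (lowest id) on ties
}

#' Stress-pattern frequencies by group
#'
#' @param model A `cluster_model` (or an integer label vector).
#' @param meta Data frame of row labels aligned with the clustered rows.
#' @param group_by Name of the grouping column in `meta` (e.g. `"site"`).
#' @return Tidy tibble `group, cluster, count, frequency`; frequencies sum to
#'   1 within each group. Clusters absent from a group appear with count 0.
#' @export
cluster_frequencies <- function(model, meta, group_by = "site") {
  labels <- if (inherits(model, "cluster_model")) model$labels else
    as.integer(model)
  k <- if (inherits(model, "cluster_model")) model$k else max(labels)
  if (!group_by %in% names(meta))
    stop("unknown group key: ", group_by)
  stopifnot(length(labels) == nrow(meta))
  df <- tibble::tibble(group = meta[[group_by]], cluster = labels)
  out <- df |>
    dplyr::count(.data$group, .data$cluster, name = "count") |>
    tidyr::complete(.data$group, cluster = seq_len(k),
                    fill = list(count = 0L)) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(frequency = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  names(out)[1] <- group_by
  out
}

#' Name fitted water-stress centroids by trajectory shape
#'
#' Heuristic labels for reporting: the centroid with the highest overall
#' mean is `"low_stress"`; among the rest, the one with the deepest
#' mid-season dip that recovers by season end is `"flowering_stress"`, the
#' one ending lowest is `"terminal_stress"`, and a terminal decline that
#' lifts over the final bins is `"terminal_recovery"`. Purely descriptive —
#' clustering itself never uses these names.
#'
#' @param centroids k x bins matrix.
#' @return Character vector of k labels (unique, suffixed if needed).
#' @export
name_wsp_centroids <- function(centroids) {
  k <- nrow(centroids)
  nb <- ncol(centroids)
  labels <- rep(NA_character_, k)
  labels[which.max(rowMeans(centroids))] <- "low_stress"
  for (j in which(is.na(labels))) {
    dip_at <- which.min(centroids[j, ])
    recovery <- centroids[j, nb] - centroids[j, dip_at]
    labels[j] <- if (recovery > 0.15) {
      if (dip_at <= 0.8 * nb) "flowering_stress" else "terminal_recovery"
    } else "terminal_stress"
  }
  make.unique(labels)
}
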