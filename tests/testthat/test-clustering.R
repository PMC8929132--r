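test_that("two separated point masses are recovered exactly", {
  x <- rbind(matrix(0.1, 20, 6), matrix(0.9, 15, 6))
  m <- fit_kmeans(x, 2, seed = 1)
  expect_equal(sort(m$centroids[, 1]), c(0.1, 0.9))
  expect_equal(m$inertia, 0)
  expect_equal(m$variance_explained, 1)
  expect_equal(length(unique(m$labels)), 2)
})

test_that("identical rows split without empty clusters, inertia zero", {
  x <- matrix(0.4, 10, 5)
  m <- fit_kmeans(x, 2, seed = 3)
  expect_equal(m$inertia, 0)
  expect_equal(m$variance_explained, 0)
  expect_true(all(tabulate(m$labels, 2) > 0))
  expect_true(all(m$centroids == 0.4))
})

test_that("fitting is deterministic for a seed and centroids are member means", {
  g <- gen_stress_prototypes(wsp_prototypes(12), 20, 0.1, seed = 5)
  m1 <- fit_kmeans(g$x, 4, seed = 11)
  m2 <- fit_kmeans(g$x, 4, seed = 11)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$centroids, m2$centroids)
  for (j in seq_len(4))
    expect_equal(m1$centroids[j, ],
                 colMeans(g$x[m1$labels == j, , drop = FALSE]))
  expect_error(fit_kmeans(g$x, 1, seed = 1), "at least 2")
  expect_error(fit_kmeans(g$x, 100, seed = 1), "exceed")
})

test_that("label recovery on noisy prototypes beats 95% after permutation", {
  g <- gen_stress_prototypes(wsp_prototypes(12), 25, 0.05, seed = 7)
  m <- fit_kmeans(g$x, 4, seed = 2)
  expect_gte(matched_accuracy(m$labels, g$truth, 4), 0.95)
})

test_that("the validity-index vote finds clear structure and falls back on none", {
  set.seed(8)
  blobs <- rbind(matrix(rnorm(60, 0.15, 0.03), ncol = 6),
                 matrix(rnorm(60, 0.5, 0.03), ncol = 6),
                 matrix(rnorm(60, 0.85, 0.03), ncol = 6))
  sel <- select_k(blobs, 2:6, seed = 4)
  expect_equal(sel$k, 3)
  expect_named(sel$votes, c("silhouette", "calinski_harabasz",
                            "davies_bouldin"))
  single <- matrix(rnorm(240, 0.5, 0.02), ncol = 6)
  sel1 <- select_k(single, 2:5, seed = 4)
  # no structure: ties resolve toward the smallest candidate
  expect_true(sel1$k %in% 2:3)
  expect_error(select_k(blobs, integer(0), seed = 1), "non-empty")
})

test_that("classification agrees with the exhaustive distance oracle", {
  g <- gen_stress_prototypes(wsp_prototypes(10), 15, 0.08, seed = 9)
  m <- fit_kmeans(g$x, 4, seed = 9)
  set.seed(10)
  trajs <- matrix(runif(200 * 10), ncol = 10)
  got <- classify_trajectory(trajs, m)
  oracle <- apply(trajs, 1, function(tr)
    which.min(colSums((t(m$centroids) - tr)^2)))
  expect_equal(got, oracle)
  # self-classification and documented tie-break
  expect_equal(classify_trajectory(m$centroids[3, ], m), 3L)
  m2 <- m
  m2$centroids <- rbind(rep(0.2, 10), rep(0.8, 10))
  m2$k <- 2
  expect_equal(classify_trajectory(rep(0.5, 10), m2), 1L)
  expect_error(classify_trajectory(rep(0.5, 9), m), "length")
})

test_that("training rows are never closer to a foreign centroid than reported", {
  g <- gen_stress_prototypes(wsp_prototypes(12), 30, 0.15, seed = 21)
  m <- fit_kmeans(g$x, 4, seed = 21)
  relabeled <- classify_trajectory(g$x, m)
  nearest_inertia <- sum(vapply(seq_len(nrow(g$x)), function(i)
    sum((g$x[i, ] - m$centroids[relabeled[i], ])^2), numeric(1)))
  expect_lte(nearest_inertia, m$inertia + 1e-8)
})

test_that("frequency tables sum to one per group and reaggregate globally", {
  labels <- c(rep(1L, 10), rep(2L, 10), rep(3L, 10), rep(4L, 10))
  meta <- tibble::tibble(site = rep("s1", 40))
  f <- cluster_frequencies(structure(list(labels = labels, k = 4L),
                                     class = "cluster_model"), meta)
  expect_equal(f$frequency, rep(0.25, 4))

  set.seed(12)
  meta2 <- tibble::tibble(site = sample(c("a", "b", "c"), 40, replace = TRUE))
  f2 <- cluster_frequencies(labels, meta2)
  sums <- tapply(f2$frequency, f2$site, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # size-weighted group frequencies reproduce the global frequency vector
  counts <- tapply(f2$count, f2$site, sum)
  global <- sapply(1:4, function(k)
    sum(f2$frequency[f2$cluster == k] * counts[f2$site[f2$cluster == k]]) /
      sum(counts))
  expect_equal(unname(global), as.numeric(table(labels) / 40))
  expect_error(cluster_frequencies(labels, meta2, "region"), "unknown group")
})

test_that("centroid shape naming identifies the four canonical patterns", {
  protos <- wsp_prototypes(12)
  centroids <- do.call(rbind, protos)
  labs <- name_wsp_centroids(centroids)
  expect_setequal(labs, c("flowering_stress", "low_stress",
                          "terminal_stress", "terminal_recovery"))
  expect_equal(labs[2], "low_stress")
})
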