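test_that("prototype copies are exact at zero noise and counted correctly", {
  protos <- wsp_prototypes(12)
  g <- gen_stress_prototypes(protos, n_per_cluster = 25, noise_sd = 0,
                             seed = 1)
  expect_equal(nrow(g$x), 100)
  for (j in 1:4)
    expect_true(all(apply(g$x[g$truth == j, ], 1, identical,
                          unname(protos[[j]]))))
})

test_that("nearest-prototype assignment recovers well-separated labels", {
  # two prototypes 0.6 apart in every bin, noise sd 0.05
  protos <- list(a = rep(0.2, 8), b = rep(0.8, 8))
  g <- gen_stress_prototypes(protos, 50, noise_sd = 0.05, seed = 42)
  # brute-force nearest-prototype oracle
  assigned <- apply(g$x, 1, function(row)
    which.min(vapply(protos, function(p) sum((row - p)^2), numeric(1))))
  expect_equal(unname(assigned), g$truth)
})

test_that("prototype generator rejects malformed inputs", {
  expect_error(gen_stress_prototypes(list(), 5, 0.1, 1), "non-empty")
  expect_error(gen_stress_prototypes(list(c(0.1, 0.2), c(0.3)), 5, 0.1, 1),
               "equal length")
  expect_error(gen_stress_prototypes(list(c(0.5, 1.2)), 5, 0.1, 1), "0, 1")
})

test_that("degenerate trial variances collapse to the grand mean", {
  tv <- trial_variance(0, 0, 0, 0, grand_mean = 5000)
  tt <- gen_trial_table(4, 3, c("h1", "h2"), tv, missing_frac = 0, seed = 9)
  expect_equal(nrow(tt), 4 * 3 * 2)
  expect_true(all(tt$yield_kg_ha == 5000))
  expect_error(trial_variance(-1, 0, 0, 0), ">= 0")
})

test_that("record deletion behaves binomially", {
  tv <- trial_variance(1e5, 1e5, 1e5, 1e5)
  tt <- gen_trial_table(8, 5, paste0("h", 1:6), tv, missing_frac = 0.2,
                        seed = 13)
  n_full <- 8 * 5 * 6
  expected <- n_full * 0.8
  sd3 <- 3 * sqrt(n_full * 0.2 * 0.8)
  expect_lt(abs(nrow(tt) - expected), sd3)
})

test_that("simulated site effects carry the requested variance", {
  tv <- trial_variance(sigma2_site = 9e5, sigma2_ecg_within_site = 1e4,
                       sigma2_hybrid = 0, sigma2_resid = 1e4)
  tt <- gen_trial_table(200, 2, "h1", tv, seed = 31)
  realized <- stats::var(attr(tt, "site_effects"))
  expect_lt(abs(realized - 9e5) / 9e5, 0.15)
})

test_that("the spread of site means grows with sigma2_site", {
  site_mean_var <- function(s2, seed) {
    tv <- trial_variance(s2, 1e3, 0, 1e3)
    tt <- gen_trial_table(30, 4, "h1", tv, seed = seed)
    stats::var(tapply(tt$yield_kg_ha, tt$site, mean))
  }
  lo <- vapply(1:30, function(s) site_mean_var(1e3, s), numeric(1))
  hi <- vapply(1:30, function(s) site_mean_var(4e5, s), numeric(1))
  expect_gt(median(hi), median(lo))
})
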