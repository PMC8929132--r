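test_that("a constant yield table decomposes to all-zero components", {
  tab <- tidyr::expand_grid(site = c("a", "b"), ecg = c("E1", "E2"),
                            rep = 1:3)
  tab$yield_kg_ha <- 4000
  vd <- variance_components(tab)
  expect_true(all(vd$components == 0))
  expect_match(paste(vd$flags, collapse = " "), "zero total variance")
  expect_equal(sum(vd$percentages), 100)
})

test_that("REML matches the expected-mean-squares oracle on balanced data", {
  # balanced nested design: closed-form method-of-moments estimators
  n_site <- 12; n_ecg <- 4; reps <- 6
  s2_site <- 40; s2_ecg <- 25; s2_res <- 9
  set.seed(55)
  tab <- tidyr::expand_grid(site = sprintf("s%02d", 1:n_site),
                            ecg = paste0("E", 1:n_ecg), rep = 1:reps)
  site_eff <- rnorm(n_site, 0, sqrt(s2_site))
  cell_eff <- rnorm(n_site * n_ecg, 0, sqrt(s2_ecg))
  cell_id <- as.integer(factor(paste(tab$site, tab$ecg)))
  tab$yield_kg_ha <- 100 + site_eff[as.integer(factor(tab$site))] +
    cell_eff[cell_id] + rnorm(nrow(tab), 0, sqrt(s2_res))

  fit <- stats::lm(yield_kg_ha ~ site + site:ecg, data = tab)
  av <- stats::anova(fit)
  ms_site <- av["site", "Mean Sq"]
  ms_cell <- av["site:ecg", "Mean Sq"]
  ms_res <- av["Residuals", "Mean Sq"]
  mom <- c(site = (ms_site - ms_cell) / (reps * n_ecg),
           ecg_in_site = (ms_cell - ms_res) / reps,
           residual = ms_res)

  vd <- variance_components(tab)
  expect_equal(vd$components[["site"]], mom[["site"]], tolerance = 1e-4)
  expect_equal(vd$components[["ecg_in_site"]], mom[["ecg_in_site"]],
               tolerance = 1e-4)
  expect_equal(vd$components[["residual"]], mom[["residual"]],
               tolerance = 1e-4)
  expect_equal(sum(vd$percentages), 100, tolerance = 1e-6)
})

test_that("percentages are invariant to unit rescaling", {
  tv <- trial_variance(4, 6, 0, 2, grand_mean = 50)
  tab <- gen_trial_table(20, 8, "h1", tv, seed = 77)
  vd1 <- variance_components(tab)
  tab2 <- tab
  tab2$yield_kg_ha <- tab2$yield_kg_ha * 1000
  vd2 <- variance_components(tab2)
  expect_equal(vd1$percentages, vd2$percentages, tolerance = 1e-3)
  expect_equal(unname(vd2$components / vd1$components),
               rep(1e6, 3), tolerance = 1e-3)
})

test_that("a fully confounded design is flagged", {
  tab <- tidyr::expand_grid(site = c("a", "b", "c"), rep = 1:5)
  tab$ecg <- paste0("E", as.integer(factor(tab$site)))  # one ECG per site
  set.seed(2)
  tab$yield_kg_ha <- rnorm(nrow(tab), 100, 5)
  vd <- variance_components(tab)
  expect_match(paste(vd$flags, collapse = " "), "confounded")
})

test_that("an optional hybrid term captures hybrid variance", {
  tv <- trial_variance(1e5, 1e5, 4e5, 1e4)
  tab <- gen_trial_table(15, 8, paste0("h", 1:6), tv, seed = 91)
  vd <- variance_components(tab, include_hybrid = TRUE)
  expect_true("hybrid" %in% names(vd$components))
  expect_gt(vd$components[["hybrid"]], vd$components[["residual"]])
})
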