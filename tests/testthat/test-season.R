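test_that("the GT seed-set factor hits both extremes", {
  cv <- toy_cultivar()                     # anthesis 400, window -50/+100
  tt <- rep(10, 80)                        # cum_tt 10..800
  cool <- rep(28, 80)
  hot <- rep(35, 80)
  expect_equal(gt_seed_set_factor(cool, tt, cv), 1)
  expect_equal(gt_seed_set_factor(hot, tt, cv), 0)
})

test_that("a half-stressed window yields a factor of one half", {
  cv <- toy_cultivar()
  tt <- rep(10, 80)
  # window covers cum_tt 350..500, i.e. days 35..50; heat the first half
  tmax <- rep(28, 80)
  tmax[35:42] <- 35                        # 8 of 16 window days, equal tt
  expect_equal(gt_seed_set_factor(tmax, tt, cv), 0.5)
})

test_that("tt weighting and day weighting disagree when hot days carry more tt", {
  cv <- toy_cultivar()
  tt <- rep(10, 80)
  tt[35:42] <- 15                          # hot days accumulate faster
  tt[43:52] <- 5
  tmax <- rep(28, 80)
  tmax[35:42] <- 35
  by_tt <- gt_seed_set_factor(tmax, tt, cv)
  by_day <- gt_seed_set_factor(tmax, tt, cv, weighting = "days")
  expect_false(isTRUE(all.equal(by_tt, by_day)))
})

test_that("a short season fails with an explicit error", {
  cv <- toy_cultivar()
  expect_error(gt_seed_set_factor(rep(30, 10), rep(10, 10), cv),
               "season too short")
})

test_that("an irrigated cool season is completely unstressed", {
  w <- constant_weather(150, tmax = 30, tmin = 20, rain = 15)
  s <- simulate_season(w, toy_soil(), toy_cultivar(), w$date[1], 28)
  expect_true(all(s$daily$rt == 1))
  expect_true(all(s$daily$gt == 1))
  expect_equal(s$gt_factor, 1)
  expect_true(s$anthesis_day < s$maturity_day)
  expect_gt(s$yield, 0)
})

test_that("withholding rain never increases yield", {
  cv <- toy_cultivar()
  sp <- toy_soil()
  for (seed in 1:8) {
    w <- gen_weather(flat_climate(tmax = 31, tmin = 18, prob = 0.35,
                                  depth = 7), 2001, 1, seed = seed)
    full <- simulate_season(w, sp, cv, "2001-05-01", 28)
    dry_w <- w
    dry_w$rain <- dry_w$rain * 0.25
    dry <- simulate_season(dry_w, sp, cv, "2001-05-01", 28)
    expect_lte(dry$yield, full$yield)
  }
})

test_that("added heat during the window never increases yield", {
  cv <- toy_cultivar()
  sp <- toy_soil()
  w <- gen_weather(flat_climate(tmax = 31, tmin = 18, prob = 0.4, depth = 8),
                   2001, 1, seed = 5)
  base <- simulate_season(w, sp, cv, "2001-05-01", 28)
  hot_w <- w
  hot_w$tmax <- hot_w$tmax + 4
  hot <- simulate_season(hot_w, sp, cv, "2001-05-01", 28)
  expect_lte(hot$gt_factor, base$gt_factor)
  expect_lte(hot$yield / max(base$yield, 1e-9), 1 + 1e-9)
})

test_that("a dry season on an empty profile collapses towards zero yield", {
  w <- constant_weather(150, tmax = 32, tmin = 18, rain = 0)
  s <- simulate_season(w, toy_soil(), toy_cultivar(), w$date[1], 28,
                       init_fraction = 0)
  stressed <- which(s$daily$rt < 1)
  expect_gt(length(stressed), 0)
  after <- s$daily$rt[min(stressed):nrow(s$daily)]
  expect_true(all(diff(after) <= 1e-9))
  expect_lt(s$yield, 500)
})

test_that("seasons are deterministic and bounded, and short weather errors", {
  w <- gen_weather(site_preset("intermediate"), 2001, 1, seed = 3)
  s1 <- simulate_season(w, toy_soil(), toy_cultivar(), "2001-06-01", 28)
  s2 <- simulate_season(w, toy_soil(), toy_cultivar(), "2001-06-01", 28)
  expect_identical(s1$daily, s2$daily)
  expect_true(all(s1$daily$rt >= 0 & s1$daily$rt <= 1))
  expect_true(all(s1$daily$gt %in% c(0, 1)))
  expect_true(all(diff(s1$daily$cum_tt) >= 0))
  expect_error(simulate_season(w[1:170, ], toy_soil(), toy_cultivar(),
                               "2001-06-01", 28), "season incomplete")
  expect_error(simulate_season(w, toy_soil(), toy_cultivar(),
                               "1999-01-01", 28), "not found")
})
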