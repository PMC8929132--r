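test_that("root water supply follows the kl-weighted extractable water", {
  sp <- toy_soil()
  at_ll <- with(sp$layers, ll * thickness)
  expect_equal(water_supply(at_ll, sp, 1000), 0)
  # one fully rooted layer, 10 mm above its lower limit, kl 0.07
  one <- soil_profile(data.frame(thickness = 300, ll = 0.1, dul = 0.3,
                                 kl = 0.07))
  expect_equal(water_supply(0.1 * 300 + 10, one, 300), 0.7)
  # uniform identical layers: doubling root depth doubles supply
  uni <- soil_profile(data.frame(thickness = rep(200, 4), ll = rep(0.1, 4),
                                 dul = rep(0.3, 4), kl = rep(0.08, 4)))
  wet <- rep(0.25 * 200, 4)
  expect_equal(water_supply(wet, uni, 400), water_supply(wet, uni, 200) * 2)
  # supply is non-decreasing in root depth
  depths <- seq(0, 800, by = 50)
  sup <- vapply(depths, function(d) water_supply(wet, uni, d), numeric(1))
  expect_true(all(diff(sup) >= 0))
  expect_error(water_supply(wet, uni, -5), "root_depth")
})

test_that("the RT index is the capped supply/demand ratio", {
  expect_equal(rt_index(5, 5), 1)
  expect_equal(rt_index(3, 0), 1)
  expect_equal(rt_index(2, 8), 0.25)
  expect_equal(rt_index(12, 8), 1)
  expect_error(rt_index(-1, 2), ">= 0")
})

test_that("a zero-flux step leaves the profile unchanged", {
  sp <- toy_soil()
  w <- init_soil_water(sp, 0.7)
  st <- step_water_balance(w, 0, 0, 0, sp, 300)
  expect_equal(st$soil_water, w)
  expect_equal(st$closure, 0)
})

test_that("rain beyond profile capacity leaves as drainage", {
  sp <- toy_soil()
  w <- init_soil_water(sp, 0.5)
  capacity_deficit <- sum(sp$layers$dul * sp$layers$thickness - w)
  rain <- capacity_deficit + 25
  st <- step_water_balance(w, rain, 0, 0, sp, 0)
  expect_equal(st$drainage, 25)
  expect_equal(st$soil_water, sp$layers$dul * sp$layers$thickness)
})

test_that("transpiration above extractable supply is refused", {
  sp <- toy_soil()
  w <- init_soil_water(sp, 0.2)
  sup <- water_supply(w, sp, 500)
  expect_error(step_water_balance(w, 0, 0, sup + 1, sp, 500),
               "exceeds extractable supply")
})

test_that("mass balance closes over random 120-day seasons", {
  sp <- toy_soil()
  for (seed in 1:10) {
    set.seed(seed)
    w <- init_soil_water(sp, runif(1))
    cum_residual <- 0
    for (d in 1:120) {
      rain <- if (runif(1) < 0.3) rexp(1, 1 / 6) else 0
      depth <- runif(1, 100, 500)
      sup <- water_supply(w, sp, depth)
      transp <- runif(1) * sup
      st <- step_water_balance(w, rain, runif(1, 0, 2), transp, sp, depth)
      w <- st$soil_water
      cum_residual <- cum_residual + abs(st$closure)
      expect_true(all(w >= sp$layers$ll * sp$layers$thickness - 1e-9))
      expect_true(all(w <= sp$layers$dul * sp$layers$thickness + 1e-9))
    }
    expect_lt(cum_residual, 1e-4)
  }
})
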