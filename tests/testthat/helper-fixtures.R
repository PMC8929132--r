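# Small deterministic fixtures shared across test files.

toy_cultivar <- function(...) {
  cultivar_params(tt_emerge = 30, tt_anthesis = 400, tt_maturity = 700,
                  lai_midpoint = 250, name = "toy", ...)
}

toy_soil <- function() {
  soil_profile(data.frame(thickness = c(200, 300),
                          ll = c(0.10, 0.12), dul = c(0.30, 0.30),
                          kl = c(0.10, 0.07)),
               u_evap = 1.5, root_front_velocity = 2, max_root_depth = 1000,
               name = "toy")
}

# Constant weather: every day identical; rain as given.
constant_weather <- function(n_days, tmax = 30, tmin = 20, rain = 0,
                             radn = 20, start = as.Date("2001-05-01")) {
  tibble::tibble(date = start + seq_len(n_days) - 1,
                 year = as.integer(format(date, "%Y")),
                 doy = as.integer(format(date, "%j")),
                 tmax = tmax, tmin = tmin, rain = rain, radn = radn)
}

# All permutations of 1..n as rows (n small), for label matching.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

# Best label-permutation accuracy against known truth.
matched_accuracy <- function(labels, truth, k) {
  perms <- all_permutations(k)
  max(apply(perms, 1, function(p) mean(p[labels] == truth)))
}

# A climate with uniform monthly values, handy for distributional checks.
flat_climate <- function(tmax = 30, tmin = 15, prob = 0.3, depth = 6,
                         temp_sd = 3, rho = 0.6) {
  site_climate(monthly_tmax_mean = rep(tmax, 12),
               monthly_tmin_mean = rep(tmin, 12),
               temp_sd = temp_sd,
               rain_prob_wet = rep(prob, 12),
               rain_mean_depth = rep(depth, 12),
               ar1_rho = rho, name = "flat")
}
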