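test_that("transfer function hits its anchor points", {
  expect_equal(transfer_P(0, 2, 0.25), 0)
  expect_equal(transfer_P(1, 2, 0.25), 1)
  for (d in c(0.1, 0.25, 0.6)) {
    expect_equal(transfer_P(d, 3, d), (1 + d^3) / 2)
  }
  expect_error(transfer_P(1.2, 2, 0.25), "\\[0, 1\\]")
})

test_that("body composition follows the affine fat relation", {
  comp <- body_composition(45)
  expect_equal(comp$TAT, 10.8)
  expect_equal(comp$FFM, 34.2)
  expect_equal(comp$TAT + comp$FFM, 45)
  # the affine relation's root and the domain floor
  expect_equal(body_composition(9.9 / 0.46 + 1e-9)$TAT, 0, tolerance = 1e-6)
  expect_error(body_composition(20), "exceed")
})

test_that("caloric density is the fat/lean-weighted tissue energy", {
  expect_equal(caloric_density(), 0.46 * 39.5 + 0.54 * 7.6)
  expect_equal(caloric_density(), 22.274)
  ep <- energy_params()
  ep$e_fat_kj_g <- 10; ep$e_lean_kj_g <- 10
  expect_equal(caloric_density(ep), 10)
  # inverse relation: dE of -22.274 kJ is one gram lost
  expect_equal(-22.274 / caloric_density(), -1)
})

test_that("control food intake reproduces the energy-balance arithmetic", {
  # constant weight: FI = RMR * FFM
  veh <- data.frame(day = 0:9, bw_g = rep(45, 10))
  ct <- fi_control(veh)
  expect_equal(ct$fi_kj_day, rep(0.86 * 34.2, 10), tolerance = 1e-12)
  # steady gain of 0.1 g/day at 45 g: + 0.1 * caloric density at day of 45 g
  veh2 <- data.frame(day = 0:10, bw_g = 45 + 0.1 * (0:10 - 5))
  ct2 <- fi_control(veh2)
  expect_equal(ct2$fi_fun(5), 0.86 * 34.2 + 0.1 * 22.274, tolerance = 1e-9)
  # a one-day fasting dip is strongly attenuated by the smoother
  veh3 <- veh2
  veh3$bw_g[6] <- veh3$bw_g[6] - 1
  ct3 <- fi_control(veh3)
  raw_effect <- 1 * 0.86 * 0.54      # unsmoothed FFM shift of a 1 g dip
  expect_lt(abs(ct3$fi_fun(5) - ct2$fi_fun(5)), 0.5 * raw_effect)
  expect_error(fi_control(veh2[1:3, ]), "4")
})

test_that("printed-variant coefficient is available for FI_control", {
  veh <- data.frame(day = 0:10, bw_g = 45 + 0.1 * 0:10)
  fi_default <- fi_control(veh)$fi_fun(5)
  fi_printed <- fi_control(veh, as_printed = TRUE)$fi_fun(5)
  expect_equal(fi_printed - fi_default,
               0.1 * ((0.46 * 7.6 + 0.54 * 39.5) - 22.274), tolerance = 1e-9)
})

test_that("food intake blends baseline and overfeeding by P", {
  expect_equal(food_intake(1, 50, 40, 2, 30, 35), 30)
  expect_equal(food_intake(0, 45, 45, 2, 30, 35), 35)
  expect_equal(food_intake(0, 44, 40, 2, 30, 35), 35 * 1.1^2)
  expect_equal(fgf21_energy(0, 10.8, 0.5), 0)
  expect_equal(fgf21_energy(1, 10.8, 0), 0)
  expect_equal(fgf21_energy(1, 10.8, 0.5), -5.4)
})

test_that("null treatment reproduces the control trajectory exactly", {
  st <- bw_study(arms = data.frame(label = "null", dose_mg_per_kg = 0,
                                   route = "IV"),
                 days = study_days, vehicle = linear_vehicle(), bw0 = 45)
  sim <- simulate_bw(st, energy = energy_params(epsilon_kj_g_day = 1e-12))
  expect_lt(max(abs(sim$bw[, 1] - sim$control_bw)), 1e-9)
})

test_that("energy balance is conserved along the trajectory", {
  st <- bw_study(arms = standard_bw_arms()[3, ], days = study_days,
                 vehicle = linear_vehicle(), bw0 = 45)
  sim <- simulate_bw(st)
  tt <- sim$times_day
  int_de <- sum(diff(tt) * (head(sim$dE[, 1], -1) + tail(sim$dE[, 1], -1)) / 2)
  # trapezoid on the reported dE(t) vs the RK4-integrated weight change;
  # dE has kinks at dosing days, so the comparison is O(h^2) at best
  expect_equal(caloric_density() * (sim$bw[nrow(sim$bw), 1] - sim$bw[1, 1]),
               int_de, tolerance = 5e-3)
})

test_that("halving the integration step leaves the solution unchanged", {
  st <- bw_study(arms = standard_bw_arms()[3, ], days = study_days,
                 vehicle = linear_vehicle(), bw0 = 45)
  s1 <- simulate_bw(st, dt = 0.05)
  s2 <- simulate_bw(st, dt = 0.025)
  i <- match(s1$times_day, s2$times_day)
  expect_lt(max(abs(s1$bw[, 1] - s2$bw[i, 1])), 2e-3)
})

test_that("dose ordering, washout convergence and early decline hold", {
  study <- gen_bw_study(generator_spec(seed = 1, noise_cv = 0))
  sim <- attr(study, "clean_sim")
  nad <- bw_nadir(sim)
  rownames(nad) <- nad$arm
  # higher IV dose, deeper nadir
  expect_lt(nad["10_IV", "nadir_gap_g"], nad["3_IV", "nadir_gap_g"])
  expect_lt(nad["3_IV", "nadir_gap_g"], nad["1_IV", "nadir_gap_g"])
  # BW declines while signaling is high (first days after the first dose)
  i <- sim$times_day >= 0.5 & sim$times_day <= 3
  expect_true(all(diff(sim$bw[i, "10_IV" == sim$arms$label]) < 0))
  # after washout the gap closes toward control
  for (arm in c("10_IV", "10_SC")) {
    expect_gt(nad[arm, "final_gap_g"], nad[arm, "nadir_gap_g"])
    expect_lt(abs(nad[arm, "final_gap_g"]), 0.25 * abs(nad[arm, "nadir_gap_g"]))
  }
})

test_that("an epsilon = 0 model family cannot approach data generated with epsilon > 0", {
  study <- gen_bw_study(generator_spec(seed = 1, noise_cv = 0))
  truth <- attr(study, "truth")
  obj_truth <- bw_objective(study, truth$binding, truth$energy)
  expect_lt(obj_truth, 1e-8)
  # best epsilon = 0 candidate over a grid of the remaining parameters
  cands <- expand.grid(K_D_N = c(5, 30, 150), beta = c(0.5, 2, 5),
                       rho = c(1, 2), delta = c(0.1, 0.4))
  objs <- apply(cands, 1, function(r) {
    e <- energy_params(rho = r[["rho"]], delta = r[["delta"]],
                       beta = r[["beta"]], epsilon_kj_g_day = 1e-6)
    bw_objective(study, binding_params(K_D_N = r[["K_D_N"]]), e)
  })
  expect_gt(min(objs), 100 * max(obj_truth, 1e-10))
})
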