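test_that("log-linear trapezoid handles constant, rising and exponential segments", {
  # constant: linear rule, AUC = height * width
  p <- conc_profile("s1", "intact_NT", "IV", 10, 45,
                    times_hr = c(0, 5, 10), conc_ug_per_ml = rep(5, 3),
                    lloq = 1e-6)
  expect_equal(auc_log_linear(p), 50)

  # rising segment: linear rule
  p <- conc_profile("s2", "intact_NT", "SC", 10, 45,
                    times_hr = c(0, 1), conc_ug_per_ml = c(0, 10),
                    blq = c(FALSE, FALSE), lloq = 1e-6)
  expect_equal(auc_log_linear(p), 5)

  # exponential sampled at knots: log rule is segment-exact
  tt <- 0:10
  p <- exp_profile(100, 0.1, tt)
  expect_equal(auc_log_linear(p), 1000 * (1 - exp(-1)), tolerance = 1e-12)

  # fewer than 2 points is an error
  p1 <- conc_profile("s3", "intact_NT", "IV", 10, 45, times_hr = c(0, 24),
                     conc_ug_per_ml = c(5, 0.01), blq = c(FALSE, TRUE),
                     lloq = 0.2)
  expect_error(auc_log_linear(p1), "2 quantifiable")
})

test_that("AUC is additive over adjacent intervals and AUCinf >= AUC0t", {
  tt <- c(0, 1, 2, 4, 8, 24, 48)
  p <- exp_profile(50, 0.08, tt)
  a_total <- auc_log_linear(p, 48)
  a_split <- auc_log_linear(p, 8) +
    (a_total - auc_log_linear(p, 8))
  expect_equal(a_total, a_split)
  # piecewise-exponential exactness over the whole profile
  expect_equal(a_total, 50 / 0.08 * (1 - exp(-0.08 * 48)), tolerance = 1e-12)
  s <- nca_summary(p)
  expect_gte(s$auc_0_inf, s$auc_0_t)
})

test_that("terminal phase recovers exact exponential half-lives", {
  p <- exp_profile(1, log(2) / 2, seq(0, 12, by = 2))
  tp <- terminal_phase(p)
  expect_equal(tp$t_half, 2, tolerance = 1e-10)

  p <- exp_profile(10, 0.05, c(24, 48, 72))
  tp <- terminal_phase(p)
  expect_equal(tp$lambda_z, 0.05, tolerance = 1e-10)

  # rising terminal phase errors out
  pr <- conc_profile("r", "intact_NT", "IV", 10, 45, times_hr = c(0, 4, 8),
                     conc_ug_per_ml = c(1, 2, 4), lloq = 1e-6)
  expect_error(terminal_phase(pr), "not declining")
})

test_that("terminal half-life estimate is unbiased under log-normal noise", {
  # 500 noisy replicates of a t1/2 = 22.7 h profile; mean recovery within 5%
  set.seed(42)
  k <- log(2) / 22.7
  tt <- c(6, 24, 48, 72)
  est <- replicate(500, {
    conc <- 10 * exp(-k * tt) * exp(rnorm(4, 0, 0.1))
    p <- conc_profile("mc", "intact_NT", "IV", 10, 45, times_hr = tt,
                      conc_ug_per_ml = conc, lloq = 1e-9)
    suppressWarnings(terminal_phase(p)$t_half)
  })
  expect_lt(abs(mean(est) - 22.7) / 22.7, 0.05)
})

test_that("nca_summary reproduces the one-compartment closed form", {
  # one-compartment IV: C0 = 200 ug/ml, k = 0.1/hr -> CL = 5 ml/h/kg, V = 50 ml/kg
  p <- exp_profile(200, 0.1, seq(0, 72, by = 0.5), dose = 10)
  s <- nca_summary(p)
  expect_equal(s$cl, 5, tolerance = 0.01)
  expect_equal(s$v_ss, 50, tolerance = 0.01)
  expect_equal(s$v_c, 50, tolerance = 0.01)
  expect_equal(s$t_half, log(2) / 0.1, tolerance = 1e-6)

  # CL identity: AUCinf numerically equal to dose (ug/kg) gives CL = 1
  p2 <- exp_profile(100, 0.1, seq(0, 96, by = 0.25), dose = 1)
  s2 <- nca_summary(p2)
  expect_equal(s2$auc_0_inf, 1000, tolerance = 1e-3) # 100/0.1
  expect_equal(s2$cl, 1, tolerance = 1e-5)
})

test_that("volumes are not applicable for SC profiles", {
  p <- exp_profile(10, 0.05, c(4, 8, 24, 48), route = "SC")
  expect_error(nca_volumes(p), "not applicable")
  s <- nca_summary(p)
  expect_true(is.na(s$v_c) && is.na(s$v_ss))
})

test_that("bioavailability follows the ratio-of-means convention", {
  expect_equal(bioavailability(x <- 7, x, 3, 3), 100)
  expect_equal(bioavailability(34.5, 448, 3, 3), 7.70, tolerance = 1e-3)
  expect_equal(bioavailability(2240, 3820, 10, 10), 58.6, tolerance = 1e-3)
  # dose normalization
  expect_equal(bioavailability(50, 100, 5, 10), 100)
  expect_error(bioavailability(10, 0, 1, 1), "IV AUC")
})

test_that("BLQ handling: leading BLQ as zero, later BLQ excluded", {
  p <- conc_profile("b", "intact_NT", "SC", 10, 45,
                    times_hr = c(0, 2, 4, 8, 24, 48),
                    conc_ug_per_ml = c(0.05, 5, 8, 4, 0.1, 1),
                    blq = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
                    lloq = 0.2)
  # AUC treats t=0 as 0 and skips the BLQ at 24 h (log segment 8 -> 48)
  expected <- (0 + 5) / 2 * 2 +              # linear up, 0-2 h
    (5 + 8) / 2 * 2 +                         # linear up, 2-4 h
    (8 - 4) / (log(8 / 4) / 4) +              # log down, 4-8 h
    (4 - 1) / (log(4 / 1) / 40)               # log down, 8-48 h (24 h skipped)
  expect_equal(auc_log_linear(p), expected)
})

test_that("group NCA table summarises per-subject parameters", {
  profs <- lapply(1:3, function(i) {
    p <- exp_profile(200 * (1 + 0.05 * i), 0.1, seq(0, 48, by = 2))
    p$subject_id <- paste0("s", i)
    p
  })
  tab <- nca_table(profs)
  expect_equal(nrow(tab$subjects), 3)
  expect_equal(nrow(tab$groups), 1)
  expect_equal(tab$groups$n, 3)
  expect_equal(tab$groups$cl_mean, mean(tab$subjects$cl))
})
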