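test_that("species enumeration gives the 16 states in three exclusive pools", {
  sp <- enumerate_species()
  expect_equal(nrow(sp), 16)
  expect_equal(anyDuplicated(sp$state), 0)
  counts <- table(sp$pool)
  expect_equal(as.integer(counts[c("intact", "n_only", "inactive")]),
               c(7, 5, 4))
  # pool labels are consistent with the bit definitions
  expect_true(all((sp$pool == "intact") ==
                    ((sp$c1 & sp$n1) | (sp$c2 & sp$n2))))
  expect_true(all((sp$pool == "n_only") ==
                    (!((sp$c1 & sp$n1) | (sp$c2 & sp$n2)) & (sp$n1 | sp$n2))))
})

test_that("reaction network matches the per-species enumeration", {
  net <- build_network(clip_pk_params(route = "SC"))
  # the worked example: [1101] participates in five systemic reactions
  expect_equal(reactions_touching(net, "1101"), 5)
  # fully clipped species: consumed only by backbone clearance
  expect_equal(reactions_touching(net, "0000", role = "source"), 1)
  # fully intact species: four clipping out-edges (2 C-rate + 2 N-rate)
  out <- net[net$source == "1111" & net$compartment == "systemic" &
               net$type != "clearance", ]
  expect_equal(nrow(out), 4)
  expect_equal(sort(table(out$type), decreasing = TRUE),
               sort(c(clip_C = 2L, clip_N = 2L), decreasing = TRUE),
               ignore_attr = TRUE)
  kC <- log(2) / 2.5
  kN <- log(2) / 13
  expect_equal(sort(unique(out$rate_per_hr)), sort(c(kN, kC)))
  # IV network has no depot or transport reactions
  net_iv <- build_network(clip_pk_params(route = "IV"))
  expect_false(any(net_iv$type == "transport"))
  expect_false(any(net_iv$compartment == "depot"))
})

test_that("with clipping off the dose decays as a single backbone exponential", {
  p <- clip_pk_params(t_half_C_hr = 1e12, t_half_N_hr = 1e12, route = "IV",
                      t_half_backbone_days = 12)
  t_half_hr <- 12 * 24
  tr <- simulate_clipping(p, c(0, t_half_hr))
  # only [1111] populated
  live <- colSums(tr$systemic) > 1e-9 * tr$dose_nmol
  expect_equal(tr$species$state[live], "1111")
  expect_equal(tr$systemic[2, tr$species$state == "1111"],
               tr$dose_nmol / 2, tolerance = 1e-6)
})

test_that("ODE observables match the independent-arm closed forms", {
  p <- clip_pk_params(route = "IV")
  tt <- seq(0, 72, by = 0.5)
  tr <- simulate_clipping(p, tt)
  obs <- pool_observables(tr)
  cf <- clip_closed_form_iv(p, tt)
  # relative where the pool is appreciable, absolute below 1e-6 of the dose
  rel <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-6))
  expect_lt(rel(obs$ct_signal / tr$dose_nmol, cf$ct_frac), 1e-6)
  expect_lt(rel(obs$nt_signal / tr$dose_nmol, cf$nt_frac), 1e-6)
  expect_lt(rel(obs$intact_pool / tr$dose_nmol, cf$intact_frac), 1e-6)

  # with backbone clearance off, intact fraction is 2s - s^2; 0.75 at s = 1/2
  p2 <- clip_pk_params(route = "IV", t_half_backbone_days = 1e9)
  k_arm <- log(2) / 2.5 + log(2) / 13
  t_star <- log(2) / k_arm
  tr2 <- simulate_clipping(p2, c(0, t_star))
  obs2 <- pool_observables(tr2)
  expect_equal(obs2$intact_pool[2] / tr2$dose_nmol, 0.75, tolerance = 1e-6)
})

test_that("pool partition identity holds: intact + n_only = nt_signal", {
  for (route in c("IV", "SC")) {
    tr <- simulate_clipping(clip_pk_params(route = route), seq(0, 96, by = 2))
    obs <- pool_observables(tr)
    expect_equal(obs$intact_pool + obs$n_only_pool, obs$nt_signal,
                 tolerance = 1e-10)
    expect_true(all(obs$intact_pool <= obs$nt_signal + 1e-12))
    expect_true(all(obs$intact_pool <= obs$ct_signal + 1e-12))
  }
})

test_that("mass conservation and dose linearity hold to solver tolerance", {
  # clearance off: total amount constant
  p <- clip_pk_params(route = "SC", t_half_backbone_days = 1e9)
  tr <- simulate_clipping(p, seq(0, 120, by = 4))
  total <- rowSums(tr$depot) + rowSums(tr$systemic)
  expect_equal(total, rep(tr$dose_nmol, length(total)), tolerance = 1e-8)

  # clearance on, IV: total = dose * exp(-kb t)
  p2 <- clip_pk_params(route = "IV")
  tt <- seq(0, 240, by = 8)
  tr2 <- simulate_clipping(p2, tt)
  kb <- log(2) / (12 * 24)
  expect_equal(rowSums(tr2$systemic), tr2$dose_nmol * exp(-kb * tt),
               tolerance = 1e-8)

  # nonnegativity within solver noise
  expect_gt(min(tr2$systemic), -1e-12 * tr2$dose_nmol)

  # doubling the dose doubles every species trajectory
  p3 <- p2
  p3$dose_mg_per_kg <- 2 * p2$dose_mg_per_kg
  tr3 <- simulate_clipping(p3, tt)
  expect_equal(tr3$systemic, 2 * tr2$systemic, tolerance = 1e-9)
})

test_that("trajectories are invariant under arm relabeling", {
  sp <- enumerate_species()
  swapped <- paste0(substr(sp$state, 3, 4), substr(sp$state, 1, 2))
  idx <- match(swapped, sp$state)
  tr <- simulate_clipping(clip_pk_params(route = "SC"), seq(0, 48, by = 4))
  expect_equal(tr$systemic, tr$systemic[, idx], tolerance = 1e-10)
  expect_equal(tr$depot, tr$depot[, idx], tolerance = 1e-10)
})

test_that("matrix exponential reproduces the lsoda solution", {
  skip_if_not_installed("Matrix")
  p <- clip_pk_params(route = "SC")
  A <- fgf21pkpd:::.clip_rate_matrix(p)
  tr <- simulate_clipping(p, c(0, 6, 24, 72))
  y0 <- numeric(32)
  y0[which(tr$species$state == "1111")] <- tr$dose_nmol
  for (i in 2:4) {
    y <- as.numeric(Matrix::expm(A * tr$times_hr[i]) %*% y0)
    expect_equal(c(tr$depot[i, ], tr$systemic[i, ]), y, tolerance = 1e-7)
  }
})

test_that("Monte-Carlo oracle agrees with the ODE pools", {
  tt <- c(3, 12, 36)
  for (route in c("IV", "SC")) {
    p <- clip_pk_params(route = route)
    tr <- simulate_clipping(p, c(0, tt))
    obs <- pool_observables(tr)
    mc <- clip_mc_oracle(p, n_molecules = 30000, seed = 7, times_hr = tt)
    cols <- c(ct = "ct_signal", nt = "nt_signal", intact = "intact_pool",
              n_only = "n_only_pool")
    for (i in seq_along(tt)) {
      for (pool in names(cols)) {
        ode_frac <- obs[[cols[[pool]]]][i + 1] / tr$dose_nmol
        se <- max(mc[[paste0(pool, "_se")]][i], 1e-6)
        expect_lt(abs(mc[[paste0(pool, "_frac")]][i] - ode_frac), 4 * se)
      }
    }
  }
})
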