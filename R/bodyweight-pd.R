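## Energy-balance body-weight model for DIO mice.  Receptor occupancy in
## adipose drives a sigmoidal instantaneous effect P(t); P(t) both blends
## food intake between the treated baseline and an overfeeding response and
## scales an adipose thermogenesis ("browning") energy-consumption term.
## Body weight integrates dBW/dt = dE(t) / caloric density with a fixed-step
## 4th-order Runge-Kutta scheme.

#' Energy-balance parameters
#'
#' Fixed physiology: total adipose tissue `TAT = 0.46 BW - 9.9 g`, fat
#' 39.5 kJ/g, lean 7.6 kJ/g, RMR 0.86 kJ/(g FFM day).  Fitted pharmacology:
#' `rho`, `delta` (transfer function), `beta` (overfeeding), `epsilon`
#' (thermogenesis, kJ/(g TAT day)).
#'
#' @param fat_slope,fat_intercept_g TAT vs BW affine relation
#' @param e_fat_kj_g,e_lean_kj_g tissue energy densities, kJ/g
#' @param rmr_kj_g_day resting metabolic rate per g fat-free mass per day
#' @param rho,delta transfer-function shape (Hill exponent, midpoint RO)
#' @param beta overfeeding exponent
#' @param epsilon_kj_g_day maximal thermogenesis rate, kJ/(g TAT day)
#' @return list of class `energy_params`
#' @export
energy_params <- function(fat_slope = 0.46, fat_intercept_g = 9.9,
                          e_fat_kj_g = 39.5, e_lean_kj_g = 7.6,
                          rmr_kj_g_day = 0.86,
                          rho = 2, delta = 0.25, beta = 2,
                          epsilon_kj_g_day = 0.8) {
  stopifnot(fat_slope > 0, fat_slope < 1, e_fat_kj_g > e_lean_kj_g,
            e_lean_kj_g > 0, rmr_kj_g_day > 0, rho > 0, delta > 0,
            delta <= 1, beta >= 0, epsilon_kj_g_day >= 0)
  structure(list(fat_slope = fat_slope, fat_intercept_g = fat_intercept_g,
                 e_fat_kj_g = e_fat_kj_g, e_lean_kj_g = e_lean_kj_g,
                 rmr_kj_g_day = rmr_kj_g_day, rho = rho, delta = delta,
                 beta = beta, epsilon_kj_g_day = epsilon_kj_g_day),
            class = "energy_params")
}

#' Sigmoidal transfer from receptor occupancy to instantaneous effect
#'
#' `P = (1 + delta^rho) RO^rho / (delta^rho + RO^rho)`; the normalization
#' makes `P(1) = 1`, and `P(delta) = (1 + delta^rho)/2`.
#'
#' @param RO receptor occupancy in `[0, 1]` (vector)
#' @param rho Hill exponent
#' @param delta midpoint occupancy
#' @return effect in `[0, 1]`
#' @export
transfer_P <- function(RO, rho, delta) {
  if (any(RO < 0 | RO > 1)) stop("RO must lie in [0, 1]")
  dr <- delta^rho
  (1 + dr) * RO^rho / (dr + RO^rho)
}

#' Body composition from body weight
#'
#' @param BW body weight, g (vector)
#' @param params an [energy_params()]
#' @return list with `TAT` and `FFM`, g
#' @export
body_composition <- function(BW, params = energy_params()) {
  floor_bw <- params$fat_intercept_g / params$fat_slope
  if (any(BW <= floor_bw)) {
    stop(sprintf("BW must exceed %.2f g for the composition relation",
                 floor_bw))
  }
  TAT <- params$fat_slope * BW - params$fat_intercept_g
  list(TAT = TAT, FFM = BW - TAT)
}

#' Caloric density of body-weight change
#'
#' The tissue-energy coefficient `0.46 e_fat + 0.54 e_lean` (22.274 kJ/g at
#' the defaults) used both to convert energy imbalance to weight change and
#' in the food-intake bookkeeping.
#'
#' @param params an [energy_params()]
#' @return kJ per g of body-weight change
#' @export
caloric_density <- function(params = energy_params()) {
  params$fat_slope * params$e_fat_kj_g +
    (1 - params$fat_slope) * params$e_lean_kj_g
}

#' Control-group food intake from vehicle body weights
#'
#' `FI_control(t) = RMR * FFM(t) + dBW/dt * caloric density`, with the body
#' weights smoothed by a centered moving average (to suppress pre-measurement
#' fasting dips) and the derivative taken on the smoothed series.
#'
#' @param vehicle data frame with `day` and `bw_g`
#' @param params an [energy_params()]
#' @param window smoothing window, in measurements (odd; default 3)
#' @param as_printed use the swapped coefficient `0.46 e_lean + 0.54 e_fat`
#'   in the weight-change term (reproduces a printed variant of the
#'   bookkeeping; default `FALSE` keeps the energy balance self-consistent)
#' @return list with `day`, `fi_kj_day`, `bw_smooth_g`, and interpolating
#'   functions `fi_fun(t)`, `bw_fun(t)`
#' @export
fi_control <- function(vehicle, params = energy_params(), window = 3,
                       as_printed = FALSE) {
  stopifnot(nrow(vehicle) >= 4, window %% 2 == 1)
  ord <- order(vehicle$day)
  day <- vehicle$day[ord]
  bw <- vehicle$bw_g[ord]
  half <- (window - 1) / 2
  n <- length(bw)
  ## local linear fit over a symmetric window, shrunk near the ends: robust
  ## to uneven measurement spacing and exact on a linear trend
  bw_s <- bw
  dbw <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    if (h == 0) next                     # endpoints: raw value, slope below
    idx <- (i - h):(i + h)
    cf <- stats::coef(stats::lm(bw[idx] ~ day[idx]))
    bw_s[i] <- cf[1] + cf[2] * day[i]
    dbw[i] <- cf[2]
  }
  dbw[1] <- (bw_s[2] - bw_s[1]) / (day[2] - day[1])
  dbw[n] <- (bw_s[n] - bw_s[n - 1]) / (day[n] - day[n - 1])
  cd <- if (as_printed) {
    params$fat_slope * params$e_lean_kj_g +
      (1 - params$fat_slope) * params$e_fat_kj_g
  } else {
    caloric_density(params)
  }
  comp <- body_composition(bw_s, params)
  fi <- params$rmr_kj_g_day * comp$FFM + dbw * cd
  list(day = day, fi_kj_day = fi, bw_smooth_g = bw_s,
       fi_fun = stats::approxfun(day, fi, rule = 2),
       bw_fun = stats::approxfun(day, bw_s, rule = 2))
}

#' Treated-animal food intake
#'
#' `FI = FI0 * P + FI_control * (BW_control/BW_treatment)^beta * (1 - P)`:
#' under full signaling intake stays at its baseline; without signaling the
#' overfeeding response pushes intake up until the treated group regains the
#' control weight.
#'
#' @param P instantaneous effect in `[0, 1]`
#' @param BW_control,BW_treatment body weights, g
#' @param beta overfeeding exponent
#' @param FI0 baseline (day 0) intake, kJ/day
#' @param FI_control_t control intake at the same time, kJ/day
#' @return intake, kJ/day
#' @export
food_intake <- function(P, BW_control, BW_treatment, beta, FI0,
                        FI_control_t) {
  stopifnot(all(BW_treatment > 0), all(P >= 0 & P <= 1))
  FI0 * P + FI_control_t * (BW_control / BW_treatment)^beta * (1 - P)
}

#' Thermogenesis energy term
#'
#' `dE_FGF21 = -epsilon * P * TAT`: browning of white adipose consumes
#' energy in proportion to the instantaneous effect and the fat mass.
#'
#' @param P instantaneous effect
#' @param TAT total adipose tissue, g
#' @param epsilon maximal rate, kJ/(g TAT day)
#' @return energy flux, kJ/day (non-positive)
#' @export
fgf21_energy <- function(P, TAT, epsilon) {
  stopifnot(all(TAT >= 0))
  -epsilon * P * TAT
}

#' Define a body-weight study
#'
#' @param arms data frame with `label`, `dose_mg_per_kg`, `route`
#' @param dosing_days dosing days (default 0, 7, 14)
#' @param days measurement days
#' @param vehicle data frame with `day`, `bw_g`
#' @param treatment optional data frame with `arm`, `day`, `bw_g`
#' @param bw0 baseline body weight, g
#' @return list of class `bw_study`
#' @export
bw_study <- function(arms, dosing_days = c(0, 7, 14), days, vehicle,
                     treatment = NULL, bw0 = 45) {
  stopifnot(all(c("label", "dose_mg_per_kg", "route") %in% names(arms)),
            all(c("day", "bw_g") %in% names(vehicle)))
  structure(list(arms = arms, dosing_days = dosing_days, days = days,
                 vehicle = vehicle, treatment = treatment, bw0 = bw0),
            class = "bw_study")
}

#' Standard five-arm dosing design
#'
#' 1, 3, 10 mg/kg IV and 1, 10 mg/kg SC, once weekly for three weeks.
#' @return data frame of arms
#' @export
standard_bw_arms <- function() {
  data.frame(label = c("1_IV", "3_IV", "10_IV", "1_SC", "10_SC"),
             dose_mg_per_kg = c(1, 3, 10, 1, 10),
             route = c("IV", "IV", "IV", "SC", "SC"),
             stringsAsFactors = FALSE)
}

## Precompute everything that does not depend on the fitted PD parameters:
## fine time grid (step dt/2), per-arm adipose exposures, control intake and
## control body weight on the grid.
.bw_prep <- function(study, pk_params, energy, dt = 0.05,
                     max_day = max(study$days), ro_step = 0.1) {
  n <- ceiling(max_day / dt)
  fine <- seq(0, n * dt, by = dt / 2)          # length 2n + 1
  ## receptor occupancy is evaluated on a coarser grid (adipose exposure is
  ## continuous and slow) and interpolated onto the integration grid
  ro_grid <- sort(unique(c(seq(0, n * dt, by = ro_step), n * dt)))
  ctrl <- fi_control(study$vehicle, energy)
  exps <- lapply(seq_len(nrow(study$arms)), function(i) {
    p <- pk_params
    p$dose_mg_per_kg <- study$arms$dose_mg_per_kg[i]
    p$route <- study$arms$route[i]
    p$dosing_times_hr <- study$dosing_days * HOURS_PER_DAY
    e <- adipose_exposure(p, ro_grid)
    cbind(I = e$intact_nM, N = e$n_only_nM)
  })
  list(n = n, dt = dt, fine = fine, ro_grid = ro_grid,
       times_day = fine[seq(1, length(fine), by = 2)],
       I = do.call(cbind, lapply(exps, function(e) e[, "I"])),
       N = do.call(cbind, lapply(exps, function(e) e[, "N"])),
       fic = ctrl$fi_fun(fine), bwc = ctrl$bw_fun(fine),
       fi0 = ctrl$fi_fun(0), ctrl = ctrl, arms = study$arms)
}

## Core integrator: given prepared grids and PD parameters, return the BW
## matrix (time x arm) on the step grid plus diagnostics.
.bw_engine <- function(prep, binding, energy, bw0) {
  n_arm <- nrow(prep$arms)
  RO_coarse <- matrix(receptor_occupancy(as.numeric(prep$I),
                                         as.numeric(prep$N), binding),
                      nrow = nrow(prep$I), ncol = n_arm)
  RO <- vapply(seq_len(n_arm), function(j) {
    stats::approx(prep$ro_grid, RO_coarse[, j], xout = prep$fine)$y
  }, numeric(length(prep$fine)))
  RO <- pmin(pmax(RO, 0), 1)
  P <- transfer_P(RO, energy$rho, energy$delta)
  fs <- energy$fat_slope; fi_g <- energy$fat_intercept_g
  rmr <- energy$rmr_kj_g_day; beta <- energy$beta
  eps <- energy$epsilon_kj_g_day
  cd <- caloric_density(energy)
  fi0 <- prep$fi0
  fic <- prep$fic; bwc <- prep$bwc
  floor_bw <- fi_g / fs
  n <- prep$n; dt <- prep$dt
  bw <- matrix(NA_real_, n + 1, n_arm)
  de <- matrix(NA_real_, n + 1, n_arm)
  w <- rep(bw0, n_arm)
  bw[1, ] <- w
  deriv <- function(wv, i) {
    TAT <- fs * wv - fi_g
    FFM <- wv - TAT
    Pv <- P[i, ]
    FI <- fi0 * Pv + fic[i] * (bwc[i] / wv)^beta * (1 - Pv)
    FI - rmr * FFM - eps * Pv * TAT                 # dE, kJ/day
  }
  de[1, ] <- deriv(w, 1)
  for (k in seq_len(n)) {
    i0 <- 2 * k - 1                                  # index of t_{k-1}
    k1 <- deriv(w, i0) / cd
    k2 <- deriv(w + dt / 2 * k1, i0 + 1) / cd
    k3 <- deriv(w + dt / 2 * k2, i0 + 1) / cd
    k4 <- deriv(w + dt * k3, i0 + 2) / cd
    w <- w + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(w <= floor_bw)) {
      stop(sprintf("body weight crossed the composition floor (%.1f g) at day %.2f",
                   floor_bw, k * dt))
    }
    bw[k + 1, ] <- w
    de[k + 1, ] <- deriv(w, i0 + 2)
  }
  step_idx <- seq(1, length(prep$fine), by = 2)
  list(times_day = prep$times_day, bw = bw, dE = de,
       control_bw = bwc[step_idx],
       RO = RO[step_idx, , drop = FALSE], P = P[step_idx, , drop = FALSE])
}

#' Simulate body-weight trajectories for all study arms
#'
#' Runs the DIO tissue PK model for every arm, converts adipose exposure to
#' receptor occupancy and the transfer effect P(t), and integrates the
#' energy-balance ODE with a fixed-step 4th-order Runge-Kutta scheme.
#'
#' @param study a [bw_study()]
#' @param pk_params a [dio_pk_params()] template (dose/route/schedule set per
#'   arm)
#' @param binding a [binding_params()]
#' @param energy an [energy_params()]
#' @param dt integration step, days
#' @return object of class `bw_simulation`: `times_day`, `bw` (time x arm,
#'   g), `control_bw`, `dE`, `RO`, `P`, `arms`
#' @export
simulate_bw <- function(study, pk_params = dio_pk_params(),
                        binding = binding_params(),
                        energy = energy_params(), dt = 0.05) {
  prep <- .bw_prep(study, pk_params, energy, dt = dt)
  out <- .bw_engine(prep, binding, energy, study$bw0)
  out$arms <- study$arms
  class(out) <- "bw_simulation"
  out
}

#' Per-arm nadir and washout summary of a simulation
#'
#' @param sim a `bw_simulation`
#' @return data frame with per-arm nadir day, nadir gap to control (g),
#'   percent change from baseline at nadir, and the final gap
#' @export
bw_nadir <- function(sim) {
  gap <- sim$bw - sim$control_bw
  data.frame(
    arm = sim$arms$label,
    nadir_day = sim$times_day[apply(gap, 2, which.min)],
    nadir_gap_g = apply(gap, 2, min),
    nadir_pct = 100 * (apply(sim$bw, 2, min) - sim$bw[1, ]) / sim$bw[1, ],
    final_gap_g = gap[nrow(gap), ],
    stringsAsFactors = FALSE)
}

#' Fit the body-weight model to all arms simultaneously
#'
#' Minimizes `sum(((model - data)/data)^2)` over the five PD parameters
#' `(K_D_N, beta, delta, rho, epsilon)` across every arm at once, with
#' multi-start Nelder-Mead simplex on transformed parameters (log scales;
#' logit for `delta`).  Box bounds K_D_N in [1, 500] nM, beta in [0, 10],
#' delta in (0, 1], rho in [0.5, 10], epsilon >= 0 are enforced by penalty.
#'
#' @param study a [bw_study()] with `treatment` data for every arm
#' @param pk_params a [dio_pk_params()] template
#' @param energy an [energy_params()] carrying the fixed physiology
#' @param binding_template a [binding_params()]; its `K_D_N` is replaced by
#'   the fitted value
#' @param starts matrix of starts, columns `K_D_N`, `beta`, `delta`, `rho`,
#'   `epsilon`
#' @param dt integration step, days
#' @param maxit iteration cap per Nelder-Mead start
#' @param n_polish extra restarts from the running best point
#' @return list with fitted `binding`, `energy`, `estimates`, `objective`,
#'   `convergence`, `starts` diagnostics
#' @export
fit_bw <- function(study, pk_params = dio_pk_params(),
                   energy = energy_params(),
                   binding_template = binding_params(),
                   starts = NULL, dt = 0.05, maxit = 500, n_polish = 4) {
  stopifnot(!is.null(study$treatment))
  if (is.null(starts)) {
    starts <- rbind(c(10, 1, 0.30, 1.5, 0.3),
                    c(80, 3, 0.15, 3.0, 1.0),
                    c(30, 1.5, 0.50, 1.0, 0.15))
    colnames(starts) <- c("K_D_N", "beta", "delta", "rho", "epsilon")
  }
  prep <- .bw_prep(study, pk_params, energy, dt = dt)
  dat <- split(study$treatment, study$treatment$arm)
  arm_labels <- prep$arms$label
  lower <- c(1, 0, 1e-4, 0.5, 1e-6)
  upper <- c(500, 10, 1, 10, 50)
  to_theta <- function(p) c(log(p[1]), log(max(p[2], 1e-6)),
                            stats::qlogis(p[3]), log(p[4]), log(p[5]))
  from_theta <- function(th) c(exp(th[1]), exp(th[2]),
                               stats::plogis(th[3]), exp(th[4]), exp(th[5]))
  objective <- function(theta) {
    p <- from_theta(theta)
    pen <- sum(pmax(lower - p, 0)^2 + pmax(p - upper, 0)^2)
    p <- pmin(pmax(p, lower), upper)
    b <- binding_template
    b$K_D_N <- p[1]
    e <- energy
    e$beta <- p[2]; e$delta <- p[3]; e$rho <- p[4]
    e$epsilon_kj_g_day <- p[5]
    sim <- tryCatch(.bw_engine(prep, b, e, study$bw0),
                    error = function(err) NULL)
    if (is.null(sim)) return(1e8)
    obj <- 0
    for (j in seq_along(arm_labels)) {
      d <- dat[[arm_labels[j]]]
      if (is.null(d)) next
      m <- stats::approx(sim$times_day, sim$bw[, j], xout = d$day)$y
      obj <- obj + sum(((m - d$bw_g) / d$bw_g)^2)
    }
    obj + 1e4 * pen
  }
  best <- NULL
  trace <- list()
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(to_theta(as.numeric(starts[i, ])), objective,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    trace[[i]] <- c(from_theta(fit$par), objective = fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  for (i in seq_len(n_polish)) {
    if (best$value < 1e-11) break
    nxt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-13))
    if (nxt$value >= best$value - 1e-15) {
      best <- if (nxt$value < best$value) nxt else best
      break
    }
    best <- nxt
  }
  p <- from_theta(best$par)
  names(p) <- c("K_D_N", "beta", "delta", "rho", "epsilon")
  b <- binding_template
  b$K_D_N <- p[1]
  e <- energy
  e$beta <- p[2]; e$delta <- p[3]; e$rho <- p[4]; e$epsilon_kj_g_day <- p[5]
  list(binding = b, energy = e, estimates = p, objective = best$value,
       convergence = best$convergence,
       starts = do.call(rbind, trace))
}
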