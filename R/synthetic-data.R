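## Seeded generators emulating the statistical structure of the animal
## studies: biexponential-like concentration profiles at the study sampling
## grids with log-normal residual error and LLOQ censoring, OGTT day/dose
## effect tables from the convolution model with additive noise, and
## vehicle + five-arm body-weight trajectories from the energy-balance model
## with known ground truth.

#' Generator specification
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical output
#' @param n_subjects subjects per group
#' @param noise_cv residual coefficient of variation (fraction)
#' @return list of class `generator_spec`
#' @export
generator_spec <- function(seed = 1L, n_subjects = 4L, noise_cv = 0.1) {
  stopifnot(is.numeric(seed), noise_cv >= 0, n_subjects >= 1)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 noise_cv = noise_cv),
            class = "generator_spec")
}

#' Study sampling grids (hours)
#'
#' The post-dose plasma sampling times used in each mouse model and route.
#' @param model `"obob"` or `"dio"`
#' @param route `"IV"` or `"SC"`
#' @return numeric vector of hours
#' @export
pk_sampling_times <- function(model = c("obob", "dio"),
                              route = c("IV", "SC")) {
  model <- match.arg(model)
  route <- match.arg(route)
  switch(paste(model, route),
         "dio IV" = c(0.25, 1, 2, 6, 24, 48, 72),
         "dio SC" = c(4, 6, 8, 24, 48, 72),
         "obob IV" = c(0.083, 1, 4, 8, 12, 24),
         "obob SC" = c(2, 4, 6, 8, 12, 24))
}

## Mean-1 multiplicative log-normal noise factors.
.lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate a synthetic concentration-time dataset
#'
#' Simulates the chosen PK model at the truth parameters, samples the CT and
#' NT assay observables at the study grid, applies multiplicative log-normal
#' noise, and censors at the assay LLOQ (0.2 ug/ml).
#'
#' @param spec a [generator_spec()]
#' @param model `"obob"` (cleavage network) or `"dio"` (tissue model)
#' @param route `"IV"` or `"SC"`
#' @param dose_mg_per_kg dose
#' @param truth model parameters; default [clip_pk_params()] or
#'   [dio_pk_params()] at the study values
#' @param times_hr sampling grid; default the study grid for (model, route)
#' @param lloq LLOQ in ug/ml
#' @return list of [conc_profile()] objects (one per subject and analyte)
#' @export
gen_pk_dataset <- function(spec, model = c("obob", "dio"),
                           route = c("IV", "SC"), dose_mg_per_kg = 10,
                           truth = NULL, times_hr = NULL, lloq = 0.2) {
  model <- match.arg(model)
  route <- match.arg(route)
  set.seed(spec$seed)
  if (is.null(times_hr)) times_hr <- pk_sampling_times(model, route)
  if (model == "obob") {
    if (is.null(truth)) truth <- clip_pk_params()
    truth$route <- route
    truth$dose_mg_per_kg <- dose_mg_per_kg
    traj <- simulate_clipping(truth, c(0, times_hr))
    obs <- pool_observables(traj, units = "ug_per_ml")
    ct <- obs$ct_signal[-1]
    nt <- obs$nt_signal[-1]
    bw_g <- truth$body_weight_g
  } else {
    if (is.null(truth)) truth <- dio_pk_params()
    truth$route <- route
    truth$dose_mg_per_kg <- dose_mg_per_kg
    truth$dosing_times_hr <- 0
    traj <- simulate_dio(truth, c(0, times_hr))
    mw <- truth$mw_g_per_mol
    ct <- nM_to_ug_per_ml(.dio_observable_conc(traj, "ct_signal", "central"),
                          mw)[-1]
    nt <- nM_to_ug_per_ml(.dio_observable_conc(traj, "nt_signal", "central"),
                          mw)[-1]
    bw_g <- truth$body_weight_g
  }
  profiles <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (analyte in c("intact_CT", "intact_NT")) {
      mu <- if (analyte == "intact_CT") ct else nt
      conc <- mu * .lognormal_factors(length(mu), spec$noise_cv)
      blq <- conc < lloq
      profiles[[length(profiles) + 1]] <-
        conc_profile(subject_id = sprintf("%s_%s_s%02d", model, route, s),
                     analyte = analyte, route = route,
                     dose_mg_per_kg = dose_mg_per_kg, body_weight_g = bw_g,
                     times_hr = times_hr, conc_ug_per_ml = conc,
                     blq = blq, lloq = lloq)
    }
  }
  attr(profiles, "truth") <- truth
  profiles
}

#' Generate a synthetic OGTT effect table
#'
#' Model-predicted glucose dAUC effects at the design points plus additive
#' Gaussian noise with `sd = noise_cv * effect`.
#'
#' @param spec a [generator_spec()]
#' @param truth an [ogtt_pd_params()] with `A` set (amplitude ground truth)
#' @param design data frame with `day`, `dose_mg_per_kg`, `route`; default
#'   days 3-6 at 3 and 10 mg/kg SC (the fitting design)
#' @param exposures optional precomputed [ogtt_reference_exposure()] list
#'   (by route); computed if missing
#' @return data frame with `day`, `dose_mg_per_kg`, `route`, `effect`, `se`,
#'   with the truth attached as an attribute
#' @export
gen_ogtt_dataset <- function(spec, truth = ogtt_pd_params(A = 100),
                             design = expand.grid(
                               day = 3:6, dose_mg_per_kg = c(3, 10),
                               route = "SC", stringsAsFactors = FALSE),
                             exposures = NULL) {
  stopifnot(!is.na(truth$A))
  set.seed(spec$seed)
  if (is.null(exposures)) {
    exposures <- lapply(stats::setNames(nm = unique(design$route)),
                        ogtt_reference_exposure, max_day = max(design$day))
  }
  mu <- predict_ogtt(design, exposures, truth)
  sds <- spec$noise_cv * abs(mu)
  out <- design
  out$effect <- mu + stats::rnorm(length(mu), 0, sds)
  out$se <- sds
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic body-weight study
#'
#' Vehicle body weight follows a slow linear drift; the treated arms come
#' from [simulate_bw()] at the truth parameters.  Multiplicative log-normal
#' noise is applied to every measured weight.
#'
#' @param spec a [generator_spec()] (body-weight noise is typically small,
#'   e.g. `noise_cv = 0.01`)
#' @param binding,energy ground-truth [binding_params()] / [energy_params()]
#' @param pk_params a [dio_pk_params()] template
#' @param arms arm table, default [standard_bw_arms()]
#' @param days measurement days (twice weekly to day 57)
#' @param bw0 baseline weight, g
#' @param drift_g_day vehicle drift, g/day
#' @return a [bw_study()] with `treatment` filled in and the truth attached
#'   as attributes
#' @export
gen_bw_study <- function(spec, binding = binding_params(),
                         energy = energy_params(),
                         pk_params = dio_pk_params(),
                         arms = standard_bw_arms(),
                         days = c(0, 4, 7, 11, 14, 18, 21, 25, 28, 32, 35,
                                  39, 42, 46, 49, 53, 57),
                         bw0 = 45, drift_g_day = 0.05) {
  set.seed(spec$seed)
  vehicle_clean <- data.frame(day = days, bw_g = bw0 + drift_g_day * days)
  study <- bw_study(arms = arms, days = days, vehicle = vehicle_clean,
                    bw0 = bw0)
  sim <- simulate_bw(study, pk_params, binding, energy)
  treat <- do.call(rbind, lapply(seq_len(nrow(arms)), function(j) {
    mu <- stats::approx(sim$times_day, sim$bw[, j], xout = days)$y
    data.frame(arm = arms$label[j], day = days,
               bw_g = mu * .lognormal_factors(length(days), spec$noise_cv),
               stringsAsFactors = FALSE)
  }))
  vehicle <- vehicle_clean
  vehicle$bw_g <- vehicle$bw_g * .lognormal_factors(length(days),
                                                    spec$noise_cv)
  out <- bw_study(arms = arms, days = days, vehicle = vehicle,
                  treatment = treat, bw0 = bw0)
  attr(out, "truth") <- list(binding = binding, energy = energy,
                             pk_params = pk_params)
  attr(out, "clean_sim") <- sim
  out
}
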