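# Shared fixtures, built in code.

# Noiseless single-exponential IV profile sampled at given times.
exp_profile <- function(c0, k, times, dose = 10, route = "IV",
                        analyte = "intact_NT", lloq = 1e-9) {
  conc_profile(subject_id = "fx", analyte = analyte, route = route,
               dose_mg_per_kg = dose, body_weight_g = 45,
               times_hr = times, conc_ug_per_ml = c0 * exp(-k * times),
               blq = rep(FALSE, length(times)), lloq = lloq)
}

# Cached OGTT reference exposures (expensive enough to share across tests).
ogtt_exps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(SC = ogtt_reference_exposure("SC", max_day = 6),
                     IV = ogtt_reference_exposure("IV", max_day = 6))
    }
    cache
  }
})

# Linear-drift vehicle on the study measurement grid.
study_days <- c(0, 4, 7, 11, 14, 18, 21, 25, 28, 32, 35, 39, 42, 46, 49,
                53, 57)
linear_vehicle <- function(bw0 = 45, drift = 0.05, days = study_days) {
  data.frame(day = days, bw_g = bw0 + drift * days)
}

# Sum of squared data-normalized residuals of a BW simulation vs study data.
bw_objective <- function(study, binding, energy) {
  sim <- simulate_bw(study, binding = binding, energy = energy)
  obj <- 0
  for (j in seq_len(nrow(study$arms))) {
    d <- study$treatment[study$treatment$arm == study$arms$label[j], ]
    m <- approx(sim$times_day, sim$bw[, j], xout = d$day)$y
    obj <- obj + sum(((m - d$bw_g) / d$bw_g)^2)
  }
  obj
}
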