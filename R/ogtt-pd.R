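## OGTT pharmacodynamics: instantaneous signaling S(t) from the intact and
## N-only pools (hyperbolic, central-compartment concentrations), convolved
## with an exponential effect-persistence kernel of time constant gamma.
## The amplitude A is anchored to one observation, never fitted.

#' OGTT PD parameters
#'
#' @param K_I half-maximal concentration of the intact pool, nM (in vitro
#'   pERK EC50; fixed, not fitted)
#' @param K_N half-maximal concentration of the N-only pool, nM (fitted)
#' @param gamma effect-persistence time constant, days (fitted)
#' @param A amplitude, effect units per unit of convolved signal (anchored)
#' @return list of class `ogtt_pd_params`
#' @export
ogtt_pd_params <- function(K_I = 0.5, K_N = 22, gamma = 3, A = NA_real_) {
  stopifnot(K_I > 0, K_N > 0, gamma > 0)
  structure(list(K_I = K_I, K_N = K_N, gamma = gamma, A = A),
            class = "ogtt_pd_params")
}

#' Instantaneous signaling from the intact and N-only pools
#'
#' `S = (I/K_I + N/K_N) / (1 + I/K_I + N/K_N)`, a hyperbolic efficacy in
#' `[0, 1)` shared by both pools (equal Emax).
#'
#' @param I,N intact and N-only concentrations, nM (vectors)
#' @param params an [ogtt_pd_params()]
#' @return signaling in `[0, 1)`
#' @export
instantaneous_signaling <- function(I, N, params) {
  if (any(I < 0) || any(N < 0)) stop("concentrations must be >= 0")
  x <- I / params$K_I + N / params$K_N
  x / (1 + x)
}

## Trapezoidal cumulative integral of w on a uniform grid.
.cumtrapz <- function(x, y) {
  c(0, cumsum((utils::head(y, -1) + utils::tail(y, -1)) / 2 * diff(x)))
}

#' Convolve a signaling time course with the persistence kernel
#'
#' `OGTT(t) = A * integral_0^t S(tau) exp(-(t - tau)/gamma) dtau`, evaluated
#' by trapezoidal quadrature on a uniform grid with step at most `step` days.
#'
#' @param S data frame with columns `time_day` and `S`, covering `[0,
#'   max(t_obs)]` (linearly interpolated onto the quadrature grid)
#' @param gamma persistence time constant, days
#' @param A amplitude
#' @param t_obs observation times, days (vector)
#' @param step quadrature step, days
#' @return effect at each `t_obs`
#' @export
convolve_effect <- function(S, gamma, A = 1, t_obs, step = 0.01) {
  stopifnot(gamma > 0, step <= 0.01 + 1e-12, all(t_obs >= 0))
  if (min(S$time_day) > 0 || max(S$time_day) < max(t_obs)) {
    stop("S must be defined on [0, max(t_obs)]")
  }
  if (any(!is.finite(S$S))) stop("S contains non-finite values")
  grid <- seq(0, max(t_obs), by = step)
  if (grid[length(grid)] < max(t_obs)) grid <- c(grid, max(t_obs))
  s <- stats::approx(S$time_day, S$S, xout = grid)$y
  cum <- .cumtrapz(grid, exp(grid / gamma) * s)
  A * exp(-t_obs / gamma) * stats::approx(grid, cum, xout = t_obs)$y
}

#' Central-compartment exposure per unit dose for the OGTT model
#'
#' Runs the ob/ob cleavage-network PK model at a 1 mg/kg reference dose and
#' returns intact and N-only central concentrations on a fine day grid.
#' The PK is linear, so any dose is obtained by scaling.
#'
#' @param route `"IV"` or `"SC"`
#' @param max_day last day needed
#' @param clip_params base [clip_pk_params()] (dose and route overridden)
#' @param step_day grid step, days
#' @return data frame `time_day`, `intact_nM`, `n_only_nM` (per mg/kg)
#' @export
ogtt_reference_exposure <- function(route, max_day = 7,
                                    clip_params = clip_pk_params(),
                                    step_day = 0.01) {
  p <- clip_params
  p$dose_mg_per_kg <- 1
  p$route <- route
  times_day <- seq(0, max_day, by = step_day)
  traj <- simulate_clipping(p, times_day * HOURS_PER_DAY)
  obs <- pool_observables(traj, units = "nM")
  ## clamp solver noise at the nonnegativity boundary
  data.frame(time_day = times_day, intact_nM = pmax(obs$intact_pool, 0),
             n_only_nM = pmax(obs$n_only_pool, 0))
}

## Unnormalized (A = 1) predictions for a design, given per-route reference
## exposures.  design: data.frame(day, dose_mg_per_kg, route).
.ogtt_unnorm <- function(design, exposures, params, pool = c("both", "n_only")) {
  pool <- match.arg(pool)
  out <- numeric(nrow(design))
  combos <- unique(design[, c("dose_mg_per_kg", "route")])
  for (k in seq_len(nrow(combos))) {
    dose <- combos$dose_mg_per_kg[k]
    route <- combos$route[k]
    ref <- exposures[[route]]
    if (is.null(ref)) stop("no reference exposure for route ", route)
    I <- dose * ref$intact_nM
    N <- dose * ref$n_only_nM
    S_all <- instantaneous_signaling(I, N, params)
    S <- if (pool == "both") S_all else {
      ## N-only share of the shared hyperbolic response
      share <- ifelse(I + N > 0, (N / params$K_N) /
                        pmax(I / params$K_I + N / params$K_N, 1e-300), 0)
      S_all * share
    }
    rows <- which(design$dose_mg_per_kg == dose & design$route == route)
    out[rows] <- convolve_effect(data.frame(time_day = ref$time_day, S = S),
                                 gamma = params$gamma,
                                 t_obs = design$day[rows])
  }
  out
}

#' Anchor the amplitude A to one observation
#'
#' `A = observed effect at the anchor / unnormalized prediction at the
#' anchor`; A is then fixed for every other point.
#'
#' @param unnorm_pred unnormalized predictions, one per observation row
#' @param observations data frame with `day`, `dose_mg_per_kg`, `route`,
#'   `effect`
#' @param anchor list with `day`, `dose_mg_per_kg`, `route`
#' @return the amplitude A
#' @export
anchor_normalization <- function(unnorm_pred, observations, anchor) {
  hit <- which(observations$day == anchor$day &
                 observations$dose_mg_per_kg == anchor$dose_mg_per_kg &
                 observations$route == anchor$route)
  if (length(hit) != 1) {
    stop("anchor point (day ", anchor$day, ", ", anchor$dose_mg_per_kg,
         " mg/kg, ", anchor$route, ") must match exactly one observation")
  }
  if (unnorm_pred[hit] == 0) stop("unnormalized prediction at anchor is zero")
  observations$effect[hit] / unnorm_pred[hit]
}

#' Predict OGTT effects for a design
#'
#' @param design data frame with `day`, `dose_mg_per_kg`, `route`
#' @param exposures named list (by route) of [ogtt_reference_exposure()]
#' @param params an [ogtt_pd_params()] with `A` set
#' @return vector of effects
#' @export
predict_ogtt <- function(design, exposures, params) {
  if (is.na(params$A)) stop("params$A is not set; anchor it first")
  params$A * .ogtt_unnorm(design, exposures, params)
}

#' Fraction of the OGTT effect attributable to the N-only pool
#'
#' Two attribution conventions are offered.  `"counterfactual"` (default)
#' answers "what fraction of the effect would remain with the N-only pool
#' alone": the convolved effect computed with the intact pool removed,
#' divided by the full effect.  `"share"` decomposes the shared hyperbolic
#' signal S into intact and N-only summands at every instant and convolves
#' the N-only summand; shares sum to one but charge part of the saturation
#' suppression to each pool.
#'
#' @param day observation day
#' @param dose_mg_per_kg,route dose and route
#' @param exposures named list of reference exposures
#' @param params an [ogtt_pd_params()]
#' @param method `"counterfactual"` or `"share"`
#' @return fraction in `[0, 1]`
#' @export
ogtt_n_only_fraction <- function(day, dose_mg_per_kg, route, exposures,
                                 params,
                                 method = c("counterfactual", "share")) {
  method <- match.arg(method)
  design <- data.frame(day = day, dose_mg_per_kg = dose_mg_per_kg,
                       route = route)
  total <- .ogtt_unnorm(design, exposures, params, pool = "both")
  if (method == "share") {
    return(.ogtt_unnorm(design, exposures, params, pool = "n_only") / total)
  }
  ref <- exposures[[route]]
  S_n <- instantaneous_signaling(rep(0, nrow(ref)),
                                 dose_mg_per_kg * ref$n_only_nM, params)
  n_alone <- convolve_effect(data.frame(time_day = ref$time_day, S = S_n),
                             gamma = params$gamma, t_obs = day)
  n_alone / total
}

#' Fit the OGTT PD model
#'
#' Minimizes the data-normalized sum of squared residuals
#' `sum(((model - data)/data)^2)` over `(K_N, gamma)` with the amplitude A
#' re-anchored at every evaluation.  Derivative-free Nelder-Mead simplex on
#' log parameters from several log-spaced starts.
#'
#' @param data data frame with `day`, `dose_mg_per_kg`, `route`, `effect`
#' @param exposures named list (by route) of [ogtt_reference_exposure()]
#' @param K_I fixed intact-pool potency, nM
#' @param anchor anchor point, default day 3 / 10 mg/kg / SC
#' @param starts matrix of starting values (columns `K_N`, `gamma`); default
#'   four log-spaced starts over K_N in [1, 100] nM, gamma in [0.5, 10] days
#' @param maxit Nelder-Mead iteration cap per start
#' @return list with `params` (fitted [ogtt_pd_params()]), `objective`,
#'   `convergence`, `starts` diagnostics
#' @export
fit_ogtt <- function(data, exposures, K_I = 0.5,
                     anchor = list(day = 3, dose_mg_per_kg = 10,
                                   route = "SC"),
                     starts = NULL, maxit = 400) {
  stopifnot(nrow(data) >= 4, all(data$effect != 0))
  if (is.null(starts)) {
    starts <- cbind(K_N = exp(seq(log(1), log(100), length.out = 4)),
                    gamma = exp(seq(log(0.5), log(10), length.out = 4)))
  }
  objective <- function(theta) {
    par <- ogtt_pd_params(K_I = K_I, K_N = exp(theta[1]),
                          gamma = exp(theta[2]))
    unnorm <- .ogtt_unnorm(data, exposures, par)
    A <- anchor_normalization(unnorm, data, anchor)
    pred <- A * unnorm
    sum(((pred - data$effect) / data$effect)^2)
  }
  best <- NULL
  trace <- list()
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(log(as.numeric(starts[i, ])), objective,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    trace[[i]] <- c(K_N = exp(fit$par[1]), gamma = exp(fit$par[2]),
                    objective = fit$value, convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ## polish from the pooled best point
  best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-14))
  par <- ogtt_pd_params(K_I = K_I, K_N = exp(best$par[1]),
                        gamma = exp(best$par[2]))
  unnorm <- .ogtt_unnorm(data, exposures, par)
  par$A <- anchor_normalization(unnorm, data, anchor)
  list(params = par, objective = best$value,
       convergence = best$convergence,
       starts = do.call(rbind, trace))
}
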