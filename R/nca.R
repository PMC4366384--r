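## Non-compartmental analysis: linear-up/log-down trapezoidal AUC/AUMC,
## terminal-phase regression, and the standard derived parameters
## (CL = dose/AUC0-inf, t1/2 = ln2/lambda_z, Vc, Vss, F).

#' Construct a concentration-time profile
#'
#' One analyte/route/dose concentration-time series for a single subject,
#' with below-limit-of-quantitation (BLQ) annotations.  This is the input
#' object for all NCA operations.
#'
#' @param subject_id subject identifier
#' @param analyte `"intact_CT"` or `"intact_NT"` (assay observable)
#' @param route `"IV"` or `"SC"`
#' @param dose_mg_per_kg dose in mg/kg
#' @param body_weight_g body weight in grams
#' @param times_hr sampling times in hours, strictly increasing
#' @param conc_ug_per_ml concentrations in ug/ml; BLQ samples may carry any
#'   value (they are masked by `blq`)
#' @param blq logical vector flagging below-LLOQ samples; by default samples
#'   with concentration `< lloq` are flagged
#' @param lloq lower limit of quantitation in ug/ml (assay default 0.2,
#'   i.e. 200 ng/ml)
#' @return an object of class `conc_profile`
#' @export
conc_profile <- function(subject_id, analyte = c("intact_NT", "intact_CT"),
                         route = c("IV", "SC"), dose_mg_per_kg,
                         body_weight_g = NA_real_,
                         times_hr, conc_ug_per_ml,
                         blq = conc_ug_per_ml < lloq, lloq = 0.2) {
  analyte <- match.arg(analyte)
  route <- match.arg(route)
  stopifnot(is.numeric(times_hr), is.numeric(conc_ug_per_ml),
            length(times_hr) == length(conc_ug_per_ml),
            length(blq) == length(times_hr),
            is.numeric(dose_mg_per_kg), dose_mg_per_kg > 0, lloq > 0)
  if (any(diff(times_hr) <= 0)) {
    stop("times must be strictly increasing for subject ", subject_id)
  }
  if (any(conc_ug_per_ml[!blq] < 0)) {
    stop("negative quantifiable concentration in profile for subject ",
         subject_id)
  }
  structure(list(subject_id = subject_id, analyte = analyte, route = route,
                 dose_mg_per_kg = dose_mg_per_kg,
                 body_weight_g = body_weight_g,
                 times_hr = as.numeric(times_hr),
                 conc_ug_per_ml = as.numeric(conc_ug_per_ml),
                 blq = as.logical(blq), lloq = lloq),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> subject %s, %s, %s %g mg/kg, %d samples (%d BLQ)\n",
              x$subject_id, x$analyte, x$route, x$dose_mg_per_kg,
              length(x$times_hr), sum(x$blq)))
  invisible(x)
}

## Quantifiable (time, conc) pairs with the BLQ policy applied:
## pre-dose/leading BLQ counted as zero concentration, later BLQ dropped.
.quantifiable <- function(profile) {
  t <- profile$times_hr
  c <- profile$conc_ug_per_ml
  blq <- profile$blq
  first_q <- match(FALSE, blq)
  if (is.na(first_q)) return(list(t = numeric(0), c = numeric(0)))
  keep_zero <- blq & seq_along(t) < first_q
  keep <- !blq | keep_zero
  c2 <- ifelse(blq, 0, c)
  list(t = t[keep], c = c2[keep])
}

## One linear-up/log-down trapezoid: returns c(auc, aumc) for one segment.
.segment_auc_aumc <- function(t1, t2, c1, c2) {
  dt <- t2 - t1
  if (c2 < c1 && c1 > 0 && c2 > 0) {
    k <- log(c1 / c2) / dt
    auc <- (c1 - c2) / k
    aumc <- (t1 * c1 - t2 * c2) / k + (c1 - c2) / k^2
  } else {
    auc <- dt * (c1 + c2) / 2
    aumc <- dt * (t1 * c1 + t2 * c2) / 2
  }
  c(auc, aumc)
}

#' Area under a concentration-time curve (linear-up/log-down)
#'
#' Linear trapezoid on non-decreasing segments, logarithmic trapezoid on
#' strictly decreasing positive segments.  The log rule is exact on
#' exponential segments sampled at their knots.  A segment touching a zero
#' concentration falls back to the linear rule.
#'
#' @param profile a [conc_profile()]
#' @param t_end upper limit in hours (default: last quantifiable time).  If
#'   `t_end` falls between samples the final partial segment is cut by the
#'   same rule (log interpolation on decreasing positive segments).
#' @return AUC(0-t_end) in ug*h/ml
#' @export
auc_log_linear <- function(profile, t_end = NULL) {
  q <- .quantifiable(profile)
  if (is.null(t_end)) t_end <- max(q$t)
  use <- q$t <= t_end
  if (sum(use) < 2) stop("need at least 2 quantifiable points at or before t_end")
  t <- q$t[use]; c <- q$c[use]
  auc <- 0
  for (i in seq_len(length(t) - 1)) {
    auc <- auc + .segment_auc_aumc(t[i], t[i + 1], c[i], c[i + 1])[1]
  }
  ## partial final segment if t_end lies inside the next sampled interval
  i_last <- length(t)
  if (t[i_last] < t_end && i_last < length(q$t)) {
    t1 <- q$t[i_last]; t2 <- q$t[i_last + 1]
    c1 <- q$c[i_last]; c2 <- q$c[i_last + 1]
    if (c2 < c1 && c1 > 0 && c2 > 0) {
      k <- log(c1 / c2) / (t2 - t1)
      c_end <- c1 * exp(-k * (t_end - t1))
    } else {
      c_end <- c1 + (c2 - c1) * (t_end - t1) / (t2 - t1)
    }
    auc <- auc + .segment_auc_aumc(t1, t_end, c1, c_end)[1]
  }
  auc
}

## AUMC(0-tlast) with the same segment dialect.
.aumc_log_linear <- function(profile) {
  q <- .quantifiable(profile)
  t <- q$t; c <- q$c
  aumc <- 0
  for (i in seq_len(length(t) - 1)) {
    aumc <- aumc + .segment_auc_aumc(t[i], t[i + 1], c[i], c[i + 1])[2]
  }
  aumc
}

#' Terminal-phase regression
#'
#' Least-squares regression of log concentration on time over the last
#' `n_points` quantifiable positive observations.  `lambda_z` is the negative
#' slope; `t_half = ln(2)/lambda_z`.
#'
#' @param profile a [conc_profile()]
#' @param n_points number of terminal points (default 3)
#' @param r2_warn warn when the regression R^2 falls below this value
#' @return list with `lambda_z` (1/hr), `t_half` (hr), `r_squared`,
#'   `n_points`, `intercept` (log ug/ml at t = 0)
#' @export
terminal_phase <- function(profile, n_points = 3, r2_warn = 0.80) {
  q <- .quantifiable(profile)
  pos <- q$c > 0
  t <- q$t[pos]; c <- q$c[pos]
  if (length(t) < n_points || n_points < 3) {
    stop("terminal-phase estimation needs at least 3 quantifiable positive points")
  }
  idx <- seq(length(t) - n_points + 1, length(t))
  fit <- stats::lm(log(c[idx]) ~ t[idx])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop("terminal phase is not declining (slope = ", signif(slope, 3),
         "); cannot estimate lambda_z")
  }
  y <- log(c[idx])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst < 1e-14) 1 else 1 - sum(stats::resid(fit)^2) / sst
  if (is.finite(r2) && r2 < r2_warn) {
    warning(sprintf("terminal regression R^2 = %.3f below %.2f", r2, r2_warn))
  }
  list(lambda_z = -slope, t_half = LN2 / (-slope), r_squared = r2,
       n_points = n_points, intercept = unname(stats::coef(fit)[1]))
}

#' Distribution volumes for an IV profile
#'
#' `Vc = dose / C(0)` with `C(0)` back-extrapolated from the first-phase
#' log-linear fit; `Vss = CL * MRT` with `MRT = AUMC(0-inf)/AUC(0-inf)`.
#' Both are defined for IV administration only.
#'
#' @param profile an IV [conc_profile()]
#' @param n_terminal terminal points for `lambda_z`
#' @param n_first points used for the C(0) back-extrapolation (default 2)
#' @return list with `v_c` and `v_ss` in ml/kg
#' @export
nca_volumes <- function(profile, n_terminal = 3, n_first = 2) {
  if (profile$route != "IV") {
    stop("not applicable: Vc and Vss are defined for IV profiles only")
  }
  s <- nca_summary(profile, n_terminal = n_terminal, n_first = n_first)
  list(v_c = s$v_c, v_ss = s$v_ss)
}

#' Non-compartmental parameter summary for one profile
#'
#' Computes Cmax/Tmax, AUC(0-t), AUC(0-inf) = AUC(0-t) + Clast/lambda_z,
#' lambda_z and t1/2, CL = dose/AUC(0-inf) in ml/h/kg, and (IV only) Vc and
#' Vss.  Doses are converted to ug/kg internally so that CL carries no hidden
#' unit factor.
#'
#' @param profile a [conc_profile()]
#' @param n_terminal number of terminal points for `lambda_z`
#' @param n_first points for the IV C(0) back-extrapolation
#' @return list of class `nca_result`
#' @export
nca_summary <- function(profile, n_terminal = 3, n_first = 2) {
  q <- .quantifiable(profile)
  if (length(q$t) < 3) stop("profile too short for NCA")
  cmax <- max(q$c)
  tmax <- q$t[which.max(q$c)]
  auc_t <- auc_log_linear(profile)
  term <- terminal_phase(profile, n_points = n_terminal)
  c_last <- q$c[length(q$c)]
  auc_inf <- auc_t + c_last / term$lambda_z
  dose_ug_per_kg <- profile$dose_mg_per_kg * 1000
  cl <- dose_ug_per_kg / auc_inf                       # ml/h/kg
  v_c <- NA_real_
  v_ss <- NA_real_
  if (profile$route == "IV") {
    pos <- which(q$c > 0)
    i1 <- pos[seq_len(min(n_first, length(pos)))]
    if (length(i1) >= 2) {
      f1 <- stats::lm(log(q$c[i1]) ~ q$t[i1])
      c0 <- exp(unname(stats::coef(f1)[1]))
      v_c <- dose_ug_per_kg / c0                       # ml/kg
    }
    t_last <- q$t[length(q$t)]
    aumc_inf <- .aumc_log_linear(profile) +
      c_last * t_last / term$lambda_z + c_last / term$lambda_z^2
    v_ss <- cl * aumc_inf / auc_inf                    # ml/kg
  }
  structure(list(subject_id = profile$subject_id, analyte = profile$analyte,
                 route = profile$route, dose_mg_per_kg = profile$dose_mg_per_kg,
                 c_max = cmax, t_max = tmax, auc_0_t = auc_t,
                 auc_0_inf = auc_inf, lambda_z = term$lambda_z,
                 t_half = term$t_half, cl = cl, v_c = v_c, v_ss = v_ss,
                 n_terminal_points = term$n_points,
                 r_squared = term$r_squared),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(paste0("<nca_result> %s %s %g mg/kg: Cmax %.3g ug/ml @ %g h, ",
                     "AUCinf %.4g ug*h/ml, t1/2 %.3g h, CL %.3g ml/h/kg\n"),
              x$analyte, x$route, x$dose_mg_per_kg, x$c_max, x$t_max,
              x$auc_0_inf, x$t_half, x$cl))
  invisible(x)
}

#' Absolute subcutaneous bioavailability from mean AUCs
#'
#' `F = 100 * (AUC_sc/dose_sc) / (AUC_iv/dose_iv)`, the ratio-of-means
#' convention used for group-level summary tables.
#'
#' @param mean_auc_sc,mean_auc_iv mean AUC values (same AUC flavour), ug*h/ml
#' @param dose_sc,dose_iv doses in mg/kg
#' @return percent bioavailability
#' @export
bioavailability <- function(mean_auc_sc, mean_auc_iv, dose_sc, dose_iv) {
  stopifnot(mean_auc_sc > 0, dose_sc > 0, dose_iv > 0)
  if (mean_auc_iv <= 0) stop("IV AUC must be positive")
  100 * (mean_auc_sc / dose_sc) / (mean_auc_iv / dose_iv)
}

#' Per-subject and group NCA tables
#'
#' Runs [nca_summary()] on every profile and summarises mean and SD per
#' (analyte, route, dose) group, mirroring the usual PK summary-table layout.
#'
#' @param profiles list of [conc_profile()] objects
#' @param n_terminal terminal points per profile
#' @param skip_failures drop profiles whose parameters cannot be estimated
#'   (e.g. no declining terminal phase within the sampling window) instead
#'   of stopping; skipped profiles are reported in the `skipped` element
#' @return list with `subjects` and `groups` data frames (and `skipped`
#'   when `skip_failures = TRUE`)
#' @export
nca_table <- function(profiles, n_terminal = 3, skip_failures = FALSE) {
  skipped <- character(0)
  rows <- lapply(profiles, function(p) {
    s <- if (skip_failures) {
      tryCatch(nca_summary(p, n_terminal = n_terminal),
               error = function(e) {
                 skipped <<- c(skipped,
                               paste0(p$subject_id, "/", p$analyte, ": ",
                                      conditionMessage(e)))
                 NULL
               })
    } else {
      nca_summary(p, n_terminal = n_terminal)
    }
    if (is.null(s)) return(NULL)
    data.frame(subject_id = s$subject_id, analyte = s$analyte,
               route = s$route, dose_mg_per_kg = s$dose_mg_per_kg,
               c_max = s$c_max, t_max = s$t_max, auc_0_t = s$auc_0_t,
               auc_0_inf = s$auc_0_inf, t_half = s$t_half, cl = s$cl,
               v_c = s$v_c, v_ss = s$v_ss, stringsAsFactors = FALSE)
  })
  subj <- do.call(rbind, rows)
  if (is.null(subj) || nrow(subj) == 0) stop("no profile could be analysed")
  key <- interaction(subj$analyte, subj$route, subj$dose_mg_per_kg, drop = TRUE)
  num <- c("c_max", "t_max", "auc_0_t", "auc_0_inf", "t_half", "cl",
           "v_c", "v_ss")
  groups <- do.call(rbind, lapply(split(subj, key), function(g) {
    out <- data.frame(analyte = g$analyte[1], route = g$route[1],
                      dose_mg_per_kg = g$dose_mg_per_kg[1], n = nrow(g),
                      stringsAsFactors = FALSE)
    for (v in num) {
      out[[paste0(v, "_mean")]] <- mean(g[[v]])
      out[[paste0(v, "_sd")]] <- stats::sd(g[[v]])
    }
    out
  }))
  rownames(groups) <- NULL
  out <- list(subjects = subj, groups = groups)
  if (skip_failures) out$skipped <- skipped
  out
}
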