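## Species-resolved PK for the ob/ob mouse: the two-armed conjugate is coded
## as a 4-bit state [C1 N1 C2 N2] (1 = terminus intact).  Each intact terminus
## is clipped by an independent first-order process (identical rates in the
## depot and systemic compartments), every species is cleared from the
## systemic compartment at the backbone rate, and for SC dosing every species
## is transported depot -> systemic at the absorption rate.  The resulting
## 32-state linear ODE system is integrated with deSolve.

#' Parameters of the ob/ob cleavage-network PK model
#'
#' Defaults are the measured terminal half-lives of the assay observables:
#' 2.5 h (C-terminus) and 13 h (N-terminus), 48 h absorption half-life,
#' ~12 day backbone half-life, and a systemic volume of 4% of body weight.
#'
#' @param t_half_C_hr C-terminus clipping half-life, hours
#' @param t_half_N_hr N-terminus clipping half-life, hours
#' @param t_abs_hr depot absorption half-life, hours (SC only)
#' @param t_half_backbone_days antibody-backbone clearance half-life, days
#' @param systemic_volume_fraction systemic volume as a fraction of body weight
#' @param body_weight_g body weight, grams
#' @param dose_mg_per_kg dose, mg/kg
#' @param route `"IV"` or `"SC"`
#' @param mw_g_per_mol molecular weight used for nM/ug-ml conversions.  Not
#'   stated by the assay; the default 198,000 g/mol (IgG scaffold plus two
#'   FGF21 arms) is a configurable assumption and any K_I comparison in nM
#'   depends on it.
#' @return list of class `clip_pk_params`
#' @export
clip_pk_params <- function(t_half_C_hr = 2.5, t_half_N_hr = 13,
                           t_abs_hr = 48, t_half_backbone_days = 12,
                           systemic_volume_fraction = 0.04,
                           body_weight_g = 50, dose_mg_per_kg = 10,
                           route = c("IV", "SC"),
                           mw_g_per_mol = 198000) {
  route <- match.arg(route)
  stopifnot(t_half_C_hr > 0, t_half_N_hr > 0, t_abs_hr > 0,
            t_half_backbone_days > 0,
            systemic_volume_fraction > 0, systemic_volume_fraction < 1,
            body_weight_g > 0, dose_mg_per_kg >= 0, mw_g_per_mol > 0)
  structure(list(t_half_C_hr = t_half_C_hr, t_half_N_hr = t_half_N_hr,
                 t_abs_hr = t_abs_hr,
                 t_half_backbone_days = t_half_backbone_days,
                 systemic_volume_fraction = systemic_volume_fraction,
                 body_weight_g = body_weight_g,
                 dose_mg_per_kg = dose_mg_per_kg, route = route,
                 mw_g_per_mol = mw_g_per_mol),
            class = "clip_pk_params")
}

#' Enumerate all cleavage states of the two-armed conjugate
#'
#' Returns the 16 states of the bit array `[C1 N1 C2 N2]`, each labelled by
#' its bioactivity pool: `intact` (at least one arm with both termini
#' intact), `n_only` (no intact arm but at least one intact N-terminus), or
#' `inactive`.  The labels are mutually exclusive and exhaustive.
#'
#' @return data frame with columns `state`, `c1`, `n1`, `c2`, `n2`, `pool`,
#'   plus the assay-observable flags `has_ct` and `has_nt`
#' @export
enumerate_species <- function() {
  idx <- 0:15
  c1 <- idx %/% 8 %% 2
  n1 <- idx %/% 4 %% 2
  c2 <- idx %/% 2 %% 2
  n2 <- idx %% 2
  intact <- (c1 & n1) | (c2 & n2)
  has_nt <- n1 | n2
  pool <- ifelse(intact, "intact", ifelse(has_nt, "n_only", "inactive"))
  data.frame(state = paste0(c1, n1, c2, n2),
             c1 = c1 == 1, n1 = n1 == 1, c2 = c2 == 1, n2 = n2 == 1,
             pool = pool, has_ct = c1 == 1 | c2 == 1, has_nt = has_nt == 1,
             stringsAsFactors = FALSE)
}

#' Build the first-order reaction network
#'
#' One clipping reaction per intact terminus of every state (listed in both
#' the depot and systemic compartments for SC dosing, systemic only for IV),
#' one backbone-clearance sink reaction per state in the systemic compartment,
#' and one depot-to-systemic transport reaction per state for SC dosing.
#'
#' @param params a [clip_pk_params()]
#' @return data frame with columns `source`, `product` (`NA` for the
#'   clearance sink), `rate_per_hr`, `type`, `compartment`
#' @export
build_network <- function(params) {
  sp <- enumerate_species()
  kC <- halflife_to_rate(params$t_half_C_hr)
  kN <- halflife_to_rate(params$t_half_N_hr)
  kb <- halflife_to_rate(params$t_half_backbone_days * HOURS_PER_DAY)
  ka <- halflife_to_rate(params$t_abs_hr)
  rows <- list()
  bit_info <- list(c("c1", "C", 1), c("n1", "N", 2), c("c2", "C", 3),
                   c("n2", "N", 4))
  compartments <- if (params$route == "SC") c("depot", "systemic") else "systemic"
  for (i in seq_len(nrow(sp))) {
    st <- sp$state[i]
    bits <- as.integer(strsplit(st, "")[[1]])
    for (b in bit_info) {
      pos <- as.integer(b[3])
      if (bits[pos] == 1) {
        prod_bits <- bits
        prod_bits[pos] <- 0
        rate <- if (b[2] == "C") kC else kN
        for (cmp in compartments) {
          rows[[length(rows) + 1]] <- data.frame(
            source = st, product = paste(prod_bits, collapse = ""),
            rate_per_hr = rate, type = paste0("clip_", b[2]),
            compartment = cmp, stringsAsFactors = FALSE)
        }
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      source = st, product = NA_character_, rate_per_hr = kb,
      type = "clearance", compartment = "systemic", stringsAsFactors = FALSE)
    if (params$route == "SC") {
      rows[[length(rows) + 1]] <- data.frame(
        source = st, product = st, rate_per_hr = ka, type = "transport",
        compartment = "depot_to_systemic", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count reactions touching a species
#'
#' @param network output of [build_network()]
#' @param state state string, e.g. `"1101"`
#' @param compartment compartment to filter on (default `"systemic"`)
#' @param include_transport count depot-to-systemic transport too?
#' @param role `"any"` counts the state as reactant or product (the ODE terms
#'   for that species); `"source"` counts only reactions consuming it
#' @return number of matching reactions
#' @export
reactions_touching <- function(network, state, compartment = "systemic",
                               include_transport = FALSE,
                               role = c("any", "source")) {
  role <- match.arg(role)
  net <- network
  if (!include_transport) net <- net[net$type != "transport", , drop = FALSE]
  net <- net[net$compartment == compartment, , drop = FALSE]
  hit <- net$source == state
  if (role == "any") hit <- hit | (!is.na(net$product) & net$product == state)
  sum(hit)
}

## 32x32 rate matrix: rows/cols 1..16 depot, 17..32 systemic, state order as
## in enumerate_species().  dy/dt = A %*% y.
.clip_rate_matrix <- function(params) {
  sp <- enumerate_species()
  n <- nrow(sp)
  kC <- halflife_to_rate(params$t_half_C_hr)
  kN <- halflife_to_rate(params$t_half_N_hr)
  kb <- halflife_to_rate(params$t_half_backbone_days * HOURS_PER_DAY)
  ka <- halflife_to_rate(params$t_abs_hr)
  A <- matrix(0, 2 * n, 2 * n)
  state_index <- stats::setNames(seq_len(n), sp$state)
  for (i in seq_len(n)) {
    bits <- as.integer(strsplit(sp$state[i], "")[[1]])
    rates <- c(kC, kN, kC, kN)
    for (pos in 1:4) {
      if (bits[pos] == 1) {
        prod_bits <- bits
        prod_bits[pos] <- 0
        j <- state_index[[paste(prod_bits, collapse = "")]]
        r <- rates[pos]
        ## depot block
        A[j, i] <- A[j, i] + r
        A[i, i] <- A[i, i] - r
        ## systemic block
        A[n + j, n + i] <- A[n + j, n + i] + r
        A[n + i, n + i] <- A[n + i, n + i] - r
      }
    }
    ## transport depot -> systemic
    A[n + i, i] <- A[n + i, i] + ka
    A[i, i] <- A[i, i] - ka
    ## backbone clearance, systemic only
    A[n + i, n + i] <- A[n + i, n + i] - kb
  }
  A
}

#' Simulate the cleavage-network PK model
#'
#' Integrates the 32-state (16 species x depot/systemic) linear ODE system.
#' IV dosing places the full dose in systemic `[1 1 1 1]` at t = 0; SC dosing
#' places it in the depot.
#'
#' @param params a [clip_pk_params()]
#' @param times_hr output time grid in hours, starting at 0
#' @param rtol,atol_frac solver tolerances; absolute tolerance is
#'   `atol_frac * dose`
#' @return object of class `clip_pk_trajectory` with per-species amount
#'   matrices (`depot`, `systemic`, nmol) and the time grid
#' @export
simulate_clipping <- function(params, times_hr, rtol = 1e-9,
                              atol_frac = 1e-12) {
  stopifnot(times_hr[1] == 0, !is.unsorted(times_hr))
  sp <- enumerate_species()
  A <- .clip_rate_matrix(params)
  dose <- dose_nmol(params$dose_mg_per_kg, params$body_weight_g,
                    params$mw_g_per_mol)
  y0 <- numeric(32)
  i1111 <- which(sp$state == "1111")
  if (params$route == "IV") y0[16 + i1111] <- dose else y0[i1111] <- dose
  sol <- deSolve::ode(y = y0, times = times_hr,
                      func = function(t, y, p) list(p %*% y), parms = A,
                      jacfunc = function(t, y, p) p, jactype = "fullusr",
                      rtol = rtol, atol = atol_frac * max(dose, 1),
                      method = "lsoda")
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed (rtol = ", rtol, ", atol = ",
         atol_frac * max(dose, 1), ")")
  }
  structure(list(params = params, species = sp,
                 times_hr = sol[, 1],
                 depot = unname(sol[, 2:17, drop = FALSE]),
                 systemic = unname(sol[, 18:33, drop = FALSE]),
                 dose_nmol = dose),
            class = "clip_pk_trajectory")
}

#' Assay observables and bioactive pools of a simulated trajectory
#'
#' `ct_signal` / `nt_signal` are the ELISA observables (species with at least
#' one intact C- / N-terminus in the systemic compartment); `intact_pool`
#' counts species with at least one fully intact arm (a doubly intact
#' molecule counted once); `n_only_pool` counts species with no intact arm
#' but at least one intact N-terminus.
#'
#' @param trajectory a `clip_pk_trajectory`
#' @param units `"nmol"`, `"nM"` or `"ug_per_ml"`
#' @return data frame with `time_hr` and the four observables
#' @export
pool_observables <- function(trajectory,
                             units = c("nmol", "nM", "ug_per_ml")) {
  units <- match.arg(units)
  sp <- trajectory$species
  sys <- trajectory$systemic
  out <- data.frame(
    time_hr = trajectory$times_hr,
    ct_signal = rowSums(sys[, sp$has_ct, drop = FALSE]),
    nt_signal = rowSums(sys[, sp$has_nt, drop = FALSE]),
    intact_pool = rowSums(sys[, sp$pool == "intact", drop = FALSE]),
    n_only_pool = rowSums(sys[, sp$pool == "n_only", drop = FALSE]))
  if (units != "nmol") {
    p <- trajectory$params
    v_L <- p$systemic_volume_fraction * p$body_weight_g / 1000  # ml -> L
    for (v in c("ct_signal", "nt_signal", "intact_pool", "n_only_pool")) {
      conc_nM <- out[[v]] / v_L
      out[[v]] <- if (units == "nM") conc_nM else
        nM_to_ug_per_ml(conc_nM, p$mw_g_per_mol)
    }
  }
  out
}

#' Closed-form IV assay observables (no-transport survival formulas)
#'
#' For an IV dose, the probability that a molecule retains at least one
#' intact C-terminus is `2s - s^2` with `s = exp(-kC t)` (independent arms),
#' times backbone survival.  Used as an analytic oracle for the ODE system.
#'
#' @param params a [clip_pk_params()]
#' @param times_hr times in hours
#' @return data frame with `time_hr`, `ct_frac`, `nt_frac`, `intact_frac`
#'   (fractions of the administered dose)
#' @export
clip_closed_form_iv <- function(params, times_hr) {
  kC <- halflife_to_rate(params$t_half_C_hr)
  kN <- halflife_to_rate(params$t_half_N_hr)
  kb <- halflife_to_rate(params$t_half_backbone_days * HOURS_PER_DAY)
  sC <- exp(-kC * times_hr)
  sN <- exp(-kN * times_hr)
  sb <- exp(-kb * times_hr)
  arm <- sC * sN                      # one arm fully intact
  data.frame(time_hr = times_hr,
             ct_frac = (2 * sC - sC^2) * sb,
             nt_frac = (2 * sN - sN^2) * sb,
             intact_frac = (2 * arm - arm^2) * sb)
}

#' Per-molecule Monte-Carlo oracle for the cleavage network
#'
#' Simulates independent exponential clipping times per terminus, an
#' exponential absorption time (SC), and an exponential backbone-clearance
#' time per molecule, and reports empirical systemic pool fractions with
#' binomial standard errors.  This is a verification oracle for the ODE
#' model, not a production path.
#'
#' @param params a [clip_pk_params()]
#' @param n_molecules number of molecules
#' @param seed RNG seed
#' @param times_hr evaluation times
#' @return data frame with fractions (`*_frac`) and standard errors (`*_se`)
#'   for ct/nt/intact/n_only pools
#' @export
clip_mc_oracle <- function(params, n_molecules, seed, times_hr) {
  stopifnot(n_molecules >= 1)
  set.seed(seed)
  kC <- halflife_to_rate(params$t_half_C_hr)
  kN <- halflife_to_rate(params$t_half_N_hr)
  kb <- halflife_to_rate(params$t_half_backbone_days * HOURS_PER_DAY)
  ka <- halflife_to_rate(params$t_abs_hr)
  n <- n_molecules
  tc1 <- stats::rexp(n, kC); tn1 <- stats::rexp(n, kN)
  tc2 <- stats::rexp(n, kC); tn2 <- stats::rexp(n, kN)
  t_abs <- if (params$route == "SC") stats::rexp(n, ka) else numeric(n)
  t_clear <- t_abs + stats::rexp(n, kb)
  res <- lapply(times_hr, function(t) {
    present <- t >= t_abs & t < t_clear
    c1 <- tc1 > t; n1 <- tn1 > t; c2 <- tc2 > t; n2 <- tn2 > t
    intact <- (c1 & n1) | (c2 & n2)
    pools <- list(ct = present & (c1 | c2), nt = present & (n1 | n2),
                  intact = present & intact,
                  n_only = present & !intact & (n1 | n2))
    out <- data.frame(time_hr = t)
    for (nm in names(pools)) {
      p <- mean(pools[[nm]])
      out[[paste0(nm, "_frac")]] <- p
      ## one-pseudocount floor keeps the SE meaningful at empty cells
      out[[paste0(nm, "_se")]] <- sqrt(max(p * (1 - p), 1 / n) / n)
    }
    out
  })
  do.call(rbind, res)
}
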