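## Equilibrium binding of two ligand pools (intact, N-only) competing for one
## receptor complex (KLB/FGFR1c), with ligand depletion.  The 5-equation
## system (two K_D relations, three mass balances) reduces to one monotone
## scalar equation in free receptor:
##   g(R) = R * (1 + I_tot/(K_D_I + R) + N_tot/(K_D_N + R)) = R_tot
## which always has exactly one root in (0, R_tot].

#' Binding parameters
#'
#' @param R_tot total receptor-complex concentration, nM (10,000 sites per
#'   adipocyte in 4 pl extracellular volume gives 4.15 nM)
#' @param K_D_I intact-pool affinity, nM
#' @param K_D_N N-only-pool affinity, nM (estimated by the body-weight fit)
#' @return list of class `binding_params`
#' @export
binding_params <- function(R_tot = 4.15, K_D_I = 0.5, K_D_N = 30) {
  stopifnot(R_tot > 0, K_D_I > 0, K_D_N > 0)
  structure(list(R_tot = R_tot, K_D_I = K_D_I, K_D_N = K_D_N),
            class = "binding_params")
}

## Vectorised safeguarded solve for free receptor: bisection to bracket
## tightly, then Newton polish to |g - R_tot| < tol.
.free_receptor <- function(I_tot, N_tot, params, tol = 1e-12) {
  Rt <- params$R_tot
  KI <- params$K_D_I
  KN <- params$K_D_N
  g <- function(R) R * (1 + I_tot / (KI + R) + N_tot / (KN + R))
  lo <- rep(0, length(I_tot))
  hi <- rep(Rt, length(I_tot))
  for (i in 1:45) {
    mid <- (lo + hi) / 2
    too_big <- g(mid) > Rt
    hi[too_big] <- mid[too_big]
    lo[!too_big] <- mid[!too_big]
  }
  R <- (lo + hi) / 2
  for (i in 1:5) {
    gv <- g(R) - Rt
    dg <- 1 + I_tot * KI / (KI + R)^2 + N_tot * KN / (KN + R)^2
    R <- pmin(pmax(R - gv / dg, 0), Rt)
  }
  R
}

#' Receptor occupancy for vectors of total ligand concentrations
#'
#' @param I_tot,N_tot total intact and N-only concentrations, nM (vectors)
#' @param params a [binding_params()]
#' @return vector of occupancies `([IR]+[NR])/R_tot` in `[0,1]`
#' @export
receptor_occupancy <- function(I_tot, N_tot, params) {
  stopifnot(length(I_tot) == length(N_tot))
  if (any(I_tot < 0) || any(N_tot < 0)) stop("ligand concentrations must be >= 0")
  R <- .free_receptor(I_tot, N_tot, params)
  IR <- I_tot * R / (params$K_D_I + R)
  NR <- N_tot * R / (params$K_D_N + R)
  (IR + NR) / params$R_tot
}

#' Solve the two-ligand equilibrium binding system
#'
#' @param I_tot,N_tot total intact and N-only concentrations, nM (scalars)
#' @param params a [binding_params()]
#' @param tol residual tolerance on the receptor mass balance, nM
#' @return list of class `binding_solution` with `I_free`, `N_free`,
#'   `R_free`, `IR`, `NR` (nM) and `RO`
#' @export
solve_equilibrium <- function(I_tot, N_tot, params, tol = 1e-12) {
  stopifnot(length(I_tot) == 1, length(N_tot) == 1)
  if (I_tot < 0 || N_tot < 0) stop("ligand concentrations must be >= 0")
  R <- .free_receptor(I_tot, N_tot, params, tol = tol)
  IR <- I_tot * R / (params$K_D_I + R)
  NR <- N_tot * R / (params$K_D_N + R)
  structure(list(I_free = I_tot - IR, N_free = N_tot - NR, R_free = R,
                 IR = IR, NR = NR, RO = (IR + NR) / params$R_tot),
            class = "binding_solution")
}

#' Single-ligand closed-form occupancy (quadratic, with depletion)
#'
#' Independent oracle for the special case `N_tot = 0`: the physical root of
#' `RL^2 - (R_tot + L_tot + K_D) RL + R_tot L_tot = 0`.
#'
#' @param L_tot total ligand, nM
#' @param K_D affinity, nM
#' @param R_tot total receptor, nM
#' @return bound complex concentration, nM
#' @export
single_ligand_bound <- function(L_tot, K_D, R_tot) {
  b <- R_tot + L_tot + K_D
  (b - sqrt(b^2 - 4 * R_tot * L_tot)) / 2
}
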