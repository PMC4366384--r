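#' @keywords internal
"_PACKAGE"

## Shared unit conversions.  Internal convention: PK in hours and nmol,
## concentrations in nM; the body-weight PD model runs in days.

LN2 <- log(2)
AVOGADRO <- 6.02214076e23
HOURS_PER_DAY <- 24

#' Convert a first-order half-life to a rate constant
#'
#' @param t_half half-life (any time unit)
#' @return rate constant `ln(2)/t_half` in the reciprocal unit
#' @export
halflife_to_rate <- function(t_half) {
  stopifnot(is.numeric(t_half), all(t_half > 0))
  LN2 / t_half
}

#' Total dose in nmol from a weight-normalised dose
#'
#' @param dose_mg_per_kg dose in mg/kg
#' @param body_weight_g animal body weight in grams
#' @param mw_g_per_mol molecular weight in g/mol
#' @return dose in nmol
#' @export
dose_nmol <- function(dose_mg_per_kg, body_weight_g, mw_g_per_mol) {
  ## mg/kg * g = ug total; ug -> nmol is *1e3/MW
  dose_mg_per_kg * body_weight_g * 1000 / mw_g_per_mol
}

#' Convert nM to ug/ml for a given molecular weight
#' @param conc_nM concentration in nM
#' @param mw_g_per_mol molecular weight in g/mol
#' @export
nM_to_ug_per_ml <- function(conc_nM, mw_g_per_mol) {
  conc_nM * mw_g_per_mol * 1e-6
}

#' Convert ug/ml to nM for a given molecular weight
#' @param conc_ug_per_ml concentration in ug/ml
#' @param mw_g_per_mol molecular weight in g/mol
#' @export
ug_per_ml_to_nM <- function(conc_ug_per_ml, mw_g_per_mol) {
  conc_ug_per_ml * 1e6 / mw_g_per_mol
}

#' Receptor-complex concentration from sites per cell
#'
#' Converts a receptor copy number per adipocyte into a molar concentration in
#' the extracellular space assigned to that cell (default: 10,000 sites in
#' 4 pl, i.e. 4% of a 100 pl adipocyte).
#'
#' @param sites_per_cell receptor complexes per cell
#' @param volume_pl extracellular volume per cell, picolitres
#' @return concentration in nM
#' @export
receptor_concentration_nM <- function(sites_per_cell = 1e4, volume_pl = 4) {
  stopifnot(sites_per_cell >= 0, volume_pl > 0)
  ## sites / N_A = mol; volume_pl * 1e-12 = litres; *1e9 -> nM
  sites_per_cell / AVOGADRO / (volume_pl * 1e-12) * 1e9
}

#' Adipose extracellular volume from fat mass
#'
#' @param fat_g fat mass in grams (density taken as 1 g/ml)
#' @param extracellular_fraction fraction of fat volume that is extracellular
#' @return volume in ml
#' @export
adipose_extracellular_volume_ml <- function(fat_g = 20,
                                            extracellular_fraction = 0.04) {
  stopifnot(fat_g > 0, extracellular_fraction > 0, extracellular_fraction < 1)
  fat_g * extracellular_fraction
}

#' Plasma/adipose exchange rate from a turnover time
#'
#' The extracellular adipose volume is assumed to exchange completely with
#' plasma over the turnover time, giving a flow `volume / turnover`.
#'
#' @param volume_ml exchanging volume in ml
#' @param turnover_hr turnover time in hours
#' @return flow in ml/hr
#' @export
exchange_rate_ml_per_hr <- function(volume_ml = 0.8, turnover_hr = 48) {
  stopifnot(volume_ml > 0, turnover_hr > 0)
  volume_ml / turnover_hr
}
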