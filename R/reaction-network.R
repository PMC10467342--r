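# Nitrogen-cycle reaction network: aerobic mineralization, denitrification,
# nitrification and anammox, with Monod / inhibition kinetics.
#
# Organic-carbon mineralization is prescribed as R_C(z) = R0 * exp(-z / z_att)
# (no explicit solid organic-matter state); the aerobic and denitrifying
# fractions are partitioned by Monod factors, and any remainder is implicitly
# routed to pathways outside the modeled state (sulfate reduction etc.).
# Anammox is written lumped on nitrate with electron-balanced stoichiometry
# 5 NH4+ + 3 NO3- -> 4 N2 (per mol NH4: 0.6 NO3 consumed, 1.6 N to N2),
# because nitrite is unmeasured in the profiles the model is fit to.

#' Kinetic parameters of the nitrogen network
#'
#' @param R0 Total organic-carbon mineralization rate at the sediment surface,
#'   uM-C yr^-1.
#' @param z_att Attenuation length of mineralization with depth, m.
#' @param r_NC N:C ratio of mineralized organic matter (Redfield 16/106 by
#'   default), dimensionless, in (0, 1).
#' @param k_nit Nitrification rate constant, yr^-1 (first order in NH4).
#' @param k_amx Anammox rate constant, uM^-1 yr^-1 (bimolecular in NH4, NO3).
#' @param K_O2 Monod half-saturation of O2 for aerobic mineralization, uM.
#' @param K_O2nit Monod half-saturation of O2 for nitrification, uM.
#' @param K_NO3 Monod half-saturation of NO3 for denitrification, uM.
#' @param Ki_O2 O2 inhibition constant for anaerobic pathways (denitrification,
#'   anammox), uM.
#' @return A list of class `nat_kinetics`.
#' @examples
#' kinetic_params()
#' kinetic_params(k_amx = 5)
#' @export
kinetic_params <- function(R0 = 900, z_att = 0.09, r_NC = 16 / 106,
                           k_nit = 100, k_amx = 0.1,
                           K_O2 = 8, K_O2nit = 4, K_NO3 = 15, Ki_O2 = 0.3) {
  kp <- list(R0 = R0, z_att = z_att, r_NC = r_NC, k_nit = k_nit, k_amx = k_amx,
             K_O2 = K_O2, K_O2nit = K_O2nit, K_NO3 = K_NO3, Ki_O2 = Ki_O2)
  for (nm in names(kp)) {
    check_number(kp[[nm]], nm, lower = 0, strict_lower = TRUE)
  }
  if (r_NC >= 1) abort_input("`r_NC` must lie in (0, 1)")
  structure(kp, class = "nat_kinetics")
}

#' Monod saturation factor
#'
#' @param c Concentration, uM (>= 0). Vectorized.
#' @param K Half-saturation constant, uM (> 0).
#' @return `c / (c + K)`, in \[0, 1).
#' @examples
#' monod(5, 5)   # 0.5
#' monod(15, 5)  # 0.75
#' @export
monod <- function(c, K) {
  check_nonneg_vector(c, "c")
  check_number(K, "K", lower = 0, strict_lower = TRUE)
  c / (c + K)
}

#' Oxygen inhibition factor for anaerobic pathways
#'
#' @param c Inhibitor (O2) concentration, uM (>= 0). Vectorized.
#' @param Ki Inhibition constant, uM (> 0).
#' @return `Ki / (Ki + c)`, in (0, 1\]; 1 under full anoxia.
#' @examples
#' inhibition(0, 1)  # 1
#' inhibition(1, 1)  # 0.5
#' @export
inhibition <- function(c, Ki) {
  check_nonneg_vector(c, "c")
  check_number(Ki, "Ki", lower = 0, strict_lower = TRUE)
  Ki / (Ki + c)
}

#' Per-cell volumetric reaction rates
#'
#' Evaluates the four pathway rates at each grid cell:
#' \itemize{
#'   \item `R_O2C` aerobic carbon mineralization, uM-C yr^-1:
#'     \eqn{R_C(z)\,\mathrm{monod}(O_2, K_{O2})}
#'   \item `R_denC` denitrifying carbon mineralization, uM-C yr^-1:
#'     \eqn{R_C(z)\,(1-\mathrm{monod}(O_2,K_{O2}))\,\mathrm{monod}(NO_3,K_{NO3})\,\mathrm{inh}(O_2,K_{i})}
#'   \item `R_nit` nitrification, uM-NH4 yr^-1:
#'     \eqn{k_{nit}\,NH_4\,\mathrm{monod}(O_2, K_{O2nit})}
#'   \item `R_amx` anammox, uM-NH4 yr^-1:
#'     \eqn{k_{amx}\,NH_4\,NO_3\,\mathrm{inh}(O_2, K_{i})}
#' }
#' with \eqn{R_C(z) = R_0 e^{-z/z_{att}}}.
#'
#' @param concs Data frame (or matrix) with columns `O2`, `NO3`, `NH4`: per-cell
#'   concentrations in uM, all >= 0, one row per grid cell.
#' @param grid A `nat_grid` with matching number of cells.
#' @param kinetics A [kinetic_params()] object.
#' @return Tibble with columns `cell`, `z_mid`, `R_O2C`, `R_denC`, `R_nit`,
#'   `R_amx` (all >= 0).
#' @export
volumetric_rates <- function(concs, grid, kinetics) {
  concs <- as.data.frame(concs)
  for (sp in c("O2", "NO3", "NH4")) {
    if (is.null(concs[[sp]])) abort_input(sprintf("`concs` must contain column `%s`", sp))
    check_nonneg_vector(concs[[sp]], sp)
  }
  if (nrow(concs) != nrow(grid)) abort_input("`concs` and `grid` differ in cell count")
  kp <- kinetics
  O2 <- concs$O2; NO3 <- concs$NO3; NH4 <- concs$NH4
  R_C <- kp$R0 * exp(-grid$z_mid / kp$z_att)
  f_O2 <- O2 / (O2 + kp$K_O2)
  tibble::tibble(
    cell = grid$cell,
    z_mid = grid$z_mid,
    R_O2C = R_C * f_O2,
    R_denC = R_C * (1 - f_O2) * (NO3 / (NO3 + kp$K_NO3)) * (kp$Ki_O2 / (kp$Ki_O2 + O2)),
    R_nit = kp$k_nit * NH4 * (O2 / (O2 + kp$K_O2nit)),
    R_amx = kp$k_amx * NH4 * NO3 * (kp$Ki_O2 / (kp$Ki_O2 + O2))
  )
}

#' Net source terms per species from pathway rates
#'
#' Stoichiometric bookkeeping, uM yr^-1 of each solute per unit porewater
#' volume:
#' \deqn{S_{O2} = -R_{O2C} - 2 R_{nit}}
#' \deqn{S_{NO3} = +R_{nit} - 0.8 R_{denC} - 0.6 R_{amx}}
#' \deqn{S_{NH4} = +r_{NC} (R_{O2C} + R_{denC}) - R_{nit} - R_{amx}}
#' \deqn{S_{N2N} = +0.8 R_{denC} + 1.6 R_{amx}}
#' Aerobic respiration consumes 1 mol O2 per mol C; nitrification 2 mol O2 per
#' mol NH4; denitrification 0.8 mol NO3 per mol C (5 CH2O : 4 NO3-); anammox
#' 0.6 mol NO3 and 1 mol NH4 per mol NH4, releasing 1.6 mol N as N2. `S_N2N`
#' is a produced-nitrogen diagnostic pool (no back-reaction): fixed N consumed
#' equals N2-N produced exactly.
#'
#' @param rates Tibble from [volumetric_rates()].
#' @param kinetics A [kinetic_params()] object (supplies `r_NC`).
#' @return Tibble with columns `cell`, `z_mid`, `S_O2`, `S_NO3`, `S_NH4`,
#'   `S_N2N` in uM yr^-1.
#' @export
species_sources <- function(rates, kinetics) {
  for (nm in c("R_O2C", "R_denC", "R_nit", "R_amx")) {
    if (is.null(rates[[nm]])) abort_input(sprintf("`rates` must contain column `%s`", nm))
  }
  tibble::tibble(
    cell = rates$cell,
    z_mid = rates$z_mid,
    S_O2 = -rates$R_O2C - 2 * rates$R_nit,
    S_NO3 = rates$R_nit - 0.8 * rates$R_denC - 0.6 * rates$R_amx,
    S_NH4 = kinetics$r_NC * (rates$R_O2C + rates$R_denC) - rates$R_nit - rates$R_amx,
    S_N2N = 0.8 * rates$R_denC + 1.6 * rates$R_amx
  )
}
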