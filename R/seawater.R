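# Empirical seawater physics: oxygen solubility and molecular diffusivity.

#' Air-equilibrated oxygen concentration of seawater
#'
#' Saturation concentration of dissolved oxygen at the top of the diffusive
#' boundary layer, for a given temperature, salinity and atmospheric oxygen
#' partial pressure expressed as a percentage of the present atmospheric
#' level (%PAL).  The modern-atmosphere solubility is evaluated with the
#' Garcia and Gordon (1992) combined fit to the Benson and Krause data
#' (umol kg-1), converted to volumetric units with a nominal seawater
#' density of 1.025 kg L-1, and scaled linearly in ppO2 (Henry's law).
#'
#' @param temperature water temperature, degrees C.
#' @param salinity salinity, PSU.
#' @param ppO2 atmospheric oxygen as % of the present atmospheric level.
#' @return oxygen concentration in uM.  Strictly decreasing in temperature
#'   and salinity, strictly linear in `ppO2`.
#' @references Garcia, H. E. and Gordon, L. I. (1992) Oxygen solubility in
#'   seawater: better fitting equations. Limnology and Oceanography 37,
#'   1307-1312.
#' @examples
#' o2_saturation(5, 35, 100)   # cold, fully modern atmosphere
#' o2_saturation(25, 35, 30)   # warm, 30 %PAL
#' @export
o2_saturation <- function(temperature, salinity, ppO2) {
  check_number(temperature, "temperature", -2, 60)
  check_number(salinity, "salinity", 0, 45)
  check_number(ppO2, "ppO2", 0, 150, open_lower = TRUE)
  # Garcia & Gordon (1992), Benson-Krause coefficients, C* in umol/kg
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  c0 <- -2.75915e-7
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  lnc <- sum(a * ts^(0:5)) + salinity * sum(b * ts^(0:3)) + c0 * salinity^2
  umol_kg <- exp(lnc)
  umol_kg * 1.025 * ppO2 / 100
}

#' Molecular diffusivity of oxygen in seawater
#'
#' Free-solution diffusion coefficient of O2, using the quadratic
#' temperature fit of Boudreau (1997) for fresh water with a linear
#' salinity (viscosity) correction.  Strictly increasing in temperature.
#'
#' @inheritParams o2_saturation
#' @return diffusivity in cm2 h-1.
#' @references Boudreau, B. P. (1997) Diagenetic Models and Their
#'   Implementation. Springer.
#' @examples
#' o2_diffusivity(20, 35)
#' @export
o2_diffusivity <- function(temperature, salinity) {
  check_number(temperature, "temperature", -2, 60)
  check_number(salinity, "salinity", 0, 45)
  d_fw <- (11.70 + 0.3444 * temperature + 0.005048 * temperature^2) * 1e-6 # cm2/s
  d_sw <- d_fw * (1 - 1.25e-3 * salinity)
  d_sw * 3600
}
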