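# Shared physical constants (SI)
.R_GAS <- 8.31446   # J mol-1 K-1
.ATM_PA <- 101325   # Pa per atm

#' Species registry for isoprene oxidation products
#'
#' Physical constants for the compounds handled by the exchange pipeline:
#' molar mass, effective Henry's law constant \eqn{H^*} (M atm\eqn{^{-1}},
#' including hydration equilibria), the Wesely surface-reactivity factor
#' \eqn{f_0}, and the in-leaf conversion map (product species and molar
#' yields of the deposited parent).
#'
#' `ISOPOOH_12` and `ISOPOOH_43` are the 1,2- and 4,3-isomers of isoprene
#' hydroxy hydroperoxide. The 1,2-isomer decomposes to MVK (+ HCHO), the
#' 4,3-isomer to MACR; MVK is enzymatically reduced to MEK.
#'
#' @param name optional character vector of species to return; default all.
#' @return A data.frame with columns `name`, `molar_mass` (g mol-1),
#'   `henry_eff` (M atm-1), `f0`, and a list-column `conversion_products`
#'   of named numeric yield vectors.
#' @examples
#' species_registry("MEK")$molar_mass
#' @export
species_registry <- function(name = NULL) {
  reg <- data.frame(
    name       = c("isoprene", "ISOPOOH_12", "ISOPOOH_43", "MVK", "MACR",
                   "MEK", "HCHO"),
    molar_mass = c(68.12, 118.13, 118.13, 70.09, 70.09, 72.11, 30.03),
    henry_eff  = c(0.013, 1.7e6, 1.7e6, 44, 6.5, 21, 3.2e3),
    f0         = c(0, 1.0, 1.0, 1.0, 1.0, 0.1, 0.2),
    stringsAsFactors = FALSE
  )
  reg$conversion_products <- list(
    numeric(0),
    c(MVK = 0.5, MEK = 0.5),     # 1,2-ISOPOOH: measured daytime split
    c(MACR = 1.0),               # 4,3-isomer: MACR, no MEK
    c(MEK = 1.0),                # MVK -> MEK, complete
    numeric(0),
    numeric(0),
    numeric(0)
  )
  if (!is.null(name)) {
    miss <- setdiff(name, reg$name)
    if (length(miss))
      stop("unknown species: ", paste(miss, collapse = ", "))
    reg <- reg[match(name, reg$name), , drop = FALSE]
    rownames(reg) <- NULL
  }
  reg
}

#' Look up a single species' properties
#'
#' @param name species identifier present in [species_registry()].
#' @return A one-row data.frame of properties.
#' @export
species_properties <- function(name) {
  stopifnot(length(name) == 1L)
  species_registry(name)
}

#' Convert a volume mixing ratio to a concentration
#'
#' Ideal-gas conversion \eqn{c = \chi \cdot 10^{-9} p / (RT)} from ppbv to
#' mol m\eqn{^{-3}}, with a mass view in \eqn{\mu}g cm\eqn{^{-3}} when a
#' species (for its molar mass) is supplied.
#'
#' @param vmr volume mixing ratio, ppbv (vectorised).
#' @param temperature air temperature, K.
#' @param pressure air pressure, Pa.
#' @param species optional species name for the mass view.
#' @return A data.frame with columns `mol_m3` and, if `species` is given,
#'   `ug_cm3`.
#' @seealso [concentration_to_vmr()] for the inverse.
#' @export
vmr_to_concentration <- function(vmr, temperature = 298.15,
                                 pressure = .ATM_PA, species = NULL) {
  if (any(vmr < 0)) stop("vmr must be nonnegative")
  stopifnot(temperature > 0, pressure > 0)
  mol_m3 <- vmr * 1e-9 * pressure / (.R_GAS * temperature)
  out <- data.frame(mol_m3 = mol_m3)
  if (!is.null(species)) {
    m <- species_properties(species)$molar_mass
    # mol m-3 -> g m-3 -> ug cm-3: * M * 1e6 / 1e6
    out$ug_cm3 <- mol_m3 * m
  }
  out
}

#' Convert a concentration back to a volume mixing ratio
#'
#' @param mol_m3 concentration, mol m-3.
#' @inheritParams vmr_to_concentration
#' @return ppbv, numeric.
#' @export
concentration_to_vmr <- function(mol_m3, temperature = 298.15,
                                 pressure = .ATM_PA) {
  stopifnot(temperature > 0, pressure > 0)
  mol_m3 * (.R_GAS * temperature) / pressure * 1e9
}

# molar flow of air through the enclosure, mol s-1, from Q in L min-1
.air_molar_flow <- function(flow_l_min, temperature, pressure) {
  q_m3_s <- flow_l_min / 1000 / 60
  pressure * q_m3_s / (.R_GAS * temperature)
}
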