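#' Load the packaged standard-state thermodynamic constants
#'
#' Standard Gibbs free energies and enthalpies of formation (kJ mol-1, 25
#' degC, 1 bar) for the aqueous species of the anammox reaction, from
#' standard compilations for aqueous geochemistry. The table is an editable
#' TSV so alternative constants can be substituted.
#'
#' @param path optional path to an alternative table with columns
#'   \code{species}, \code{dG0f_kJ_mol}, \code{dH0f_kJ_mol}, \code{charge}
#' @return data.frame of formation constants
#' @export
thermo_constants <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "thermo_constants.tsv",
                        package = "natzamx", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "dG0f_kJ_mol", "dH0f_kJ_mol", "charge")
  if (!all(need %in% names(tab)))
    stop("invalid configuration: thermo table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  tab
}

#' In-situ thermodynamic state
#'
#' Bundles everything needed to evaluate reaction energetics at depth:
#' formation constants, temperature, pressure, ionic strength, pH and the
#' activity model. Activity coefficients are either unity (ideal, used by
#' verification oracles) or Davies at the stated ionic strength (seawater
#' default I = 0.7 mol kg-1).
#'
#' @param temperature_C in-situ temperature (degrees C)
#' @param pressure_bar in-situ pressure (bar)
#' @param ionic_strength mol kg-1
#' @param pH porewater pH (sets the H+ activity directly)
#' @param activity_model \code{"davies"} or \code{"unit"}
#' @param constants formation-constant table, see
#'   \code{\link{thermo_constants}}
#' @return an object of class \code{thermo_state}
#' @export
thermo_state <- function(temperature_C = 2, pressure_bar = 250,
                         ionic_strength = 0.7, pH = 7.8,
                         activity_model = c("davies", "unit"),
                         constants = thermo_constants()) {
  activity_model <- match.arg(activity_model)
  T_K <- temperature_C + 273.15
  if (T_K <= 0) stop("invalid configuration: temperature below 0 K",
                     call. = FALSE)
  if (ionic_strength < 0)
    stop("invalid configuration: ionic_strength must be >= 0", call. = FALSE)
  structure(list(T_K = T_K, P_bar = pressure_bar,
                 ionic_strength = ionic_strength, pH = pH,
                 activity_model = activity_model, constants = constants,
                 R = 8.314e-3),          # kJ mol-1 K-1
            class = "thermo_state")
}

.lookup_thermo <- function(thermo, species) {
  i <- match(species, thermo$constants$species)
  if (anyNA(i))
    stop("invalid configuration: no thermodynamic constants for ",
         paste(species[is.na(i)], collapse = ", "), call. = FALSE)
  thermo$constants[i, , drop = FALSE]
}

#' Standard Gibbs free energy of a reaction at in-situ T and P
#'
#' Sums formation energies over the stoichiometric coefficients, corrects to
#' in-situ temperature with the integrated van 't Hoff (Gibbs-Helmholtz)
#' relation assuming a temperature-independent reaction enthalpy,
#' \eqn{\Delta G^0_r(T) = \Delta H^0_r (1 - T/T_0) + \Delta G^0_r(T_0)
#' T/T_0}, and optionally to pressure with a user-supplied reaction volume
#' (\code{dV_cm3_mol}, default 0).
#'
#' @param reaction named stoichiometric coefficient vector (negative =
#'   consumed), e.g. \code{\link{anammox_stoichiometry}} output
#' @param thermo a \code{\link{thermo_state}}
#' @param dV_cm3_mol reaction volume change (cm3 mol-1) for the pressure
#'   correction
#' @return kJ per mol of reaction as written
#' @examples
#' th <- thermo_state(temperature_C = 25, pressure_bar = 1)
#' standard_gibbs(anammox_stoichiometry("nitrite_canonical"), th)
#' @export
standard_gibbs <- function(reaction, thermo, dV_cm3_mol = 0) {
  reaction <- reaction[reaction != 0]
  if (!length(reaction)) return(0)
  tab <- .lookup_thermo(thermo, names(reaction))
  T0 <- 298.15
  dG0 <- sum(reaction * tab$dG0f_kJ_mol)
  dH0 <- sum(reaction * tab$dH0f_kJ_mol)
  dG_T <- dH0 * (1 - thermo$T_K / T0) + dG0 * thermo$T_K / T0
  # 1 cm3 bar = 1e-4 kJ
  dG_T + dV_cm3_mol * (thermo$P_bar - 1) * 1e-4
}

# Davies activity coefficient; A fixed at its 25 degC value, adequate for
# the 0-25 degC range used here
.activity_coefficient <- function(charge, ionic_strength, model) {
  if (model == "unit" || ionic_strength == 0) return(rep(1, length(charge)))
  sqI <- sqrt(ionic_strength)
  10^(-0.509 * charge^2 * (sqI / (1 + sqI) - 0.3 * ionic_strength))
}

#' In-situ Gibbs free energy of reaction
#'
#' \eqn{\Delta G_r = \Delta G^0_r + RT \ln Q} with the reaction quotient
#' built from molal activities (molar concentration approximated as molal,
#' activity coefficients from the thermo state's model). Water activity is
#' 1; the H+ activity comes from the state's pH. Concentrations at or below
#' zero are replaced by a floor (logged via a message) so profiles with
#' below-detection values remain evaluable.
#'
#' @param reaction named stoichiometric coefficient vector
#' @param thermo a \code{\link{thermo_state}}
#' @param concentrations named vector or list of numeric vectors (uM) for
#'   every aqueous species in the quotient except H2O and H
#' @param floor_uM replacement for non-positive concentrations (uM); set
#'   \code{NULL} to make non-positive input an error
#' @param per normalisation: per mol \code{"NH4"} consumed (default), per
#'   mol \code{"N"} converted, or per mol \code{"reaction"} as written
#' @param dV_cm3_mol passed to \code{\link{standard_gibbs}}
#' @return kJ per mol of the chosen normalisation (vectorised over
#'   concentration profiles); negative = exergonic
#' @export
in_situ_gibbs <- function(reaction, thermo, concentrations,
                          floor_uM = 0.001, per = c("NH4", "N", "reaction"),
                          dV_cm3_mol = 0) {
  per <- match.arg(per)
  reaction <- reaction[reaction != 0]
  dG0 <- standard_gibbs(reaction, thermo, dV_cm3_mol)
  conc_sp <- setdiff(names(reaction), c("H2O", "H"))
  lnQ <- 0
  for (sp in conc_sp) {
    c_uM <- concentrations[[sp]]
    if (is.null(c_uM))
      stop("invalid input: no concentration supplied for ", sp,
           call. = FALSE)
    if (any(c_uM <= 0)) {
      if (is.null(floor_uM))
        stop("domain error: non-positive concentration for ", sp,
             " and no floor enabled", call. = FALSE)
      message("in_situ_gibbs: ", sum(c_uM <= 0), " non-positive ", sp,
              " value(s) floored at ", floor_uM, " uM")
      c_uM <- pmax(c_uM, floor_uM)
    }
    z <- .lookup_thermo(thermo, sp)$charge
    gamma <- .activity_coefficient(z, thermo$ionic_strength,
                                   thermo$activity_model)
    a <- gamma * c_uM * 1e-6          # uM -> mol kg-1
    lnQ <- lnQ + reaction[[sp]] * log(a)
  }
  if ("H" %in% names(reaction))
    lnQ <- lnQ + reaction[["H"]] * log(10^(-thermo$pH))
  dG <- dG0 + thermo$R * thermo$T_K * lnQ
  norm <- switch(per,
    NH4 = abs(reaction[["NH4"]]),
    N = {   # mol N converted to N2 per mol reaction
      2 * abs(reaction[["N2"]])
    },
    reaction = 1)
  unname(dG / norm)
}

#' Catabolic power-supply profile
#'
#' Power supply of a reaction is the product of its volumetric rate and the
#' magnitude of its in-situ Gibbs free energy. With rate in umol cm-3 yr-1
#' and energy in kJ mol-1 the product x 1e-3 gives J cm-3 yr-1.
#'
#' @param rate volumetric rate profile (umol cm-3 yr-1)
#' @param gibbs in-situ Gibbs energy profile (kJ mol-1), same grid
#' @param depth optional depths (cm) carried into the result
#' @param source \code{"modeled"} or \code{"measured"} provenance label
#' @return data.frame of class \code{power_profile} with power in
#'   J cm-3 yr-1 and W cm-3
#' @export
power_supply <- function(rate, gibbs, depth = NULL,
                         source = c("modeled", "measured")) {
  source <- match.arg(source)
  if (length(gibbs) == 1) gibbs <- rep(gibbs, length(rate))
  if (length(rate) != length(gibbs))
    stop("invalid input: rate and gibbs profiles are on different grids",
         call. = FALSE)
  if (!is.null(depth) && length(depth) != length(rate))
    stop("invalid input: depth grid does not match the profiles",
         call. = FALSE)
  p <- rate * abs(gibbs) * 1e-3
  out <- data.frame(
    depth_cm = if (is.null(depth)) NA_real_ else depth,
    gibbs_kJ_mol = gibbs, rate_umol_cm3_yr = rate,
    power_J_cm3_yr = p, power_W_cm3 = p / 3.154e7,
    source = source)
  class(out) <- c("power_profile", "data.frame")
  out
}

#' Cell-specific metabolic rate
#'
#' Divides a bulk volumetric reaction rate by the local cell abundance.
#' Abundances per gram dry sediment are converted to cells per cm3 bulk
#' sediment via the dry density and solid volume fraction.
#'
#' @param rate bulk rate (umol substrate cm-3 bulk yr-1)
#' @param abundance cell abundance, in the unit named by
#'   \code{abundance_unit}
#' @param abundance_unit \code{"cells_g"} (per g dry sediment) or
#'   \code{"cells_cm3"} (per cm3 bulk)
#' @param rho_dry dry-sediment density (g cm-3)
#' @param porosity porosity fraction
#' @return fmol substrate cell-1 d-1
#' @export
cell_specific_rate <- function(rate, abundance,
                               abundance_unit = c("cells_g", "cells_cm3"),
                               rho_dry = 2.5, porosity = 0.8) {
  abundance_unit <- match.arg(abundance_unit)
  if (any(abundance <= 0))
    stop("division guard: cell abundance must be > 0", call. = FALSE)
  cells_cm3 <- if (abundance_unit == "cells_g")
    abundance * rho_dry * (1 - porosity) else abundance
  # umol cm-3 yr-1 -> fmol cell-1 d-1
  rate / cells_cm3 * 1e9 / 365.25
}

#' Cell-specific proton-pumping rate
#'
#' Converts a cell-specific catabolic rate to the rate of protons
#' translocated across the membrane, assuming \code{n_H} protons pumped per
#' NH4+ oxidised.
#'
#' @param cell_rate fmol NH4+ cell-1 d-1
#' @param n_H protons translocated per NH4+ (default 4)
#' @return protons cell-1 s-1
#' @examples
#' proton_pumping_rate(0.1)    # ~2,800 protons per cell per second
#' proton_pumping_rate(0.001)  # ~28
#' @export
proton_pumping_rate <- function(cell_rate, n_H = 4) {
  if (any(cell_rate < 0))
    stop("cell_rate must be >= 0", call. = FALSE)
  if (n_H <= 0) stop("n_H must be > 0", call. = FALSE)
  cell_rate * 1e-15 * 6.022e23 * n_H / 86400
}
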