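#' Six-reaction diagenetic kinetic network
#'
#' Assembles the stoichiometry matrix and kinetic constants for the two
#' reaction sets of the nitrogen-manganese diagenetic model: primary
#' organic-matter degradation pathways -- aerobic respiration (R1),
#' heterotrophic denitrification (R2) and dissimilatory MnO2 reduction (R3)
#' -- and secondary redox reactions -- nitrification (R4), Mn(II) oxidation
#' by O2 (R5) and anammox (R6).
#'
#' Primary rates are first-order in organic carbon with Monod limitation on
#' the terminal electron acceptor and hyperbolic inhibition by the
#' energetically superior acceptors above it in the redox cascade.
#' Secondary rates are bimolecular. Anammox consumes nitrate at the overall
#' electron-balanced 5 NH4+ : 3 NO3- stoichiometry (nitrite implicit, see
#' \code{\link{anammox_stoichiometry}}) and is hyperbolically inhibited by
#' oxygen. Organic matter carries \code{r_NC} mol N per mol C, released as
#' NH4+ during all three degradation pathways. Dinitrogen is carried as a
#' bookkeeping row (not transported) so that the matrix conserves N atoms
#' exactly; conservation of N and Mn is asserted at construction.
#'
#' @param k_TOC first-order organic-carbon decay constant (yr-1)
#' @param K_O2,K_NO3 Monod half-saturation constants (uM)
#' @param K_MnO2 Monod half-saturation for MnO2 (umol g-1 dry sediment)
#' @param Kin_O2,Kin_NO3 hyperbolic inhibition constants (uM)
#' @param k_nit,k_mnox,k_amx bimolecular rate constants (uM-1 yr-1)
#' @param r_NC organic-matter N:C molar ratio, in (0, 1)
#' @param rho_dry dry-sediment grain density (g cm-3) coupling solid and
#'   porewater units
#' @return an object of class \code{reaction_network}
#' @examples
#' net <- reaction_network()
#' net$stoich
#' @export
reaction_network <- function(k_TOC = 2e-5,
                             K_O2 = 8, K_NO3 = 5, K_MnO2 = 10,
                             Kin_O2 = 8, Kin_NO3 = 5,
                             k_nit = 1, k_mnox = 0.5, k_amx = 1,
                             r_NC = 16 / 106, rho_dry = 2.5) {
  pars <- c(k_TOC = k_TOC, K_O2 = K_O2, K_NO3 = K_NO3, K_MnO2 = K_MnO2,
            Kin_O2 = Kin_O2, Kin_NO3 = Kin_NO3, k_nit = k_nit,
            k_mnox = k_mnox, k_amx = k_amx, rho_dry = rho_dry)
  if (any(pars <= 0))
    stop("invalid configuration: all kinetic constants must be > 0 (",
         paste(names(pars)[pars <= 0], collapse = ", "), ")", call. = FALSE)
  if (r_NC <= 0 || r_NC >= 1)
    stop("invalid configuration: r_NC must lie in (0, 1)", call. = FALSE)

  amx <- anammox_stoichiometry("nitrate_coupled")
  # columns R1..R6; units: per mol C oxidised (R1-R3), per mol NH4+ (R4, R6),
  # per mol Mn2+ (R5)
  stoich <- rbind(
    O2   = c(-1,     0,     0,   -2, -0.5,  0),
    NO3  = c( 0,  -0.8,     0,    1,    0,  amx["NO3"]),
    NH4  = c(r_NC, r_NC, r_NC,  -1,    0,  amx["NH4"]),
    Mn2  = c( 0,     0,     2,    0,   -1,  0),
    DIC  = c( 1,     1,     1,    0,    0,  0),
    TOC  = c(-1,    -1,    -1,    0,    0,  0),
    MnO2 = c( 0,     0,    -2,    0,    1,  0),
    N2   = c( 0,   0.4,     0,    0,    0,  amx["N2"]))
  colnames(stoich) <- paste0("R", 1:6)

  net <- structure(
    c(as.list(pars), list(r_NC = r_NC, stoich = stoich)),
    class = "reaction_network")
  check_atom_conservation(net)
  net
}

# N and Mn atom balance of every reaction column; organic N rides on the
# TOC column at r_NC mol N per mol C
check_atom_conservation <- function(net, tol = 1e-12) {
  s <- net$stoich
  n_bal <- s["NO3", ] + s["NH4", ] + 2 * s["N2", ] + net$r_NC * s["TOC", ]
  mn_bal <- s["Mn2", ] + s["MnO2", ]
  if (any(abs(n_bal) > tol))
    stop("stoichiometry does not conserve N in ",
         paste(colnames(s)[abs(n_bal) > tol], collapse = ", "), call. = FALSE)
  if (any(abs(mn_bal) > tol))
    stop("stoichiometry does not conserve Mn in ",
         paste(colnames(s)[abs(mn_bal) > tol], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Diagenetic reaction network (R1 aerobic, R2 denitrification,",
      "R3 MnO2 reduction,\n  R4 nitrification, R5 Mn2+ oxidation, R6 anammox)\n")
  cat(sprintf("  k_TOC = %g /yr, k_nit = %g, k_mnox = %g, k_amx = %g /uM/yr\n",
              x$k_TOC, x$k_nit, x$k_mnox, x$k_amx))
  cat(sprintf("  K_O2 = %g, K_NO3 = %g uM, K_MnO2 = %g umol/g; Kin_O2 = %g, Kin_NO3 = %g uM\n",
              x$K_O2, x$K_NO3, x$K_MnO2, x$Kin_O2, x$Kin_NO3))
  cat(sprintf("  r_NC = %.4f mol N / mol C, rho_dry = %g g/cm3\n",
              x$r_NC, x$rho_dry))
  invisible(x)
}

#' Anammox stoichiometry in canonical or nitrate-coupled form
#'
#' The canonical anammox reaction oxidises ammonium with nitrite,
#' NH4+ + NO2- -> N2 + 2 H2O, and is the form used for thermodynamic
#' calculations. Because porewater nitrite is typically undetectable in
#' these sediments, the transport model instead uses the electron-balanced
#' overall coupling with nitrate, 5 NH4+ + 3 NO3- -> 4 N2 + 9 H2O + 2 H+,
#' in which nitrite is an implicit intermediate. Coefficients are
#' normalised per mol NH4+ consumed.
#'
#' @param mode \code{"nitrite_canonical"} or \code{"nitrate_coupled"}
#' @return named numeric vector of stoichiometric coefficients per mol NH4+
#'   (negative = consumed)
#' @examples
#' anammox_stoichiometry("nitrate_coupled")
#' @export
anammox_stoichiometry <- function(mode = c("nitrate_coupled",
                                           "nitrite_canonical")) {
  mode <- match.arg(mode)
  if (mode == "nitrite_canonical")
    c(NH4 = -1, NO2 = -1, N2 = 1, H2O = 2, H = 0)
  else
    c(NH4 = -1, NO3 = -3 / 5, N2 = 4 / 5, H2O = 9 / 5, H = 2 / 5)
}

# unit conversions between native solid units and bulk umol cm-3
.toc_umol_per_g <- function(wtpct) wtpct * 1e4 / 12.011
.umol_g_to_wtpct_factor <- 12.011 / 1e4

#' Kinetic rates of the six diagenetic reactions
#'
#' Evaluates R1..R6 from local concentrations. Accepts either a named
#' vector (one depth) or a matrix with one row per depth and the seven
#' species as columns. Solutes are in uM, TOC in wt\% dry sediment, MnO2 in
#' umol g-1 dry sediment. Rates are returned per unit bulk sediment volume
#' (umol cm-3 bulk yr-1): R1-R3 as mol C oxidised, R4 and R6 as mol NH4+
#' turned over, R5 as mol Mn2+ oxidised.
#'
#' @param state named concentration vector or matrix (columns O2, NO3, NH4,
#'   Mn2, DIC, TOC, MnO2)
#' @param net a \code{\link{reaction_network}}
#' @param porosity porosity fraction(s), recycled along depths
#' @return matrix (depths x 6) of rates, columns R1..R6
#' @export
reaction_rates <- function(state, net, porosity) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1,
                                           dimnames = list(NULL, names(state)))
  miss <- setdiff(.species_order, colnames(state))
  if (length(miss))
    stop("state is missing species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(state < 0, na.rm = TRUE))
    stop("domain error: negative concentrations passed to reaction_rates",
         call. = FALSE)
  phi <- rep_len(porosity, nrow(state))
  if (any(phi <= 0 | phi >= 1))
    stop("invalid configuration: porosity must lie in (0, 1)", call. = FALSE)

  O2 <- state[, "O2"]; NO3 <- state[, "NO3"]; NH4 <- state[, "NH4"]
  Mn2 <- state[, "Mn2"]; TOC <- state[, "TOC"]; MnO2 <- state[, "MnO2"]

  # solid pools expressed per bulk volume
  toc_bulk <- .toc_umol_per_g(TOC) * net$rho_dry * (1 - phi)   # umol C cm-3
  f_O2   <- O2 / (net$K_O2 + O2)
  f_NO3  <- NO3 / (net$K_NO3 + NO3)
  f_MnO2 <- MnO2 / (net$K_MnO2 + MnO2)
  i_O2   <- net$Kin_O2 / (net$Kin_O2 + O2)
  i_NO3  <- net$Kin_NO3 / (net$Kin_NO3 + NO3)

  # secondary bimolecular rates are per porewater volume (uM yr-1);
  # x 1e-3 x phi converts to bulk umol cm-3 yr-1
  pw2bulk <- 1e-3 * phi
  cbind(
    R1 = net$k_TOC * toc_bulk * f_O2,
    R2 = net$k_TOC * toc_bulk * f_NO3 * i_O2,
    R3 = net$k_TOC * toc_bulk * f_MnO2 * i_O2 * i_NO3,
    R4 = net$k_nit * O2 * NH4 * pw2bulk,
    R5 = net$k_mnox * O2 * Mn2 * pw2bulk,
    R6 = net$k_amx * NH4 * NO3 * i_O2 * pw2bulk)
}
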