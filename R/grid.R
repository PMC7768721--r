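#' Build a one-dimensional sediment grid
#'
#' Constructs the uniform finite-volume grid used by the steady-state
#' diagenetic solver: cell-centre depths, an exponential compaction porosity
#' profile and a step bioturbation profile.
#'
#' Porosity follows \eqn{\phi(z) = \phi_\infty + (\phi_0 - \phi_\infty)
#' e^{-z/\lambda}} with attenuation length \eqn{\lambda}. Bioturbation mixing
#' is constant (\code{Db0}) down to \code{zbio} and zero below, reflecting
#' the shallow (<10 cm) reach of benthic animals in deep-sea muds. Solute
#' advection is set equal to the solid burial velocity \code{w}
#' (constant-compaction simplification; at gravity-core scale w ~ 2 cm/ky
#' advection is nearly negligible relative to diffusion).
#'
#' @param domain_length total modelled depth (cm below seafloor)
#' @param n_cells number of uniform finite-volume cells (>= 10)
#' @param porosity_surface porosity at the sediment-water interface (fraction)
#' @param porosity_deep asymptotic deep porosity (fraction)
#' @param attenuation e-folding depth of compaction (cm)
#' @param temperature in-situ temperature (degrees C)
#' @param pressure in-situ pressure (bar)
#' @param salinity salinity (PSU)
#' @param w burial velocity (cm yr-1)
#' @param Db0 bioturbation mixing coefficient in the mixed layer (cm2 yr-1)
#' @param zbio bioturbation depth (cm); Db = 0 below it
#' @return an object of class \code{sediment_grid}
#' @examples
#' g <- build_grid(300, n_cells = 100)
#' head(g$depths)
#' @export
build_grid <- function(domain_length, n_cells = 200L,
                       porosity_surface = 0.85, porosity_deep = 0.75,
                       attenuation = 50, temperature = 2, pressure = 250,
                       salinity = 35, w = 0.002, Db0 = 0.1, zbio = 10) {
  if (!is.numeric(domain_length) || domain_length <= 0)
    stop("invalid configuration: domain_length must be > 0", call. = FALSE)
  n_cells <- as.integer(n_cells)
  if (n_cells < 10L)
    stop("invalid configuration: n_cells must be >= 10", call. = FALSE)
  if (!(porosity_deep > 0 && porosity_deep <= porosity_surface &&
        porosity_surface < 1))
    stop("invalid configuration: require 0 < porosity_deep <= porosity_surface < 1",
         call. = FALSE)
  if (attenuation <= 0)
    stop("invalid configuration: attenuation must be > 0", call. = FALSE)
  if (Db0 < 0 || zbio < 0)
    stop("invalid configuration: Db0 and zbio must be >= 0", call. = FALSE)

  h <- domain_length / n_cells
  depths <- (seq_len(n_cells) - 0.5) * h
  phi <- porosity_deep + (porosity_surface - porosity_deep) *
    exp(-depths / attenuation)
  Db <- ifelse(depths <= zbio, Db0, 0)

  structure(
    list(depths = depths, cell_thickness = h, n_cells = n_cells,
         domain_length = domain_length, porosity = phi,
         porosity_surface = porosity_surface, porosity_deep = porosity_deep,
         attenuation = attenuation,
         temperature = temperature, pressure = pressure, salinity = salinity,
         burial_velocity = w, bioturbation_coeff = Db,
         bioturbation_depth = zbio, Db0 = Db0),
    class = "sediment_grid")
}

#' @export
print.sediment_grid <- function(x, ...) {
  cat("Sediment grid:", x$n_cells, "cells over", x$domain_length, "cm",
      sprintf("(h = %.3g cm)\n", x$cell_thickness))
  cat(sprintf("  porosity %.3f (surface) -> %.3f (deep), attenuation %g cm\n",
              x$porosity_surface, x$porosity_deep, x$attenuation))
  cat(sprintf("  T = %g degC, P = %g bar, S = %g PSU, w = %g cm/yr, Db0 = %g cm2/yr (zbio %g cm)\n",
              x$temperature, x$pressure, x$salinity, x$burial_velocity,
              x$Db0, x$bioturbation_depth))
  invisible(x)
}

#' Porosity at arbitrary depth for a grid's compaction profile
#'
#' @param grid a \code{sediment_grid}
#' @param z depths (cm)
#' @return porosity fractions at \code{z}
#' @export
porosity_at <- function(grid, z) {
  grid$porosity_deep + (grid$porosity_surface - grid$porosity_deep) *
    exp(-z / grid$attenuation)
}

#' Tortuosity-corrected sediment diffusivity
#'
#' Converts a free-solution diffusion coefficient to an effective sediment
#' diffusivity with the Boudreau relation \eqn{D_s = D_0 / (1 - 2\ln\phi)},
#' the de-facto standard closure for fine-grained muds.
#'
#' @param D0 free-solution diffusivity (cm2 yr-1) at in-situ temperature
#' @param porosity porosity fraction(s), strictly in (0, 1)
#' @return sediment diffusivity (cm2 yr-1), same length as the longer input
#' @examples
#' tortuosity_corrected_diffusivity(300, exp(-1))  # denominator is exactly 3
#' @export
tortuosity_corrected_diffusivity <- function(D0, porosity) {
  if (any(D0 <= 0))
    stop("invalid configuration: D0 must be > 0", call. = FALSE)
  if (any(porosity <= 0 | porosity >= 1))
    stop("invalid configuration: porosity must lie strictly in (0, 1)",
         call. = FALSE)
  D0 / (1 - 2 * log(porosity))
}

#' Species table for the seven-species diagenetic model
#'
#' The five solutes (O2, NO3-, NH4+, Mn2+, DIC) carry free-solution
#' diffusivities at cold deep-sea temperature (~2 degC); the two solids
#' (TOC as wt\% dry sediment, MnO2 as umol per g dry sediment) do not
#' diffuse in porewater and are mixed only by bioturbation.
#'
#' @param D0 optionally override the named diffusivity vector (cm2 yr-1)
#' @return a data.frame with columns name, phase, unit, D0
#' @export
species_table <- function(D0 = NULL) {
  d0_default <- c(O2 = 380, NO3 = 310, NH4 = 320, Mn2 = 100, DIC = 190)
  if (!is.null(D0)) {
    bad <- setdiff(names(D0), names(d0_default))
    if (length(bad))
      stop("invalid configuration: unknown solute(s) in D0: ",
           paste(bad, collapse = ", "), call. = FALSE)
    d0_default[names(D0)] <- D0
  }
  if (any(d0_default <= 0))
    stop("invalid configuration: solute diffusivities must be > 0",
         call. = FALSE)
  data.frame(
    name  = c("O2", "NO3", "NH4", "Mn2", "DIC", "TOC", "MnO2"),
    phase = c(rep("solute", 5), "solid", "solid"),
    unit  = c(rep("uM", 5), "wt%", "umol/g"),
    D0    = c(unname(d0_default), NA_real_, NA_real_),
    stringsAsFactors = FALSE)
}

# canonical species order used throughout the solver
.species_order <- c("O2", "NO3", "NH4", "Mn2", "DIC", "TOC", "MnO2")
.solutes <- c("O2", "NO3", "NH4", "Mn2", "DIC")
.solids <- c("TOC", "MnO2")
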