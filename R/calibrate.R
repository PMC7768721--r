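#' Calibrate the anammox rate constant against a measured profile
#'
#' One-dimensional least-squares calibration of \code{k_amx}: for each
#' candidate value the steady-state model is re-solved (warm-started from
#' the previous solution) and the sum of squared NO3 + NH4 misfits at the
#' measured depths is minimised by golden-section search on a log10 scale.
#' This is the scripted counterpart of visual model tuning; the attained
#' RMSE is always reported alongside the estimate.
#'
#' @param profile a \code{\link{porewater_profile}} with NO3 and NH4 series
#' @param grid the \code{\link{build_grid}} used for the fit
#' @param net \code{\link{reaction_network}} holding all other constants
#' @param bcs boundary conditions
#' @param interval multiplicative search range around \code{net$k_amx}
#' @param rel_tol convergence tolerance of the line search (in log10 units)
#' @return list with \code{k_amx}, \code{rmse} (named, uM) and
#'   \code{objective}
#' @export
fit_k_amx <- function(profile, grid, net = reaction_network(),
                      bcs = default_boundary_conditions(),
                      interval = c(1 / 30, 30), rel_tol = 1e-4) {
  warm <- new.env(parent = emptyenv())
  warm$x0 <- NULL
  objective <- function(log10k) {
    net$k_amx <- 10^log10k
    sol <- solve_steady_state(grid, net = net, bcs = bcs, x0 = warm$x0)
    warm$x0 <- as.matrix(sol$concentrations[.species_order])
    warm$sol <- sol
    rmse_model_vs_data(sol, profile, "NO3")^2 +
      rmse_model_vs_data(sol, profile, "NH4")^2
  }
  rng <- log10(net$k_amx) + log10(sort(interval))
  opt <- stats::optimize(objective, rng, tol = rel_tol)
  k_hat <- 10^opt$minimum
  objective(opt$minimum)   # leave warm$sol at the optimum
  list(k_amx = k_hat,
       rmse = c(NO3 = rmse_model_vs_data(warm$sol, profile, "NO3"),
                NH4 = rmse_model_vs_data(warm$sol, profile, "NH4")),
       objective = opt$objective)
}
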