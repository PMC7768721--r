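#' Boundary conditions for the reaction-transport model
#'
#' Each of the seven species needs exactly one condition at the top
#' (sediment-water interface) and one at the bottom of the domain. Kinds are
#' \code{fixed_concentration} (Dirichlet, in the species' native unit),
#' \code{fixed_flux} (umol cm-2 yr-1, positive downward) and
#' \code{zero_gradient} (no diffusive flux). Fixed-flux conditions for
#' solids are only admitted at the top (depositional rain).
#'
#' @param ... named per-species overrides, each a list with elements
#'   \code{top} and/or \code{bottom}, themselves \code{list(kind =, value =)}
#' @return a validated list of class \code{rt_boundary_conditions}
#' @examples
#' bcs <- default_boundary_conditions(NH4 = list(
#'   bottom = list(kind = "fixed_concentration", value = 400)))
#' @export
default_boundary_conditions <- function(...) {
  bc <- function(kind, value = NA_real_) list(kind = kind, value = value)
  base <- list(
    O2   = list(top = bc("fixed_concentration", 300),
                bottom = bc("zero_gradient")),
    NO3  = list(top = bc("fixed_concentration", 20),
                bottom = bc("zero_gradient")),
    NH4  = list(top = bc("fixed_concentration", 0),
                bottom = bc("fixed_concentration", 300)),
    Mn2  = list(top = bc("fixed_concentration", 0),
                bottom = bc("zero_gradient")),
    DIC  = list(top = bc("fixed_concentration", 2300),
                bottom = bc("zero_gradient")),
    TOC  = list(top = bc("fixed_concentration", 1.5),
                bottom = bc("zero_gradient")),
    MnO2 = list(top = bc("fixed_concentration", 0.5),
                bottom = bc("zero_gradient")))
  over <- list(...)
  for (sp in names(over)) {
    if (!sp %in% .species_order)
      stop("invalid configuration: unknown species in boundary conditions: ",
           sp, call. = FALSE)
    for (edge in names(over[[sp]])) base[[sp]][[edge]] <- over[[sp]][[edge]]
  }
  validate_boundary_conditions(base)
}

validate_boundary_conditions <- function(bcs) {
  kinds <- c("fixed_concentration", "fixed_flux", "zero_gradient")
  for (sp in .species_order) {
    if (is.null(bcs[[sp]]) || is.null(bcs[[sp]]$top) || is.null(bcs[[sp]]$bottom))
      stop("invalid configuration: species ", sp,
           " needs one boundary condition per edge", call. = FALSE)
    for (edge in c("top", "bottom")) {
      b <- bcs[[sp]][[edge]]
      if (!b$kind %in% kinds)
        stop("invalid configuration: unknown boundary kind '", b$kind,
             "' for ", sp, " ", edge, call. = FALSE)
      if (b$kind != "zero_gradient" && !is.finite(b$value))
        stop("invalid configuration: ", sp, " ", edge,
             " requires a finite value", call. = FALSE)
      if (b$kind == "fixed_flux" && edge == "bottom" && sp %in% .solids)
        stop("invalid configuration: fixed_flux for solids only at top (",
             sp, ")", call. = FALSE)
    }
  }
  structure(bcs, class = "rt_boundary_conditions")
}

# Precompute everything geometry/species dependent so the residual is cheap.
# Units: solute concentrations uM, solid concentrations native (wt% TOC,
# umol/g MnO2); all fluxes umol cm-2 yr-1, positive downward; residuals per
# cell in umol cm-2 yr-1.
.make_discretization <- function(grid, net, bcs, species, source_fn = NULL) {
  n <- grid$n_cells
  h <- grid$cell_thickness
  zf <- seq(0, grid$domain_length, by = h)          # n + 1 faces
  phi_f <- porosity_at(grid, zf)
  phi_c <- grid$porosity
  w <- grid$burial_velocity
  Db_f <- ifelse(zf <= grid$bioturbation_depth, grid$Db0, 0)

  d0 <- stats::setNames(species$D0[match(.solutes, species$name)], .solutes)
  Ds_f <- lapply(d0, function(D) tortuosity_corrected_diffusivity(D, phi_f))

  # native-unit -> umol cm-3 conversion factors along the flux expressions
  conv <- c(O2 = 1e-3, NO3 = 1e-3, NH4 = 1e-3, Mn2 = 1e-3, DIC = 1e-3,
            TOC = 1e4 / 12.011, MnO2 = 1)

  list(n = n, h = h, zf = zf, phi_f = phi_f, phi_c = phi_c, w = w,
       Db_f = Db_f, Ds_f = Ds_f, conv = conv, bcs = bcs, net = net,
       stoich = net$stoich[.species_order, , drop = FALSE],
       rho = net$rho_dry, source_fn = source_fn)
}

# Per-species face fluxes for the full column; X is the n x 7 state matrix.
.species_fluxes <- function(X, disc) {
  n <- disc$n; h <- disc$h
  out <- matrix(0, n + 1, length(.species_order),
                dimnames = list(NULL, .species_order))
  for (sp in .species_order) {
    C <- X[, sp]
    b <- disc$bcs[[sp]]
    solute <- sp %in% .solutes
    if (solute) {
      mob_f <- disc$phi_f
      D_f <- disc$Ds_f[[sp]]
      v <- disc$w                       # porewater advection = burial
      unit <- disc$conv[[sp]]
    } else {
      mob_f <- (1 - disc$phi_f) * disc$rho
      D_f <- disc$Db_f
      v <- disc$w
      unit <- disc$conv[[sp]]
    }
    F <- numeric(n + 1)
    # internal faces: central diffusion, upwind advection (w > 0 downward)
    i <- seq_len(n - 1)
    F[i + 1] <- mob_f[i + 1] * (-D_f[i + 1] * (C[i + 1] - C[i]) / h + v * C[i])
    # top face
    F[1] <- switch(b$top$kind,
      fixed_concentration = mob_f[1] *
        (-D_f[1] * (C[1] - b$top$value) / (h / 2) + v * b$top$value),
      zero_gradient = mob_f[1] * v * C[1],
      fixed_flux = b$top$value / unit)
    # bottom face
    F[n + 1] <- switch(b$bottom$kind,
      fixed_concentration = mob_f[n + 1] *
        (-D_f[n + 1] * (b$bottom$value - C[n]) / (h / 2) + v * C[n]),
      zero_gradient = mob_f[n + 1] * v * C[n],
      fixed_flux = b$bottom$value / unit)
    out[, sp] <- F * unit
  }
  out
}

# residual of the steady-state balance, one entry per (cell, species),
# ordered cell-major to keep the Jacobian banded
.rt_residual <- function(x, disc) {
  n <- disc$n
  X <- matrix(pmax(x, 0), nrow = n, byrow = TRUE,
              dimnames = list(NULL, .species_order))
  Fl <- .species_fluxes(X, disc)
  if (is.null(disc$source_fn)) {
    R <- reaction_rates(X, disc$net, disc$phi_c)         # n x 6, bulk units
    src <- R %*% t(disc$stoich[, colnames(R), drop = FALSE]) # n x 7
  } else {
    src <- disc$source_fn(X, disc)
  }
  res <- Fl[seq_len(n), , drop = FALSE] -
         Fl[seq_len(n) + 1, , drop = FALSE] + src * disc$h
  as.vector(t(res))
}

# finite-difference Jacobian via 3-colour x 7-species column grouping:
# column (i, j) only touches residual rows in cells i-1..i+1
.rt_jacobian <- function(x, f0, disc, eps_sp) {
  n <- disc$n; ns <- length(.species_order)
  idx <- function(i, j) (i - 1L) * ns + j
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (cc in 0:2) for (j in seq_len(ns)) {
    cells <- seq.int(cc + 1L, n, by = 3L)
    cols <- idx(cells, j)
    dx <- numeric(length(x))
    dx[cols] <- eps_sp[j]
    f1 <- .rt_residual(x + dx, disc)
    for (k in seq_along(cells)) {
      i <- cells[k]
      nb <- i + c(-1L, 0L, 1L)
      nb <- nb[nb >= 1L & nb <= n]
      rows <- c(idx(i, seq_len(ns)), idx(setdiff(nb, i), j))
      vals <- (f1[rows] - f0[rows]) / eps_sp[j]
      keep <- vals != 0 | rows == cols[k]   # always keep the diagonal
      ii <- c(ii, rows[keep]); jj <- c(jj, rep(cols[k], sum(keep)))
      vv <- c(vv, vals[keep])
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                       dims = c(length(x), length(x)))
}

#' Solve the coupled steady-state reaction-transport problem
#'
#' Discretizes the diagenetic conservation equations on a uniform
#' finite-volume grid -- for solutes
#' \eqn{0 = \partial_z(\phi D_s \partial_z C) - \partial_z(\phi u C) +
#' \Sigma\nu R}, for solids
#' \eqn{0 = \partial_z((1-\phi) D_b \partial_z S) - \partial_z((1-\phi) w S)
#' + \Sigma\nu R} -- and solves the coupled nonlinear system for all seven
#' species simultaneously by damped Newton iteration (numerical banded
#' Jacobian, sparse direct solve) with a pseudo-transient continuation
#' fallback whose time step grows geometrically as the iteration stabilises.
#' Advection is upwinded; Dirichlet conditions enter through half-cell ghost
#' fluxes, zero-gradient through mirrored ghosts, fixed-flux by direct face
#' substitution. Negative iterates are clipped to zero; the solve fails if
#' the clipped mass at convergence exceeds \code{clip_tol}.
#'
#' @param grid a \code{\link{build_grid}} object
#' @param net a \code{\link{reaction_network}}
#' @param bcs boundary conditions, see
#'   \code{\link{default_boundary_conditions}}
#' @param species species/diffusivity table from \code{\link{species_table}}
#' @param tol relative residual tolerance (2-norm, relative to the initial
#'   residual)
#' @param max_iter maximum Newton/pseudo-transient iterations
#' @param clip_tol largest admissible negative excursion (uM-equivalent) at
#'   convergence
#' @param x0 optional warm-start state matrix (n_cells x 7, native units)
#' @param source_fn optional override of the reaction source: a
#'   \code{function(X, disc)} returning an n_cells x 7 matrix of bulk
#'   source terms (umol cm-3 yr-1); used for verification against closed
#'   forms. When supplied, the kinetic network is bypassed.
#' @param quiet suppress per-iteration progress
#' @return an object of class \code{rt_solution}: concentration profiles,
#'   per-reaction rate profiles (umol cm-3 bulk yr-1), boundary fluxes
#'   (umol cm-2 yr-1, positive downward), residual norm and convergence
#'   diagnostics
#' @export
solve_steady_state <- function(grid, net = reaction_network(),
                               bcs = default_boundary_conditions(),
                               species = species_table(),
                               tol = 1e-10, max_iter = 200L,
                               clip_tol = 1e-6, x0 = NULL, source_fn = NULL,
                               quiet = TRUE) {
  disc <- .make_discretization(grid, net, bcs, species, source_fn)
  n <- disc$n; ns <- length(.species_order)

  scale_sp <- vapply(.species_order, function(sp) {
    b <- disc$bcs[[sp]]
    vals <- c(if (b$top$kind == "fixed_concentration") b$top$value,
              if (b$bottom$kind == "fixed_concentration") b$bottom$value)
    max(abs(vals), 1)
  }, numeric(1))

  if (is.null(x0)) {
    X <- sapply(.species_order, function(sp) {
      b <- disc$bcs[[sp]]
      vt <- if (b$top$kind == "fixed_concentration") b$top$value else NA
      vb <- if (b$bottom$kind == "fixed_concentration") b$bottom$value else NA
      if (is.na(vt)) vt <- if (is.na(vb)) 0 else vb
      if (is.na(vb)) vb <- vt
      vt + (vb - vt) * grid$depths / grid$domain_length
    })
  } else {
    X <- x0[, .species_order, drop = FALSE]
  }
  x <- as.vector(t(X))

  eps_sp <- sqrt(.Machine$double.eps) * scale_sp
  capvec <- rep(disc$h, n * ns)   # pseudo-time capacity scale per unknown

  f <- .rt_residual(x, disc)
  fnorm <- sqrt(sum(f^2))
  f0norm <- max(fnorm, .Machine$double.xmin)
  target <- max(tol * f0norm, 1e-11)   # absolute floor, umol cm-2 yr-1
  history <- fnorm
  dt <- Inf
  clip_mass <- 0
  it <- 0L
  while (fnorm > target && it < max_iter) {
    it <- it + 1L
    J <- .rt_jacobian(x, f, disc, eps_sp)
    A <- if (is.finite(dt)) J + Matrix::Diagonal(x = capvec / dt) else J
    dx <- tryCatch(as.numeric(Matrix::solve(A, -f)),
                   error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(dx) && all(is.finite(dx))) {
      lambda <- 1
      for (ls in 1:12) {
        xn <- x + lambda * dx
        clip <- -pmin(xn, 0)
        xn <- pmax(xn, 0)
        fn <- .rt_residual(xn, disc)
        fnn <- sqrt(sum(fn^2))
        if (is.finite(fnn) && (fnn < fnorm * (1 - 1e-4 * lambda) ||
                               fnn < target)) {
          x <- xn; f <- fn; fnorm <- fnn
          clip_mass <- max(clip)
          accepted <- TRUE
          break
        }
        lambda <- lambda / 2
      }
    }
    if (accepted) {
      if (is.finite(dt)) { dt <- dt * 5; if (dt > 1e9) dt <- Inf }
    } else {
      dt <- if (is.infinite(dt)) 50 else dt / 10
      if (dt < 1e-8) break
    }
    history <- c(history, fnorm)
    if (!quiet)
      message(sprintf("iter %3d  |F| = %.3e  dt = %s", it, fnorm,
                      if (is.finite(dt)) format(dt) else "Inf"))
  }

  converged <- fnorm <= target
  if (!converged) {
    cond <- structure(
      class = c("natzamx_convergence_error", "error", "condition"),
      list(message = sprintf(
             "steady-state solver did not converge: |F| = %.3e after %d iterations (target %.3e)",
             fnorm, it, target),
           call = sys.call(-1), residuals = history))
    stop(cond)
  }
  if (clip_mass > clip_tol)
    stop("solver failure: negative concentrations clipped by ",
         format(clip_mass), " (exceeds ", format(clip_tol), ")",
         call. = FALSE)

  X <- matrix(pmax(x, 0), nrow = n, byrow = TRUE,
              dimnames = list(NULL, .species_order))
  Fl <- .species_fluxes(X, disc)
  R <- if (is.null(source_fn)) reaction_rates(X, net, disc$phi_c) else
    matrix(0, n, 6, dimnames = list(NULL, paste0("R", 1:6)))
  src <- if (is.null(source_fn))
    R %*% t(disc$stoich[, colnames(R), drop = FALSE]) else source_fn(X, disc)
  bf <- rbind(top = Fl[1, ], bottom = Fl[n + 1, ])

  structure(
    list(grid = grid, net = net, bcs = bcs, species = species,
         concentrations = cbind(data.frame(depth_cm = grid$depths),
                                as.data.frame(X)),
         reaction_rates = R,
         net_source = src,
         boundary_fluxes = bf,
         face_fluxes = Fl,
         face_depths = disc$zf,
         residual_norm = fnorm / f0norm,
         residual_history = history,
         iterations = it,
         clip_mass = clip_mass,
         converged = TRUE),
    class = "rt_solution")
}

#' @export
print.rt_solution <- function(x, ...) {
  cat("Steady-state reaction-transport solution\n")
  cat(sprintf("  %d cells over %g cm; converged in %d iterations (relative residual %.2e)\n",
              x$grid$n_cells, x$grid$domain_length, x$iterations,
              x$residual_norm))
  pk <- which.max(x$reaction_rates[, "R6"])
  cat(sprintf("  peak anammox rate %.3g umol cm-3 yr-1 at %.1f cm\n",
              x$reaction_rates[pk, "R6"], x$grid$depths[pk]))
  invisible(x)
}

#' @export
summary.rt_solution <- function(object, ...) {
  mb <- mass_balance_report(object)
  cat("Steady-state solution summary\n")
  print(object)
  cat("\nBoundary fluxes (umol cm-2 yr-1, positive downward):\n")
  print(round(object$boundary_fluxes, 5))
  cat("\nMass balance closure (relative):\n")
  print(round(mb$species, 6))
  invisible(mb)
}

#' @export
plot.rt_solution <- function(x, which = c("O2", "NO3", "NH4", "Mn2"), ...) {
  op <- graphics::par(mfrow = c(1, length(which) + 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  z <- x$grid$depths
  for (sp in which) {
    graphics::plot(x$concentrations[[sp]], z, type = "l", ylim = rev(range(z)),
                   xlab = sp, ylab = "depth (cm)", ...)
  }
  graphics::plot(x$reaction_rates[, "R6"], z, type = "l",
                 ylim = rev(range(z)), xlab = "anammox rate",
                 ylab = "depth (cm)", ...)
  invisible(x)
}

#' Per-species and nitrogen mass-balance report
#'
#' Checks the steady-state contract of a converged solution: for every
#' species, the difference between top and bottom boundary fluxes must equal
#' the depth-integrated net reaction source/sink, and total fixed nitrogen
#' consumption must equal N2 production.
#'
#' @param sol an \code{rt_solution}
#' @param floor flux floor (umol cm-2 yr-1) used in the relative closure
#'   denominator
#' @return list with a per-species closure table and the nitrogen budget
#' @export
mass_balance_report <- function(sol, floor = 1e-8) {
  if (!inherits(sol, "rt_solution") || !isTRUE(sol$converged))
    stop("mass_balance_report needs a converged rt_solution", call. = FALSE)
  h <- sol$grid$cell_thickness
  src <- sol$net_source
  integ <- colSums(src) * h                       # umol cm-2 yr-1
  ftop <- sol$boundary_fluxes["top", ]
  fbot <- sol$boundary_fluxes["bottom", ]
  imbalance <- ftop - fbot + integ
  rel <- abs(imbalance) / pmax(pmax(abs(ftop), abs(fbot)), floor)
  species <- data.frame(
    species = .species_order,
    flux_top = unname(ftop), flux_bottom = unname(fbot),
    integrated_reaction = unname(integ),
    imbalance = unname(imbalance), relative = unname(rel))

  # nitrogen budget: organic-N release + boundary N fluxes vs N2 production
  n2_prod <- sum(sol$reaction_rates %*% sol$net$stoich["N2", ]) * h
  n_in <- (ftop["NO3"] - fbot["NO3"]) + (ftop["NH4"] - fbot["NH4"]) +
    (-sol$net$r_NC) * sum(sol$reaction_rates %*%
                            sol$net$stoich["TOC", ]) * h
  nitrogen <- c(fixed_N_supply = unname(n_in),
                N2_production = unname(2 * n2_prod),
                relative_gap = unname(abs(n_in - 2 * n2_prod) /
                                        max(abs(n_in), floor)))
  list(species = species, nitrogen = nitrogen)
}

#' Root-mean-square error between model and measured profile
#'
#' Interpolates the modelled profile of one species linearly to the measured
#' depths and returns \eqn{\sqrt{\mathrm{mean}((model - measured)^2)}} in uM.
#'
#' @param sol an \code{rt_solution}
#' @param profile a \code{\link{porewater_profile}} with the species present
#' @param species species name (e.g. \code{"NO3"})
#' @return RMSE in the species' native unit
#' @export
rmse_model_vs_data <- function(sol, profile, species) {
  if (!species %in% names(profile$concentrations))
    stop("invalid input: profile lacks a ", species, " series", call. = FALSE)
  obs <- profile$concentrations[[species]]
  keep <- is.finite(obs)
  if (!any(keep))
    stop("invalid input: empty measured profile for ", species, call. = FALSE)
  z <- profile$depths[keep]; obs <- obs[keep]
  if (any(z < 0 | z > sol$grid$domain_length))
    stop("invalid input: measured depths fall outside the model domain",
         call. = FALSE)
  mod <- stats::approx(sol$grid$depths, sol$concentrations[[species]],
                       xout = z, rule = 2)$y
  sqrt(mean((mod - obs)^2))
}
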