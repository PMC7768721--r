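# shared fixtures; everything is built in code at test time

# small grid solves quickly and is accurate enough for oracle comparisons
quick_grid <- function(n = 100, L = 300, ...) build_grid(L, n_cells = n, ...)

# uniform-porosity, no-advection grid for closed-form transport oracles
oracle_grid <- function(n, L = 100, phi = 0.8)
  build_grid(L, n_cells = n, porosity_surface = phi, porosity_deep = phi,
             w = 1e-12, Db0 = 0)

# boundary conditions exercising a single solute, all others inert-ish
single_solute_bcs <- function(species, top, bottom_kind, bottom = NA) {
  args <- list(
    list(top = list(kind = "fixed_concentration", value = top),
         bottom = list(kind = bottom_kind, value = bottom)),
    # keep NH4's default deep source out of the way
    list(bottom = list(kind = "zero_gradient", value = NA)))
  names(args) <- c(species, "NH4")
  if (species == "NH4") args <- args[1]
  do.call(default_boundary_conditions, args)
}

zero_source <- function(X, disc) matrix(0, nrow(X), ncol(X))

# zero-order consumption of one species (rate in uM/yr per porewater)
zero_order_source <- function(species, k0, phi) {
  function(X, disc) {
    out <- matrix(0, nrow(X), ncol(X),
                  dimnames = list(NULL, colnames(X)))
    out[, species] <- -k0 * 1e-3 * phi
    out
  }
}

# hand-built piecewise-linear profile (the worked NATZ example)
linear_natz_profile <- function() {
  z <- seq(0, 200, by = 10)
  no3 <- pmax(40 * (1 - z / 100), 0)
  nh4 <- pmax(40 * (z - 100) / 100, 0)
  suppressMessages(porewater_profile("LIN", z, list(NO3 = no3, NH4 = nh4)))
}

# reference synthetic core at modest resolution, computed once per test run
reference_core <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(make_core(default_core_spec(n_cells = 150)))
    cache
  }
})

# noiseless densely-sampled core for flux/NATZ consistency checks
dense_noiseless_core <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- default_core_spec(
        n_cells = 150, sample_depths = seq(2, 298, by = 2),
        noise_sd = c(O2 = 0, NO3 = 0, NH4 = 0, Mn2 = 0, DIC = 0,
                     TOC = 0, MnO2 = 0))
      cache <<- suppressMessages(make_core(spec))
    }
    cache
  }
})
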