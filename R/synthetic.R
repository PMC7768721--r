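# run fn with a private RNG stream; the session RNG state is untouched
.with_seed <- function(seed, fn) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Specification of a synthetic sediment core
#'
#' Bundles the forward-model configuration, the coring-style sample depths
#' (5-cm spacing over the upper half metre, 25-cm spacing below, as for
#' Rhizon porewater extraction from gravity cores), per-species measurement
#' noise and the seed. The defaults are the reference study conditions:
#' they produce a core with an oxic zone whose O2 is depleted between 0.4
#' and 1.2 m below seafloor, nitrate depletion just below it, and a deep
#' ammonium source -- the geochemical structure whose overlap region is the
#' NATZ.
#'
#' @param domain_length core length (cm)
#' @param n_cells forward-model grid resolution
#' @param net \code{\link{reaction_network}}
#' @param bcs \code{\link{default_boundary_conditions}}
#' @param sample_depths measurement depths (cm)
#' @param noise_sd named per-species Gaussian measurement noise (uM for
#'   solutes; native units for solids)
#' @param seed integer seed; identical seeds give identical cores
#' @param ... further arguments passed to \code{\link{build_grid}}
#' @return a list of class \code{core_spec}
#' @export
default_core_spec <- function(domain_length = 300, n_cells = 200,
                              net = reaction_network(),
                              bcs = default_boundary_conditions(),
                              sample_depths = c(seq(5, 50, by = 5),
                                                seq(75, 300, by = 25)),
                              noise_sd = c(O2 = 2, NO3 = 1, NH4 = 1,
                                           Mn2 = 2, DIC = 10, TOC = 0.05,
                                           MnO2 = 0.05),
                              seed = 1L, ...) {
  if (any(noise_sd < 0))
    stop("invalid configuration: noise_sd must be >= 0", call. = FALSE)
  if (any(sample_depths < 0 | sample_depths > domain_length))
    stop("invalid configuration: sample_depths outside the domain",
         call. = FALSE)
  structure(list(domain_length = domain_length, n_cells = n_cells,
                 net = net, bcs = bcs, sample_depths = sort(sample_depths),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 grid_args = list(...)),
            class = "core_spec")
}

#' Generate a synthetic sediment core with known truth
#'
#' Runs the steady-state forward model, samples the solution at the spec's
#' measurement depths, adds independent Gaussian noise (clipped at zero)
#' and returns the observed profile together with the full generating truth
#' (noiseless profiles, anammox rate profile, NATZ interval and boundary
#' fluxes of the model, and all generator parameters).
#'
#' @param spec a \code{\link{default_core_spec}}
#' @param site_id identifier for the emitted profile
#' @param water_depth nominal water depth (m)
#' @return list with elements \code{profile} (a
#'   \code{\link{porewater_profile}}) and \code{truth}
#' @export
make_core <- function(spec = default_core_spec(), site_id = "SYN01",
                      water_depth = 2500) {
  grid <- do.call(build_grid, c(list(domain_length = spec$domain_length,
                                     n_cells = spec$n_cells),
                                spec$grid_args))
  sol <- solve_steady_state(grid, net = spec$net, bcs = spec$bcs)

  z <- spec$sample_depths
  true_at <- lapply(.species_order, function(sp)
    stats::approx(grid$depths, sol$concentrations[[sp]], xout = z,
                  rule = 2)$y)
  names(true_at) <- .species_order

  obs <- .with_seed(spec$seed, function() {
    lapply(.species_order, function(sp) {
      sd <- spec$noise_sd[[sp]]
      if (is.null(sd) || sd == 0) return(true_at[[sp]])
      pmax(true_at[[sp]] + stats::rnorm(length(z), 0, sd), 0)
    })
  })
  names(obs) <- .species_order

  profile <- suppressMessages(porewater_profile(
    site_id, z, obs, water_depth = water_depth,
    porosity = porosity_at(grid, z), temperature = grid$temperature))

  # truth-side NATZ from the noiseless model profile on the model grid
  dense <- suppressMessages(porewater_profile(
    paste0(site_id, "_true"), grid$depths,
    list(NO3 = sol$concentrations$NO3, NH4 = sol$concentrations$NH4),
    porosity = grid$porosity, temperature = grid$temperature))
  interval <- detect_natz(dense, check_qc = FALSE)

  truth <- list(solution = sol,
                profiles = c(list(depth_cm = z), true_at),
                R6 = sol$reaction_rates[, "R6"],
                depth_R6_max = grid$depths[which.max(
                  sol$reaction_rates[, "R6"])],
                natz = interval,
                boundary_fluxes = sol$boundary_fluxes,
                parameters = spec)
  list(profile = profile, truth = truth)
}

#' Synthetic anammox-abundance profile over a transition zone
#'
#' Cell abundance is a log-scale Gaussian bump centred in the NATZ on a flat
#' background, with multiplicative lognormal noise. The defaults give a
#' peak-to-background ratio of 1e4 -- the four-orders-of-magnitude abundance
#' increase characteristic of anammox bacteria in these zones.
#'
#' @param natz a \code{\link{natz_interval}} (the bump centre is its
#'   midpoint)
#' @param depths output depths (cm)
#' @param background background abundance (cells g-1 dry sediment)
#' @param peak peak abundance at the bump centre (cells g-1)
#' @param width Gaussian standard deviation of the bump (cm)
#' @param noise_sd_log10 lognormal noise, in log10 units
#' @param seed integer seed
#' @return data.frame with depth_cm, abundance_cells_g, true_cells_g
#' @export
make_abundance_profile <- function(natz, depths, background = 1e4,
                                   peak = 1e8, width = 20,
                                   noise_sd_log10 = 0.3, seed = 1L) {
  if (!(peak >= background && background > 0))
    stop("invalid configuration: need peak >= background > 0", call. = FALSE)
  if (width <= 0)
    stop("invalid configuration: width must be > 0", call. = FALSE)
  centre <- (natz$top + natz$bottom) / 2
  l10 <- log10(background) + (log10(peak) - log10(background)) *
    exp(-(depths - centre)^2 / (2 * width^2))
  noisy <- .with_seed(seed, function()
    10^(l10 + stats::rnorm(length(depths), 0, noise_sd_log10)))
  data.frame(depth_cm = depths, abundance_cells_g = noisy,
             true_cells_g = 10^l10)
}

# piecewise-linear profile templates for literature-style sites; much
# faster than a forward-model run per site
.template_site <- function(id, natz_depth, n_points, efflux, water_depth,
                           noise_sd = 0.5, threshold = 2) {
  depth_max <- max(natz_depth * 2, natz_depth + 60)
  # always sample near the surface so the efflux classifier has points
  # above the transition zone
  z <- sort(c(0.5, stats::runif(n_points - 1, 0, depth_max)))
  no3_top <- stats::runif(1, 15, 45)
  nh4_deep <- stats::runif(1, 60, 400)
  natz_bottom <- natz_depth + stats::runif(1, 2, 0.3 * natz_depth + 10)
  no3 <- pmax(no3_top * (1 - z / natz_depth), 0)
  nh4 <- pmax(nh4_deep * (z - natz_bottom) / (depth_max - natz_bottom), 0)
  if (efflux) # ammonium escaping upward: shallow lens decaying with depth
    nh4 <- nh4 + pmax((threshold + stats::runif(1, 4, 15)) *
                        (1 - z / (0.6 * natz_depth)), 0)
  no3 <- pmax(no3 + stats::rnorm(n_points, 0, noise_sd), 0)
  nh4 <- pmax(nh4 + stats::rnorm(n_points, 0, noise_sd), 0)
  suppressMessages(porewater_profile(
    id, z, list(NO3 = no3, NH4 = nh4), water_depth = water_depth))
}

#' Generate a multi-site porewater profile collection
#'
#' Draws each site as efflux or no-efflux with the stated probability and
#' builds piecewise-linear NO3/NH4 profile templates with randomised
#' transition-zone depths spanning 1.3-460 cm and water depths 900-5,200 m
#' (the ranges seen across compiled literature sites). A controlled
#' fraction of sites is generated with fewer than the QC minimum of
#' datapoints to exercise the quality filter.
#'
#' @param n_sites number of sites
#' @param no_efflux_fraction probability that a site has no upward
#'   ammonium efflux
#' @param sparsity typical datapoints per profile
#' @param qc_fail_fraction fraction of sites deliberately generated with
#'   2-5 points (below the 6-point gate)
#' @param seed integer seed
#' @return list with \code{profiles} (list of
#'   \code{\link{porewater_profile}}) and \code{truth} (per-site labels)
#' @export
make_site_collection <- function(n_sites = 67, no_efflux_fraction = 0.84,
                                 sparsity = 12, qc_fail_fraction = 0.1,
                                 seed = 1L) {
  if (no_efflux_fraction < 0 || no_efflux_fraction > 1)
    stop("invalid configuration: no_efflux_fraction must be in [0, 1]",
         call. = FALSE)
  if (sparsity < 2)
    stop("invalid configuration: sparsity must be >= 2", call. = FALSE)
  .with_seed(seed, function() {
    ids <- sprintf("SITE%03d", seq_len(n_sites))
    efflux <- stats::runif(n_sites) > no_efflux_fraction
    few <- stats::runif(n_sites) < qc_fail_fraction
    npts <- ifelse(few, sample(2:5, n_sites, replace = TRUE),
                   pmax(6, stats::rpois(n_sites, sparsity)))
    natz_depth <- 10^stats::runif(n_sites, log10(1.3), log10(460))
    wd <- stats::runif(n_sites, 900, 5200)
    profiles <- lapply(seq_len(n_sites), function(i)
      .template_site(ids[i], natz_depth[i], npts[i], efflux[i], wd[i]))
    truth <- data.frame(site_id = ids, efflux_true = efflux,
                        designed_qc_fail = few, n_points = npts,
                        natz_depth_cm = natz_depth, water_depth_m = wd)
    list(profiles = profiles, truth = truth)
  })
}

#' Generate a synthetic genome-coverage track
#'
#' Expected read depth decreases log-linearly with distance from a fixed
#' replication origin, bidirectionally around the circular chromosome to
#' the terminus opposite it, with origin:terminus coverage ratio
#' \code{ori_ter_ratio}. The genome is cut into contiguous scaffolds and
#' overlapping windows are laid within each scaffold. Optional Poisson
#' noise draws each window's total base coverage as
#' Poisson(expected depth x window size).
#'
#' @param genome_length bp
#' @param ori_ter_ratio expected origin:terminus coverage ratio (>= 1)
#' @param n_scaffolds number of contiguous scaffolds the genome is split
#'   into
#' @param noise_model \code{"none"} or \code{"poisson"}
#' @param mean_depth genome-wide mean expected depth (x)
#' @param window_size,step window geometry (bp)
#' @param seed integer seed
#' @return list with \code{track} (a \code{\link{coverage_track}}) and
#'   \code{truth}
#' @export
make_coverage <- function(genome_length = 3e6, ori_ter_ratio = 1.3,
                          n_scaffolds = 10, noise_model = c("none",
                                                            "poisson"),
                          mean_depth = 20, window_size = 5000, step = 100,
                          seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (ori_ter_ratio < 1)
    stop("invalid configuration: ori_ter_ratio must be >= 1", call. = FALSE)
  if (mean_depth <= 0)
    stop("invalid configuration: mean_depth must be > 0", call. = FALSE)

  # scaffold boundaries: contiguous, roughly equal pieces
  cuts <- round(seq(0, genome_length, length.out = n_scaffolds + 1))
  slope <- log2(ori_ter_ratio)
  expected_at <- function(p) {  # p: 0-based genome position
    d <- pmin(p, genome_length - p) / (genome_length / 2)  # 0 at origin
    2^(-slope * d)
  }
  wins <- list()
  for (s in seq_len(n_scaffolds)) {
    L <- cuts[s + 1] - cuts[s]
    if (L < window_size) next
    starts <- seq(0, L - window_size, by = step)
    mid <- cuts[s] + starts + window_size / 2
    wins[[length(wins) + 1]] <- data.frame(
      scaffold = sprintf("scf%03d", s), start = starts,
      end = starts + window_size, rel = expected_at(mid))
  }
  w <- do.call(rbind, wins)
  w$expected <- w$rel * mean_depth / mean(w$rel)
  w$coverage <- if (noise_model == "none") w$expected else
    .with_seed(seed, function()
      stats::rpois(nrow(w), w$expected * window_size) / window_size)
  track <- coverage_track(w[c("scaffold", "start", "end", "coverage")],
                          window_size = window_size, step = step)
  list(track = track,
       truth = list(ori_ter_ratio = ori_ter_ratio,
                    genome_length = genome_length,
                    n_scaffolds = n_scaffolds, mean_depth = mean_depth,
                    noise_model = noise_model, seed = seed,
                    expected = w$expected))
}
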