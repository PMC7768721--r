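#' Read porewater profiles from a delimited table
#'
#' Wide format has columns \code{site_id}, \code{depth_cm}, one column per
#' species (uM) and optional metadata columns \code{water_depth_m},
#' \code{temperature_C}, \code{porosity} (constant within a site). Long
#' format has columns \code{site_id}, \code{depth_cm}, \code{species},
#' \code{concentration_uM}. Rows are grouped by site; unsorted depths are
#' sorted with a note, duplicate depths are an error, missing values stay
#' missing.
#'
#' @param path CSV file path
#' @param dialect \code{"wide"} or \code{"long"}
#' @return named list of \code{\link{porewater_profile}} objects
#' @export
read_profile_table <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (dialect == "wide") c("site_id", "depth_cm")
          else c("site_id", "depth_cm", "species", "concentration_uM")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("input error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  num_cols <- setdiff(names(tab), c("site_id", "species"))
  for (cl in num_cols) {
    v <- tab[[cl]]
    coerced <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(coerced))
    if (length(bad))
      stop("input error: non-numeric value in column ", cl, ", row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    tab[[cl]] <- coerced
  }
  meta_cols <- intersect(c("water_depth_m", "temperature_C", "porosity"),
                         names(tab))
  out <- lapply(split(tab, tab$site_id), function(d) {
    if (dialect == "long") {
      series <- lapply(split(d, d$species), function(s)
        stats::setNames(s$concentration_uM, NULL))
      depths_by <- lapply(split(d, d$species), `[[`, "depth_cm")
      depths <- depths_by[[1]]
      if (!all(vapply(depths_by, function(z) identical(z, depths),
                      logical(1))))
        stop("input error: species of site ", d$site_id[1],
             " measured at different depths; use wide format",
             call. = FALSE)
    } else {
      depths <- d$depth_cm
      series <- as.list(d[setdiff(names(d), c("site_id", "depth_cm",
                                              meta_cols))])
    }
    meta <- lapply(meta_cols, function(cl) d[[cl]][1])
    names(meta) <- meta_cols
    porewater_profile(
      d$site_id[1], depths, series,
      water_depth = if (!is.null(meta$water_depth_m)) meta$water_depth_m
                    else NA_real_,
      porosity = meta$porosity,
      temperature = if (!is.null(meta$temperature_C)) meta$temperature_C
                    else 2)
  })
  out
}

#' Write porewater profiles to a wide-format CSV
#'
#' Full double precision; the output is readable by
#' \code{\link{read_profile_table}}.
#'
#' @param profiles list of \code{\link{porewater_profile}} objects
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
write_profile_table <- function(profiles, path) {
  if (inherits(profiles, "porewater_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    d <- data.frame(site_id = p$site_id, depth_cm = p$depths)
    for (sp in names(p$concentrations)) d[[sp]] <- p$concentrations[[sp]]
    d$water_depth_m <- p$water_depth
    d$temperature_C <- p$temperature
    d$porosity <- rep_len(p$porosity, nrow(d))
    d
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(d) {
    d[setdiff(all_cols, names(d))] <- NA
    d[all_cols]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a coverage track from a bedGraph-like TSV
#'
#' Expects four tab-separated columns (scaffold, start, end, depth) with
#' 0-based half-open coordinates, optionally with a header line.
#'
#' @param path TSV path
#' @param window_size,step window geometry metadata (bp)
#' @return a \code{\link{coverage_track}}
#' @export
read_coverage_table <- function(path, window_size = 5000, step = 100) {
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  has_header <- grepl("scaffold|chrom", first, ignore.case = TRUE)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(tab) < 4)
      stop("input error: expected 4 columns in ", path, call. = FALSE)
    names(tab)[1:4] <- c("scaffold", "start", "end", "coverage")
  }
  if ("depth" %in% names(tab) && !"coverage" %in% names(tab))
    names(tab)[names(tab) == "depth"] <- "coverage"
  coverage_track(tab[c("scaffold", "start", "end", "coverage")],
                 window_size = window_size, step = step)
}

#' Write a coverage track as bedGraph-like TSV
#' @param track a \code{\link{coverage_track}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_coverage_table <- function(track, path) {
  utils::write.table(track$windows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a steady-state solution to CSV with a JSON sidecar
#'
#' The CSV holds per-depth concentrations (native units) and the six
#' reaction-rate profiles at full double precision; the sidecar holds
#' boundary fluxes, the residual norm and convergence metadata.
#'
#' @param sol an \code{rt_solution}
#' @param dir output directory (created if needed)
#' @param stem file stem
#' @return paths, invisibly
#' @export
write_solution <- function(sol, dir, stem = "solution") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- sol$concentrations
  names(d) <- c("depth_cm", "O2_uM", "NO3_uM", "NH4_uM", "Mn2_uM",
                "DIC_uM", "TOC_wtpct", "MnO2_umol_g")
  rates <- as.data.frame(sol$reaction_rates)
  names(rates) <- paste0(names(rates), "_umol_cm3_yr")
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(cbind(d, rates), csv, row.names = FALSE, quote = FALSE)
  meta <- list(boundary_fluxes = as.data.frame(sol$boundary_fluxes),
               residual_norm = sol$residual_norm,
               iterations = sol$iterations,
               converged = sol$converged,
               n_cells = sol$grid$n_cells,
               domain_length_cm = sol$grid$domain_length)
  js <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

# bounds used by validate_config; each entry: c(lower, upper) exclusive
.config_schema <- function() {
  list(
    grid = list(domain_length = c(0, Inf), n_cells = c(9, 1e6),
                porosity_surface = c(0, 1), porosity_deep = c(0, 1),
                attenuation = c(0, Inf), temperature = c(-5, 50),
                pressure = c(0, 2000), salinity = c(0, 50),
                w = c(0, Inf), Db0 = c(-1e-12, Inf), zbio = c(-1e-12, Inf)),
    network = list(k_TOC = c(0, Inf), K_O2 = c(0, Inf), K_NO3 = c(0, Inf),
                   K_MnO2 = c(0, Inf), Kin_O2 = c(0, Inf),
                   Kin_NO3 = c(0, Inf), k_nit = c(0, Inf),
                   k_mnox = c(0, Inf), k_amx = c(0, Inf),
                   r_NC = c(0, 1), rho_dry = c(0, 10)),
    solver = list(tol = c(0, 1), max_iter = c(0, 1e6),
                  clip_tol = c(0, Inf)),
    energetics = list(enabled = NULL, n_H = c(0, 100),
                      ionic_strength = c(-1e-12, 10), pH = c(0, 14),
                      N2_uM = c(0, Inf),
                      activity_model = c("davies", "unit")),
    seed = NULL, out_dir = NULL, log_level = NULL)
}

#' Validate and materialise a run configuration
#'
#' Reads a YAML configuration (or takes an equivalent nested list), rejects
#' unknown keys naming the offending path, checks physical bounds
#' (porosities in (0,1), positive rate constants, ...) and fills every
#' omitted key with its default so the echoed configuration is fully
#' resolved.
#'
#' @param config path to a YAML file, or a nested list
#' @return the fully-resolved configuration list, of class \code{run_config}
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config error: file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  schema <- .config_schema()
  defaults <- list(
    grid = list(domain_length = 300, n_cells = 200,
                porosity_surface = 0.85, porosity_deep = 0.75,
                attenuation = 50, temperature = 2, pressure = 250,
                salinity = 35, w = 0.002, Db0 = 0.1, zbio = 10),
    network = as.list(formals(reaction_network))[
      names(.config_schema()$network)],
    solver = list(tol = 1e-10, max_iter = 200, clip_tol = 1e-6),
    energetics = list(enabled = TRUE, n_H = 4, ionic_strength = 0.7,
                      pH = 7.8, N2_uM = 500, activity_model = "davies"),
    seed = 1L, out_dir = ".", log_level = "info")
  defaults$network$r_NC <- 16 / 106

  bad <- setdiff(names(config), names(schema))
  if (length(bad))
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (blk in intersect(names(config), c("grid", "network", "solver",
                                         "energetics"))) {
    bad <- setdiff(names(config[[blk]]), names(schema[[blk]]))
    if (length(bad))
      stop("config error: unknown key(s): ",
           paste(paste0(blk, ".", bad), collapse = ", "), call. = FALSE)
    for (k in names(config[[blk]])) defaults[[blk]][[k]] <- config[[blk]][[k]]
  }
  for (k in intersect(names(config), c("seed", "out_dir", "log_level")))
    defaults[[k]] <- config[[k]]

  for (blk in c("grid", "network", "solver", "energetics")) {
    for (k in names(schema[[blk]])) {
      bound <- schema[[blk]][[k]]
      v <- defaults[[blk]][[k]]
      if (is.null(bound) || is.null(v)) next
      if (is.character(bound)) {
        if (!v %in% bound)
          stop("config error: ", blk, ".", k, " must be one of ",
               paste(bound, collapse = ", "), call. = FALSE)
      } else if (!is.numeric(v) || v <= bound[1] || v >= bound[2]) {
        stop("config error: ", blk, ".", k, " = ", v,
             " violates bound (", bound[1], ", ", bound[2], ")",
             call. = FALSE)
      }
    }
  }
  structure(defaults, class = "run_config")
}

#' Run the full analysis pipeline on a synthetic or supplied core
#'
#' End-to-end driver: forward model, anammox energetics, NATZ detection and
#' diffusive fluxes, and summary outputs, all written to the configured
#' output directory together with a run manifest (configuration echo, seed,
#' package version) sufficient to reproduce the run. Deterministic given
#' config and seed.
#'
#' @param config a \code{\link{validate_config}} result, a YAML path, or
#'   NULL for defaults
#' @param profile optional measured \code{\link{porewater_profile}} to
#'   compare against (RMSE report); defaults to a synthetic core generated
#'   from the config seed
#' @param out_dir overrides the config output directory
#' @return list of stage results (solution, power, natz, rmse, file paths)
#' @export
run_pipeline <- function(config = NULL, profile = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "configuration"
  result <- tryCatch({
    stage <- "forward model"
    grid <- build_grid(cfg$grid$domain_length, cfg$grid$n_cells,
                       cfg$grid$porosity_surface, cfg$grid$porosity_deep,
                       cfg$grid$attenuation, cfg$grid$temperature,
                       cfg$grid$pressure, cfg$grid$salinity, cfg$grid$w,
                       cfg$grid$Db0, cfg$grid$zbio)
    net <- do.call(reaction_network, cfg$network)
    spec <- default_core_spec(domain_length = cfg$grid$domain_length,
                              n_cells = cfg$grid$n_cells, net = net,
                              seed = cfg$seed)
    core <- make_core(spec)
    sol <- core$truth$solution
    if (is.null(profile)) profile <- core$profile
    write_solution(sol, cfg$out_dir)

    stage <- "NATZ detection and fluxes"
    interval <- detect_natz(profile)
    sp <- species_table()
    d0 <- stats::setNames(sp$D0, sp$name)
    interval$no3_flux_in <- diffusive_flux(profile, "NO3", interval,
                                           "above_natz", D0 = d0[["NO3"]])
    interval$nh4_flux_in <- diffusive_flux(profile, "NH4", interval,
                                           "below_natz", D0 = d0[["NH4"]])
    interval$nh4_efflux_above <- classify_efflux(profile, interval)
    natz_df <- data.frame(top_cm = interval$top, bottom_cm = interval$bottom,
                          no3_flux_in = interval$no3_flux_in,
                          nh4_flux_in = interval$nh4_flux_in,
                          nh4_efflux_above = interval$nh4_efflux_above)
    utils::write.csv(natz_df, file.path(cfg$out_dir, "natz.csv"),
                     row.names = FALSE, quote = FALSE)

    stage <- "model-data comparison"
    rmse <- c(NO3 = rmse_model_vs_data(sol, profile, "NO3"),
              NH4 = rmse_model_vs_data(sol, profile, "NH4"))

    power <- NULL
    if (isTRUE(cfg$energetics$enabled)) {
      stage <- "energetics"
      th <- thermo_state(cfg$grid$temperature, cfg$grid$pressure,
                         cfg$energetics$ionic_strength, cfg$energetics$pH,
                         cfg$energetics$activity_model)
      rx <- anammox_stoichiometry("nitrate_coupled")
      conc <- list(NH4 = sol$concentrations$NH4,
                   NO3 = sol$concentrations$NO3,
                   N2 = rep(cfg$energetics$N2_uM, grid$n_cells))
      dG <- suppressMessages(in_situ_gibbs(rx, th, conc))
      power <- power_supply(sol$reaction_rates[, "R6"], dG,
                            depth = grid$depths)
      utils::write.csv(power, file.path(cfg$out_dir, "power.csv"),
                       row.names = FALSE, quote = FALSE)
    }

    stage <- "manifest"
    manifest <- list(package = "natzamx",
                     version = as.character(utils::packageVersion("natzamx")),
                     seed = cfg$seed,
                     config = unclass(cfg),
                     rmse_uM = as.list(rmse))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(solution = sol, profile = profile, natz = interval, power = power,
         rmse = rmse, out_dir = cfg$out_dir)
  }, error = function(e) {
    if (inherits(e, "natzamx_pipeline_error")) stop(e)
    stop(structure(class = c("natzamx_pipeline_error", "error", "condition"),
                   list(message = paste0("pipeline stage '", stage,
                                         "' failed: ", conditionMessage(e)),
                        call = conditionCall(e), stage = stage)))
  })
  result
}
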