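#' Construct a porewater depth profile
#'
#' @param site_id site identifier
#' @param depths depths in cm below seafloor; sorted if needed (with a
#'   note), duplicates are an error
#' @param concentrations named list of concentration series (uM), e.g.
#'   \code{list(NO3 = ..., NH4 = ...)}; NA marks missing values
#' @param water_depth overlying water depth (m)
#' @param porosity porosity (scalar or per-depth series); defaults to 0.8
#'   with a logged assumption note when omitted
#' @param temperature in-situ temperature (degrees C)
#' @param detection_limit named per-species detection limits (uM)
#' @return an object of class \code{porewater_profile}
#' @export
porewater_profile <- function(site_id, depths, concentrations,
                              water_depth = NA_real_, porosity = NULL,
                              temperature = 2, detection_limit = NULL) {
  if (!length(concentrations) || is.null(names(concentrations)))
    stop("invalid input: concentrations must be a named list of series",
         call. = FALSE)
  lens <- lengths(concentrations)
  if (any(lens != length(depths)))
    stop("invalid input: concentration series lengths differ from depths",
         call. = FALSE)
  if (anyDuplicated(depths))
    stop("invalid input: duplicate depths in profile ", site_id,
         call. = FALSE)
  ord <- order(depths)
  if (is.unsorted(depths)) {
    message("porewater_profile: depths for site ", site_id,
            " were unsorted; rows reordered by depth")
    depths <- depths[ord]
    concentrations <- lapply(concentrations, `[`, ord)
    if (length(porosity) > 1) porosity <- porosity[ord]
  }
  for (sp in names(concentrations)) {
    v <- concentrations[[sp]]
    if (any(v < 0, na.rm = TRUE))
      stop("invalid input: negative ", sp, " concentration in profile ",
           site_id, call. = FALSE)
  }
  assumed_porosity <- is.null(porosity)
  if (assumed_porosity) {
    message("porewater_profile: no porosity for site ", site_id,
            "; assuming 0.8")
    porosity <- 0.8
  }
  structure(list(site_id = site_id, depths = depths,
                 concentrations = concentrations,
                 water_depth = water_depth, porosity = porosity,
                 temperature = temperature,
                 detection_limit = detection_limit,
                 assumed_porosity = assumed_porosity),
            class = "porewater_profile")
}

#' @export
print.porewater_profile <- function(x, ...) {
  cat(sprintf("Porewater profile %s: %d depths (%.1f-%.1f cm), species: %s\n",
              x$site_id, length(x$depths), min(x$depths), max(x$depths),
              paste(names(x$concentrations), collapse = ", ")))
  invisible(x)
}

#' Quality filter for compiled porewater profiles
#'
#' A profile is usable for transition-zone analysis only if it has enough
#' datapoints and actually reaches the nitrate-depletion depth. Profiles
#' failing either gate are discarded from compilations with a reason code.
#'
#' @param profile a \code{\link{porewater_profile}} with a NO3 series
#' @param min_points minimum number of NO3 datapoints (default 6; fewer
#'   fails with \code{too_few_points})
#' @param depletion_threshold uM below which nitrate counts as depleted
#'   (default 2; never reached fails with \code{no_depletion})
#' @return list with elements \code{pass} and \code{reasons}
#' @export
qc_filter <- function(profile, min_points = 6, depletion_threshold = 2) {
  no3 <- profile$concentrations$NO3
  if (is.null(no3))
    stop("invalid input: profile ", profile$site_id, " has no NO3 series",
         call. = FALSE)
  no3 <- no3[is.finite(no3)]
  reasons <- character(0)
  if (length(no3) < min_points) reasons <- c(reasons, "too_few_points")
  if (length(no3) && min(no3) >= depletion_threshold)
    reasons <- c(reasons, "no_depletion")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

# first depth (scanning direction chosen by caller) where a series crosses
# below `threshold`, linearly interpolated between the bracketing samples
.cross_below <- function(z, v, threshold, from = c("top", "bottom")) {
  from <- match.arg(from)
  ok <- is.finite(v)
  z <- z[ok]; v <- v[ok]
  n <- length(z)
  if (from == "top") {
    for (i in seq_len(n)) {
      if (v[i] < threshold) {
        if (i == 1) return(z[1])
        return(z[i - 1] + (z[i] - z[i - 1]) *
                 (v[i - 1] - threshold) / (v[i - 1] - v[i]))
      }
    }
    return(NA_real_)
  }
  # from bottom: walk upward; the first sample below threshold brackets the
  # shallowest extent of detectable concentration
  for (i in rev(seq_len(n))) {
    if (v[i] < threshold) {
      if (i == n) return(z[n])
      return(z[i] + (z[i + 1] - z[i]) *
               (threshold - v[i]) / (v[i + 1] - v[i]))
    }
  }
  NA_real_
}

#' Detect the nitrate-ammonium transition zone of a profile
#'
#' Locates the NATZ as the interval spanned by (i) the depth where
#' downward-decreasing nitrate first falls below the detection threshold
#' and (ii) the shallowest extent of detectable ammonium (the depth where,
#' scanning upward from the bottom of the core, NH4+ first drops below the
#' threshold). Both crossings are linearly interpolated between bracketing
#' samples; ties take the shallowest qualifying crossing. A degenerate
#' zero-thickness interval (both crossings coincide) is allowed.
#'
#' @param profile a QC-passing \code{\link{porewater_profile}} with NO3 and
#'   NH4 series
#' @param threshold detection/depletion threshold (uM) applied to both
#'   species
#' @param check_qc run \code{\link{qc_filter}} first (default TRUE)
#' @return an object of class \code{natz_interval} with elements \code{top}
#'   and \code{bottom} (cm)
#' @export
detect_natz <- function(profile, threshold = 2, check_qc = TRUE) {
  if (check_qc) {
    qc <- qc_filter(profile, depletion_threshold = threshold)
    if (!qc$pass)
      stop("profile ", profile$site_id, " failed QC: ",
           paste(qc$reasons, collapse = ", "), call. = FALSE)
  }
  nh4 <- profile$concentrations$NH4
  if (is.null(nh4))
    stop("invalid input: profile ", profile$site_id, " has no NH4 series",
         call. = FALSE)
  if (all(nh4[is.finite(nh4)] < threshold)) {
    cond <- structure(
      class = c("natzamx_no_natz", "error", "condition"),
      list(message = paste0("no NATZ in profile ", profile$site_id,
                            ": NH4 never exceeds ", threshold, " uM"),
           call = sys.call(-1)))
    stop(cond)
  }
  z_no3 <- .cross_below(profile$depths, profile$concentrations$NO3,
                        threshold, from = "top")
  z_nh4 <- .cross_below(profile$depths, nh4, threshold, from = "bottom")
  if (is.na(z_nh4)) z_nh4 <- min(profile$depths)  # detectable to the surface
  notes <- sprintf("threshold %g uM; NO3 crossing %.3f cm; NH4 crossing %.3f cm",
                   threshold, z_no3, z_nh4)
  structure(list(top = min(z_no3, z_nh4), bottom = max(z_no3, z_nh4),
                 z_no3 = z_no3, z_nh4 = z_nh4,
                 no3_flux_in = NA_real_, nh4_flux_in = NA_real_,
                 nh4_efflux_above = NA, method_notes = notes),
            class = "natz_interval")
}

#' @export
print.natz_interval <- function(x, ...) {
  cat(sprintf("NATZ interval [%.2f, %.2f] cm (thickness %.2f cm)\n",
              x$top, x$bottom, x$bottom - x$top))
  if (is.finite(x$no3_flux_in))
    cat(sprintf("  NO3 flux in from above: %.4g umol cm-2 yr-1\n",
                x$no3_flux_in))
  if (is.finite(x$nh4_flux_in))
    cat(sprintf("  NH4 flux in from below: %.4g umol cm-2 yr-1\n",
                x$nh4_flux_in))
  invisible(x)
}

#' Fickian diffusive flux into the transition zone
#'
#' Estimates the concentration gradient by least squares over the
#' \code{n_fit_points} samples nearest the interval edge on the chosen side
#' and applies Fick's first law, \eqn{J = -\phi D_s \, dC/dz}, with the
#' tortuosity-corrected diffusivity. The sign convention is positive
#' downward, so nitrate diffusing down into the zone gives J > 0 and
#' ammonium diffusing up from below gives J < 0.
#'
#' @param profile a \code{\link{porewater_profile}}
#' @param species species name with a concentration series
#' @param interval a \code{\link{detect_natz}} interval
#' @param boundary \code{"above_natz"} or \code{"below_natz"}
#' @param D0 free-solution diffusivity (cm2 yr-1)
#' @param porosity override profile porosity (fraction)
#' @param n_fit_points number of samples in the gradient window (>= 2;
#'   default 3, the minimum leaving a regression residual)
#' @return flux in umol cm-2 yr-1, positive downward
#' @export
diffusive_flux <- function(profile, species, interval,
                           boundary = c("above_natz", "below_natz"),
                           D0, porosity = NULL, n_fit_points = 3) {
  boundary <- match.arg(boundary)
  v <- profile$concentrations[[species]]
  if (is.null(v))
    stop("invalid input: profile lacks a ", species, " series", call. = FALSE)
  ok <- is.finite(v)
  z <- profile$depths[ok]; v <- v[ok]
  if (boundary == "above_natz") {
    side <- which(z <= interval$top)
    pick <- utils::tail(side, n_fit_points)
  } else {
    side <- which(z >= interval$bottom)
    pick <- utils::head(side, n_fit_points)
  }
  if (length(pick) < n_fit_points)
    stop("insufficient data: need ", n_fit_points, " points ",
         sub("_natz", " the NATZ", boundary), ", have ", length(pick),
         call. = FALSE)
  fit <- stats::lsfit(z[pick], v[pick])
  dCdz <- unname(fit$coefficients[2])               # uM cm-1
  phi <- if (!is.null(porosity)) porosity else mean(rep_len(
    profile$porosity, length(profile$depths))[ok][pick])
  Ds <- tortuosity_corrected_diffusivity(D0, phi)
  -phi * Ds * dCdz * 1e-3                           # umol cm-2 yr-1
}

#' Classify upward ammonium efflux above the transition zone
#'
#' A site loses ammonium to the overlying sediment (and eventually the
#' ocean) if any NH4+ measurement above the NATZ exceeds the detection
#' threshold. Classification is measurement-based rather than flux-based
#' because compiled literature profiles are often too sparse for a reliable
#' upper-zone gradient.
#'
#' @param profile a \code{\link{porewater_profile}}
#' @param interval a \code{\link{natz_interval}}
#' @param threshold detection threshold (uM)
#' @return TRUE (efflux), FALSE (no efflux) or NA (indeterminate: no
#'   measurements above the zone)
#' @export
classify_efflux <- function(profile, interval, threshold = 2) {
  nh4 <- profile$concentrations$NH4
  above <- profile$depths < interval$top & is.finite(nh4)
  if (!any(above)) {
    message("classify_efflux: no NH4 measurements above the NATZ for site ",
            profile$site_id, "; efflux status indeterminate")
    return(NA)
  }
  any(nh4[above] > threshold)
}

#' Process a collection of sites through QC, NATZ detection and efflux
#' classification
#'
#' @param profiles list of \code{\link{porewater_profile}} objects
#' @param threshold detection/depletion threshold (uM)
#' @param min_points QC minimum datapoint count
#' @return an object of class \code{site_compilation}
#' @export
compile_sites <- function(profiles, threshold = 2, min_points = 6) {
  sites <- lapply(profiles, function(p) {
    qc <- qc_filter(p, min_points = min_points,
                    depletion_threshold = threshold)
    entry <- list(profile = p, qc = qc, interval = NULL, efflux = NA)
    if (qc$pass) {
      iv <- tryCatch(detect_natz(p, threshold = threshold, check_qc = FALSE),
                     natzamx_no_natz = function(e) NULL)
      if (!is.null(iv)) {
        entry$interval <- iv
        entry$efflux <- classify_efflux(p, iv, threshold = threshold)
      } else {
        entry$qc <- list(pass = FALSE, reasons = "no_natz")
      }
    }
    entry
  })
  pass <- vapply(sites, function(s) isTRUE(s$qc$pass), logical(1))
  efflux <- vapply(sites, function(s) s$efflux, NA)
  structure(list(sites = sites,
                 n_sites = length(sites),
                 n_pass = sum(pass),
                 n_no_efflux = sum(pass & !efflux, na.rm = TRUE)),
            class = "site_compilation")
}

#' Summarise a multi-site compilation
#'
#' Counts QC-passing sites and sites without upward ammonium efflux, and
#' emits the (water depth, NATZ depth) pair table used to examine the
#' bathymetric spread of transition zones.
#'
#' @param compilation a \code{\link{compile_sites}} object
#' @return list with \code{counts} (n_sites, n_pass, n_no_efflux,
#'   pct_no_efflux rounded to integer percent) and \code{site_table}
#' @export
summarize_sites <- function(compilation) {
  if (compilation$n_pass == 0L)
    warning("empty summary: no sites passed QC", call. = FALSE)
  pct <- if (compilation$n_pass > 0)
    round(100 * compilation$n_no_efflux / compilation$n_pass) else NA_real_
  tab <- do.call(rbind, lapply(compilation$sites, function(s) {
    data.frame(
      site_id = s$profile$site_id,
      water_depth_m = s$profile$water_depth,
      qc_pass = isTRUE(s$qc$pass),
      qc_reasons = paste(s$qc$reasons, collapse = ";"),
      natz_top_cm = if (!is.null(s$interval)) s$interval$top else NA_real_,
      natz_bottom_cm = if (!is.null(s$interval)) s$interval$bottom
                       else NA_real_,
      nh4_efflux = s$efflux)
  }))
  list(counts = data.frame(n_sites = compilation$n_sites,
                           n_pass = compilation$n_pass,
                           n_no_efflux = compilation$n_no_efflux,
                           pct_no_efflux = pct),
       site_table = tab)
}

#' Sediment age from a constant sedimentation rate
#'
#' @param depth depth below seafloor (cm)
#' @param sedimentation_rate cm per thousand years
#' @return age in years
#' @examples
#' sediment_age(160, 2)   # 80,000 years
#' @export
sediment_age <- function(depth, sedimentation_rate) {
  if (any(sedimentation_rate <= 0))
    stop("invalid input: sedimentation_rate must be > 0", call. = FALSE)
  depth / sedimentation_rate * 1000
}
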