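#' Construct a per-window genome coverage track
#'
#' @param windows data.frame with columns \code{scaffold}, \code{start},
#'   \code{end} (0-based half-open) and \code{coverage} (mean read depth)
#' @param window_size window width in bp
#' @param step step between window starts in bp (<= window_size)
#' @return an object of class \code{coverage_track}
#' @export
coverage_track <- function(windows, window_size = 5000, step = 100) {
  need <- c("scaffold", "start", "end", "coverage")
  if (!all(need %in% names(windows)))
    stop("invalid input: windows needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(windows$coverage < 0))
    stop("invalid input: negative coverage", call. = FALSE)
  if (step > window_size)
    stop("invalid configuration: step must be <= window_size", call. = FALSE)
  structure(list(windows = windows, window_size = window_size, step = step),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("Coverage track: %d windows (%d bp / step %d) on %d scaffold(s); mean depth %.2fx\n",
              nrow(x$windows), x$window_size, x$step,
              length(unique(x$windows$scaffold)), mean(x$windows$coverage)))
  invisible(x)
}

#' Slide windows over a per-base depth table
#'
#' Converts per-base depth (scaffold, pos, depth; 1-based positions) into
#' the overlapping-window coverage track the iRep estimator consumes.
#' Scaffolds shorter than one window are dropped.
#'
#' @param depth data.frame with columns \code{scaffold}, \code{pos},
#'   \code{depth}; positions absent from the table count as depth 0
#' @param lengths named vector of scaffold lengths (bp)
#' @param window_size,step window geometry in bp
#' @return a \code{\link{coverage_track}}
#' @export
depth_to_windows <- function(depth, lengths, window_size = 5000,
                             step = 100) {
  need <- c("scaffold", "pos", "depth")
  if (!all(need %in% names(depth)))
    stop("invalid input: depth table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  out <- list()
  for (sc in names(lengths)) {
    L <- lengths[[sc]]
    if (L < window_size) next
    d <- numeric(L)
    rows <- depth$scaffold == sc
    if (any(rows)) d[depth$pos[rows]] <- depth$depth[rows]
    cs <- c(0, cumsum(d))
    starts <- seq(0L, L - window_size, by = step)
    cov <- (cs[starts + window_size + 1] - cs[starts + 1]) / window_size
    out[[sc]] <- data.frame(scaffold = sc, start = starts,
                            end = starts + window_size, coverage = cov)
  }
  if (!length(out))
    stop("insufficient data: no scaffold is at least one window long",
         call. = FALSE)
  coverage_track(do.call(rbind, c(out, make.row.names = FALSE)),
                 window_size = window_size, step = step)
}

#' Genome quality gate for iRep estimation
#'
#' Scaffolds shorter than \code{min_scaffold_length} are removed and the
#' summary statistics recomputed before gating. The estimate is attempted
#' only for genomes with completeness above 75\%, mean coverage above 5x
#' and at most 175 scaffolds per Mbp (all bounds strict as stated, so a
#' genome at exactly 75\% completeness fails).
#'
#' @param completeness percent genome completeness
#' @param mean_coverage mean read depth (x)
#' @param n_scaffolds scaffold count
#' @param genome_length total assembly length (bp)
#' @param scaffold_lengths optional vector of per-scaffold lengths; when
#'   given, the short-scaffold filter is applied and n_scaffolds /
#'   genome_length recomputed
#' @param min_scaffold_length discard threshold (bp)
#' @return list with \code{pass}, \code{reasons}, and the (possibly
#'   recomputed) \code{stats}
#' @export
genome_qc <- function(completeness, mean_coverage, n_scaffolds,
                      genome_length, scaffold_lengths = NULL,
                      min_scaffold_length = 5000) {
  if (!is.null(scaffold_lengths)) {
    keep <- scaffold_lengths >= min_scaffold_length
    n_scaffolds <- sum(keep)
    genome_length <- sum(scaffold_lengths[keep])
  }
  if (genome_length <= 0)
    return(list(pass = FALSE, reasons = "empty_assembly",
                stats = list(n_scaffolds = 0, genome_length = 0)))
  spm <- n_scaffolds / (genome_length / 1e6)
  reasons <- character(0)
  if (!(completeness > 75)) reasons <- c(reasons, "low_completeness")
  if (!(mean_coverage > 5)) reasons <- c(reasons, "low_coverage")
  if (!(spm <= 175)) reasons <- c(reasons, "too_fragmented")
  list(pass = length(reasons) == 0L, reasons = reasons,
       stats = list(completeness = completeness,
                    mean_coverage = mean_coverage,
                    n_scaffolds = n_scaffolds,
                    genome_length = genome_length,
                    scaffolds_per_mbp = spm))
}

#' Index of replication (iRep) from sorted window coverage
#'
#' Bacterial chromosomes replicate bidirectionally from a fixed origin, so
#' an actively replicating population shows higher read coverage near the
#' origin than the terminus. Sorting per-window coverages from highest to
#' lowest and regressing log2 coverage on rank fraction recovers the
#' origin:terminus coverage ratio as 2^|slope|, without needing to know
#' where the origin lies. The top and bottom \code{trim_fraction} of
#' windows are discarded for robustness against mapping artifacts.
#' No GC-bias correction is applied.
#'
#' @param track a \code{\link{coverage_track}}
#' @param trim_fraction fraction trimmed at each extreme after sorting
#' @param min_windows minimum retained window count
#' @return iRep estimate (origin:terminus coverage ratio, >= 1 in
#'   expectation for a replicating population)
#' @export
irep_estimate <- function(track, trim_fraction = 0.05, min_windows = 100) {
  cov <- track$windows$coverage
  nzero <- sum(cov == 0)
  if (nzero > 0) {
    message("irep_estimate: excluding ", nzero, " zero-coverage window(s)")
    cov <- cov[cov > 0]
  }
  cov <- sort(cov, decreasing = TRUE)
  n <- length(cov)
  lo <- floor(n * trim_fraction)
  keep <- (lo + 1):(n - lo)
  if (length(keep) < min_windows)
    stop("insufficient data: ", length(keep),
         " windows after trimming (need >= ", min_windows, ")",
         call. = FALSE)
  # x stays the rank fraction of the full sorted set; trimmed windows are
  # excluded from the fit without re-normalising, so the slope keeps its
  # per-genome-traversal meaning
  x <- (seq_len(n) - 1) / (n - 1)
  fit <- stats::lsfit(x[keep], log2(cov[keep]))
  2^abs(unname(fit$coefficients[2]))
}

#' Replicating-cell fraction implied by an iRep value
#'
#' Under the assumption that each replicating cell carries two copies of
#' the origin-proximal genome, a population iRep of r implies that a
#' fraction r - 1 of cells are replicating.
#'
#' @param irep iRep value
#' @return percent of cells replicating; values below 1 are reported as 0
#'   with a warning
#' @examples
#' replicating_fraction(1.32)   # 32
#' @export
replicating_fraction <- function(irep) {
  out <- (irep - 1) * 100
  if (any(irep < 1)) {
    warning("iRep below 1 reported as 0% replicating", call. = FALSE)
    out[irep < 1] <- 0
  }
  out
}
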