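#' Triplet of consecutive raw scans
#'
#' The acquisition unit of the sensor: three raw intensity spectra
#' measured consecutively on one sensor module during one sample
#' insertion. The triplet is the input of the on-device data-quality
#' gates -- comparing the three scans detects sample movement, and
#' averaging them improves the signal-to-noise ratio.
#'
#' @param scans list of exactly three intensity [nir_spectrum()]s on a
#'   shared grid and module.
#' @return An object of class `scan_triplet`.
#' @export
scan_triplet <- function(scans) {
  if (!is.list(scans) || length(scans) != 3) {
    stop("a scan triplet holds exactly 3 scans")
  }
  for (s in scans) {
    stopifnot(inherits(s, "nir_spectrum"))
    if (s$kind != "intensity") stop("triplet scans must be raw intensity")
  }
  if (!same_grid(scans[[1]]$grid, scans[[2]]$grid) ||
      !same_grid(scans[[1]]$grid, scans[[3]]$grid)) {
    stop("triplet scans must share one grid")
  }
  mods <- vapply(scans, function(s) s$meta$module_id, character(1))
  if (length(unique(mods)) != 1) {
    stop("triplet scans must come from one sensor module")
  }
  structure(list(scans = scans), class = "scan_triplet")
}

triplet_matrix <- function(triplet) {
  do.call(rbind, lapply(triplet$scans, function(s) s$values))
}

#' Movement statistic of a scan triplet
#'
#' Consistency check for sample movement: the mean over wavelengths of
#' the standard deviation across the three scans at each wavelength.
#' A moved sample distorts individual scans and inflates this value.
#' Standard deviation uses the sample convention (divisor n-1 = 2);
#' the three scans are a sample of the scan process.
#'
#' @param triplet a [scan_triplet()].
#' @return Scalar, in intensity units.
#' @export
movement_statistic <- function(triplet) {
  stopifnot(inherits(triplet, "scan_triplet"))
  M <- triplet_matrix(triplet)
  mean(apply(M, 2, stats::sd))
}

#' Default QC thresholds
#'
#' The device compares the movement statistic and the mean intensity of
#' a triplet to predefined limits before accepting a measurement. The
#' instrument's own limits are not public; defaults here are tied to
#' the synthetic-data generator's stated world: movement limit = 5x the
#' generator scan-noise sd, intensity floor = 10% of the white
#' reference mean.
#'
#' @param max_mean_sd movement limit (intensity units).
#' @param min_mean_intensity intensity floor (intensity units).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mean_sd = 40, min_mean_intensity = 2000) {
  if (max_mean_sd <= 0 || min_mean_intensity <= 0) {
    stop("QC thresholds must be > 0")
  }
  structure(list(max_mean_sd = max_mean_sd,
                 min_mean_intensity = min_mean_intensity),
            class = "qc_thresholds")
}

#' Run the data-quality gates on a triplet
#'
#' Applies the two on-device gates in their workflow order: first the
#' movement/consistency check (fail when the movement statistic reaches
#' `max_mean_sd`), then the intensity check (fail when the mean
#' intensity of all scans is below `min_mean_intensity`). A failed gate
#' means the sample has to be re-inserted into the sensor.
#'
#' @param triplet a [scan_triplet()].
#' @param thresholds a [qc_thresholds()].
#' @return A `qc_report` list: `passed`, `movement_stat`,
#'   `intensity_stat`, `failure_reason` (`"none"`, `"movement"`,
#'   `"low_intensity"`).
#' @export
run_qc <- function(triplet, thresholds = qc_thresholds()) {
  stopifnot(inherits(triplet, "scan_triplet"),
            inherits(thresholds, "qc_thresholds"))
  mv <- movement_statistic(triplet)
  ints <- mean(triplet_matrix(triplet))
  reason <- if (mv >= thresholds$max_mean_sd) {
    "movement"
  } else if (ints < thresholds$min_mean_intensity) {
    "low_intensity"
  } else {
    "none"
  }
  structure(list(passed = reason == "none", movement_stat = mv,
                 intensity_stat = ints, failure_reason = reason),
            class = "qc_report")
}

#' Average a QC-passed triplet into one scan
#'
#' Pointwise arithmetic mean of the three scans; metadata of the first
#' scan is inherited. Callers are expected to have run [run_qc()] first.
#'
#' @param triplet a [scan_triplet()].
#' @return An intensity [nir_spectrum()].
#' @export
average_triplet <- function(triplet) {
  stopifnot(inherits(triplet, "scan_triplet"))
  M <- triplet_matrix(triplet)
  nir_spectrum(colMeans(M), triplet$scans[[1]]$grid, kind = "intensity",
               meta = triplet$scans[[1]]$meta)
}
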