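#' Fictional NIR band library for the synthetic generator
#'
#' Gaussian absorption bands for each mixture component the generator
#' models: THC, CBD, the bulk plant matrix, water, and the PE / PP
#' packaging films. The band placement reflects what the real spectra
#' show structurally -- packaging interference concentrated between
#' 1680 and 1735 nm, a dominant water band above 1830 nm, cannabinoid
#' bands overlapping but distinct elsewhere in 1550--1950 nm -- but the
#' positions and strengths are deliberately fictional: published band
#' assignments for cannabinoids in this window are not reproduced here.
#' Amplitudes are in AU per wt% (THC, CBD), per unit mass fraction
#' (matrix, water), or per bag (PE, PP).
#'
#' @param seed accepted for API symmetry; the library is a fixed
#'   constant, so any seed returns the identical object.
#' @return A `component_library`: named list of data.frames with
#'   columns `center_nm`, `width_nm`, `amplitude`.
#' @export
default_library <- function(seed = 1) {
  band <- function(center, width, amp) {
    data.frame(center_nm = center, width_nm = width, amplitude = amp)
  }
  structure(list(
    THC    = band(c(1578, 1622, 1762, 1818), c(14, 18, 15, 12),
                  c(0.0028, 0.0045, 0.0038, 0.0032)),
    CBD    = band(c(1592, 1668, 1778), c(16, 14, 18),
                  c(0.0032, 0.0026, 0.0030)),
    matrix = band(c(1600, 1724, 1868), c(60, 50, 55),
                  c(0.26, 0.16, 0.20)),
    water  = band(1920, 45, 1.6),
    PE     = band(c(1695, 1730), c(12, 10), c(0.16, 0.11)),
    PP     = band(c(1684, 1712), c(10, 13), c(0.12, 0.15))
  ), class = "component_library")
}

# sum of Gaussian bands of one component, evaluated on the grid
component_absorbance <- function(bands, wl) {
  a <- numeric(length(wl))
  for (i in seq_len(nrow(bands))) {
    a <- a + bands$amplitude[i] *
      exp(-0.5 * ((wl - bands$center_nm[i]) / bands$width_nm[i])^2)
  }
  a
}

# smooth white-reference intensity profile (counts), same every run
white_reference_values <- function(grid, level = 20000) {
  wl <- grid$values
  level * (0.92 + 0.08 * cos((wl - 1750) / 400 * pi))
}

#' Ground-truth description of one synthetic sample
#'
#' The stated world of the generator: concentration ranges mirror the
#' real sample set (THC 0.02--24.38 wt%, CBD 0.02--18.69 wt%), samples
#' are measured through a PE or PP bag, scatter is per-spectrum
#' multiplicative plus an additive linear baseline (exactly the
#' interference the SNV + derivative preprocessing removes), sensor
#' modules differ by a multiplicative gain, and the THC content varies
#' between the measurement spots of one sample by a multiplicative
#' lognormal factor -- which makes the effective spread larger for
#' high-THC (class 2) samples, as observed on real flower buds.
#'
#' @param thc_wt_pct,cbd_wt_pct true bulk concentrations (wt%).
#' @param moisture_frac water mass fraction (default 0.10).
#' @param bag `"PE"`, `"PP"` or `"none"`.
#' @param spot_cv lognormal sd of the per-spot THC multiplier (0.25).
#' @param scatter_mult_sd lognormal sd of the per-spectrum
#'   multiplicative scatter factor (0.15).
#' @param baseline_sd sd of the additive linear baseline terms (AU, 0.02).
#' @param noise_sd per-scan detector noise sd (counts, 8).
#' @param module_gain multiplicative gain of the sensor module (1).
#' @param seed integer seed (mandatory).
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(thc_wt_pct, cbd_wt_pct = 1, moisture_frac = 0.10,
                        bag = "none", spot_cv = 0.25,
                        scatter_mult_sd = 0.15, baseline_sd = 0.02,
                        noise_sd = 8, module_gain = 1, seed) {
  if (missing(seed)) stop("sample_spec requires a seed")
  stopifnot(thc_wt_pct >= 0, cbd_wt_pct >= 0)
  bag <- match.arg(bag, c("PE", "PP", "none"))
  structure(list(thc_wt_pct = thc_wt_pct, cbd_wt_pct = cbd_wt_pct,
                 moisture_frac = moisture_frac, bag = bag,
                 spot_cv = spot_cv, scatter_mult_sd = scatter_mult_sd,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 module_gain = module_gain, seed = as.integer(seed)),
            class = "sample_spec")
}

# true absorbance of one measurement spot (before scatter and noise)
spot_absorbance <- function(spec, library, wl, thc_spot) {
  a <- thc_spot * component_absorbance(library$THC, wl) +
    spec$cbd_wt_pct * component_absorbance(library$CBD, wl) +
    component_absorbance(library$matrix, wl) +
    spec$moisture_frac * component_absorbance(library$water, wl)
  if (spec$bag != "none") {
    a <- a + component_absorbance(library[[spec$bag]], wl)
  }
  a
}

#' Simulate the raw acquisition of one sample
#'
#' Emulates one insertion of a sample into the dual-module sensor: for
#' each of `n_modules` modules (one measurement spot each), a true
#' absorbance spectrum is composed from the component library with a
#' spot-specific THC content, converted to transmitted intensity
#' `I = I0 * 10^(-A) * scatter * gain + noise`, and measured as a
#' triplet of consecutive scans differing only by seeded detector
#' noise. An optional movement artifact shifts the last scan of every
#' triplet to exercise the QC gate.
#'
#' @param spec a [sample_spec()].
#' @param library a [default_library()].
#' @param grid a [make_grid()].
#' @param n_modules number of sensor modules / spots (default 2).
#' @param movement add a movement artifact to each triplet (default FALSE).
#' @return A `generated_record`: `triplets` (one [scan_triplet()] per
#'   module), `truth` (the spec plus per-spot THC), `white_ref`
#'   (intensity [nir_spectrum()]), `n_clipped` (negative intensities
#'   clipped, with a warning when nonzero).
#' @export
simulate_record <- function(spec, library = default_library(),
                            grid = make_grid(), n_modules = 2,
                            movement = FALSE) {
  stopifnot(inherits(spec, "sample_spec"))
  wl <- grid$values
  i0 <- white_reference_values(grid)
  white_ref <- nir_spectrum(i0, grid, kind = "intensity",
                            meta = spectrum_meta("white_ref"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(spec$seed)
  triplets <- vector("list", n_modules)
  n_clipped <- 0L
  thc_spots <- numeric(n_modules)
  for (m in seq_len(n_modules)) {
    thc_spot <- spec$thc_wt_pct *
      exp(stats::rnorm(1, 0, spec$spot_cv))
    thc_spots[m] <- thc_spot
    a_true <- spot_absorbance(spec, library, wl, thc_spot)
    baseline <- stats::rnorm(1, 0, spec$baseline_sd) +
      stats::rnorm(1, 0, spec$baseline_sd) * (wl - mean(wl)) / diff(range(wl))
    scatter <- exp(stats::rnorm(1, 0, spec$scatter_mult_sd))
    clean <- i0 * 10^(-(a_true + baseline)) * scatter * spec$module_gain
    scans <- vector("list", 3)
    for (s in 1:3) {
      v <- clean + stats::rnorm(length(wl), 0, spec$noise_sd)
      if (movement && s == 3) {
        v <- v * 0.8 + 0.02 * mean(i0)   # sample shifted mid-measurement
      }
      neg <- v <= 0
      if (any(neg)) {
        n_clipped <- n_clipped + sum(neg)
        v[neg] <- .Machine$double.eps
      }
      meta <- spectrum_meta(paste0("sample", spec$seed),
                            module_id = paste0("m", m),
                            spot_id = paste0("s", m), bag = spec$bag,
                            thc_wt_pct = spec$thc_wt_pct,
                            cbd_wt_pct = spec$cbd_wt_pct)
      scans[[s]] <- nir_spectrum(v, grid, kind = "intensity", meta = meta)
    }
    triplets[[m]] <- scan_triplet(scans)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  if (n_clipped > 0) {
    warning(n_clipped, " negative intensities clipped")
  }
  structure(list(triplets = triplets,
                 truth = c(unclass(spec), list(thc_spots = thc_spots)),
                 white_ref = white_ref, n_clipped = n_clipped),
            class = "generated_record")
}

# log-uniform draw within [lo, hi]
runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Simulate a labeled dataset of absorbance spectra
#'
#' Generates `n_samples` synthetic cannabis samples with the class
#' structure of the field data: class 1 (<= 0.4 wt% THC) versus class 2
#' (> 0.4 wt%), THC drawn log-uniformly within each class range, CBD
#' drawn per chemotype (low-THC samples are the CBD-rich products the
#' authorities encounter; drug-type samples carry little CBD), bags
#' assigned independently of class, and per-module gains shared across
#' the dataset. Every sample
#' is measured by `n_modules` modules (one spot each) as a raw scan
#' triplet which is QC-averaged and converted to absorbance -- the same
#' path real spectra take -- so the returned dataset holds one
#' absorbance spectrum per (sample, module).
#'
#' @param n_samples number of samples (>= 4).
#' @param class_balance fraction of class-1 samples (default 0.421, the
#'   calibration-set split of the real data).
#' @param thc_range_class1,thc_range_class2 THC draw ranges (wt%);
#'   defaults 0.02--0.40 and 0.45--24.38.
#' @param cbd_range_class1,cbd_range_class2 CBD draw ranges per class
#'   (wt%); defaults 1--18.69 for class 1 (CBD chemotype) and
#'   0.02--2 for class 2 (drug chemotype).
#' @param n_modules sensor modules per device (default 2).
#' @param bags bag types to assign (default PE/PP).
#' @param module_gain_sd lognormal sd of the per-module gain (0.05).
#' @param seed master seed.
#' @param ... overrides passed to every [sample_spec()]
#'   (e.g. `noise_sd = 0`, `spot_cv = 0`).
#' @return A [spectral_dataset()] of absorbance spectra; the attached
#'   `$truth` data.frame holds one row of ground truth per sample.
#' @export
simulate_dataset <- function(n_samples = 200, class_balance = 0.421,
                             thc_range_class1 = c(0.02, 0.40),
                             thc_range_class2 = c(0.45, 24.38),
                             cbd_range_class1 = c(1, 18.69),
                             cbd_range_class2 = c(0.02, 2),
                             n_modules = 2, bags = c("PE", "PP"),
                             module_gain_sd = 0.05, seed = 1, ...) {
  if (n_samples < 4) stop("need at least 4 samples")
  n1 <- round(n_samples * class_balance)
  n2 <- n_samples - n1
  if (n1 < 1 || n2 < 1) stop("infeasible class balance")
  grid <- make_grid()
  library <- default_library()
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  thc <- c(runif_log(n1, thc_range_class1[1], thc_range_class1[2]),
           runif_log(n2, thc_range_class2[1], thc_range_class2[2]))
  cbd <- c(runif_log(n1, cbd_range_class1[1], cbd_range_class1[2]),
           runif_log(n2, cbd_range_class2[1], cbd_range_class2[2]))
  moisture <- stats::runif(n_samples, 0.05, 0.15)
  bag <- sample(bags, n_samples, replace = TRUE)
  gains <- exp(stats::rnorm(n_modules, 0, module_gain_sd))
  sample_seeds <- sample.int(2^30, n_samples)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  rows <- vector("list", n_samples * n_modules)
  meta <- vector("list", n_samples * n_modules)
  k <- 0L
  for (i in seq_len(n_samples)) {
    spec <- sample_spec(thc[i], cbd[i], moisture_frac = moisture[i],
                        bag = bag[i], seed = sample_seeds[i], ...)
    rec <- simulate_record(spec, library, grid, n_modules = n_modules)
    for (m in seq_len(n_modules)) {
      # module gain applies at the intensity level; fold it in here so
      # each module keeps its own gain across the whole dataset
      tri <- rec$triplets[[m]]
      avg <- average_triplet(tri)
      avg$values <- avg$values * gains[m]
      wr <- rec$white_ref
      k <- k + 1L
      rows[[k]] <- compute_absorbance(avg, wr)$values
      meta[[k]] <- data.frame(
        sample_id = sprintf("sample%04d", i),
        module_id = paste0("m", m), spot_id = paste0("s", m),
        bag = bag[i], thc_wt_pct = thc[i], cbd_wt_pct = cbd[i],
        stringsAsFactors = FALSE)
    }
  }
  ds <- spectral_dataset(do.call(rbind, rows), grid, do.call(rbind, meta),
                         kind = "absorbance")
  ds$truth <- data.frame(
    sample_id = sprintf("sample%04d", seq_len(n_samples)),
    thc_wt_pct = thc, cbd_wt_pct = cbd, moisture_frac = moisture,
    bag = bag, class = as.character(encode_labels(thc)),
    seed = sample_seeds, stringsAsFactors = FALSE)
  ds
}
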