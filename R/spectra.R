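#' Per-spectrum metadata
#'
#' Metadata attached to a single spectrum: sample, sensor module and
#' measurement spot identifiers, the packaging the sample was measured
#' through (transparent PE or PP bag, or none), and -- when a
#' chromatographic reference is available -- the THC and CBD contents
#' in weight percent. Reference concentrations are optional (`NA`).
#'
#' @param sample_id,module_id,spot_id identifiers (coerced to character).
#' @param bag one of `"PE"`, `"PP"`, `"none"`.
#' @param thc_wt_pct,cbd_wt_pct reference concentrations in wt%, or `NA`.
#' @return A `spectrum_meta` list.
#' @export
spectrum_meta <- function(sample_id, module_id = "m1", spot_id = "s1",
                          bag = "none", thc_wt_pct = NA_real_,
                          cbd_wt_pct = NA_real_) {
  bag <- match.arg(bag, c("PE", "PP", "none"))
  thc_wt_pct <- as.numeric(thc_wt_pct)
  if (!is.na(thc_wt_pct) && thc_wt_pct < 0) {
    stop("thc_wt_pct must be >= 0")
  }
  structure(
    list(sample_id = as.character(sample_id),
         module_id = as.character(module_id),
         spot_id = as.character(spot_id),
         bag = bag,
         thc_wt_pct = thc_wt_pct,
         cbd_wt_pct = as.numeric(cbd_wt_pct)),
    class = "spectrum_meta"
  )
}

#' A single spectrum on a wavelength grid
#'
#' @param values numeric vector, one value per grid wavelength. Raw
#'   intensity counts, absorbance (AU), or a preprocessed trace.
#' @param grid a [make_grid()] object.
#' @param kind `"intensity"`, `"absorbance"` or `"preprocessed"`.
#' @param meta a [spectrum_meta()] object.
#' @return An object of class `nir_spectrum`.
#' @export
nir_spectrum <- function(values, grid, kind = c("intensity", "absorbance",
                                                "preprocessed"),
                         meta = spectrum_meta("unknown")) {
  kind <- match.arg(kind)
  stopifnot(is_nir_grid(grid))
  values <- as.numeric(values)
  if (length(values) != length(grid$values)) {
    stop(sprintf("spectrum has %d values but grid has %d wavelengths",
                 length(values), length(grid$values)))
  }
  if (!all(is.finite(values))) stop("spectrum values must all be finite")
  structure(
    list(values = values, grid = grid, kind = kind, meta = meta),
    class = "nir_spectrum"
  )
}

#' @export
print.nir_spectrum <- function(x, ...) {
  cat(sprintf("<nir_spectrum> %s, %d points (%g..%g nm), sample %s\n",
              x$kind, length(x$values), x$grid$start_nm, x$grid$stop_nm,
              x$meta$sample_id))
  invisible(x)
}

#' Absorbance from a raw scan and a white reference
#'
#' Converts a raw intensity scan to absorbance against a white-reference
#' scan measured on the same grid: `A = -log10(I / I0)` in absorbance
#' units. This is how the on-device pipeline turns averaged raw scans
#' into spectra the chemometric model consumes; the white reference is
#' stored per sensor module.
#'
#' @param scan an intensity `nir_spectrum`.
#' @param white_ref the white-reference intensity `nir_spectrum` (same
#'   grid, strictly positive).
#' @return An absorbance `nir_spectrum`; metadata of `scan` preserved.
#' @export
compute_absorbance <- function(scan, white_ref) {
  stopifnot(inherits(scan, "nir_spectrum"), inherits(white_ref, "nir_spectrum"))
  if (scan$kind != "intensity" || white_ref$kind != "intensity") {
    stop("compute_absorbance expects intensity spectra")
  }
  if (!same_grid(scan$grid, white_ref$grid)) {
    stop("scan and white reference are on different grids")
  }
  bad <- which(scan$values <= 0 | white_ref$values <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive intensity at %g nm", scan$grid$values[bad[1]]))
  }
  nir_spectrum(-log10(scan$values / white_ref$values), scan$grid,
               kind = "absorbance", meta = scan$meta)
}

#' Collection of spectra sharing one grid
#'
#' The container every downstream module consumes: an `n x p` matrix of
#' spectra (rows) on a shared wavelength grid plus a metadata
#' data.frame with one row per spectrum.
#'
#' @param X numeric matrix, rows = spectra, columns = wavelengths.
#' @param grid a [make_grid()] object with `ncol(X)` wavelengths.
#' @param meta data.frame with columns `sample_id`, `module_id`,
#'   `spot_id`, `bag`, `thc_wt_pct`, `cbd_wt_pct`; one row per spectrum.
#' @param kind what the rows contain (default `"absorbance"`).
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(X, grid, meta, kind = "absorbance") {
  X <- as.matrix(X)
  stopifnot(is_nir_grid(grid))
  if (ncol(X) != length(grid$values)) {
    stop("column count of X does not match grid")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "module_id", "spot_id", "bag",
                "thc_wt_pct", "cbd_wt_pct")
  for (col in setdiff(required, names(meta))) {
    meta[[col]] <- if (col == "bag") "none" else NA
  }
  if (nrow(X) != nrow(meta)) {
    stop("X and meta must have the same number of rows")
  }
  bad_bag <- setdiff(unique(meta$bag), c("PE", "PP", "none"))
  if (length(bad_bag)) {
    stop(sprintf("unknown bag code: %s", paste(bad_bag, collapse = ", ")))
  }
  dimnames(X) <- NULL
  structure(
    list(X = X, grid = grid, meta = meta[required], kind = kind),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d %s spectra x %d wavelengths (%g..%g nm)\n",
              nrow(x$X), x$kind, ncol(x$X), x$grid$start_nm, x$grid$stop_nm))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$X)

# row subset keeping grid/meta consistent
subset_dataset <- function(ds, idx) {
  spectral_dataset(ds$X[idx, , drop = FALSE], ds$grid,
                   ds$meta[idx, , drop = FALSE], kind = ds$kind)
}
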