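#' Preprocessing configuration
#'
#' The pretreatment found best for the sensor's absorbance spectra:
#' Savitzky-Golay smoothing with first derivative (window 5 points,
#' second-order polynomial) followed by Standard Normal Variate (SNV)
#' normalization. The SG derivative removes additive baselines, SNV
#' removes multiplicative scatter -- together they strip sample
#' presentation effects while keeping the chemical band structure.
#'
#' @param sg_window odd window length in points (default 5).
#' @param sg_polyorder polynomial order (default 2), `< sg_window`.
#' @param sg_deriv derivative order (default 1), `<= sg_polyorder`.
#' @param snv_enabled apply SNV after the filter (default TRUE).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 5, sg_polyorder = 2,
                              sg_deriv = 1, snv_enabled = TRUE) {
  if (sg_window %% 2 != 1) stop("sg_window must be odd")
  if (sg_polyorder >= sg_window) stop("sg_polyorder must be < sg_window")
  if (sg_deriv > sg_polyorder) stop("sg_deriv must be <= sg_polyorder")
  structure(list(sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = as.integer(sg_deriv),
                 snv_enabled = isTRUE(snv_enabled)),
            class = "preprocess_config")
}

# least-squares polynomial-filter weights for one output position.
# offsets: integer index offsets of the points entering the fit,
# relative to the evaluation point. Returns the weight vector w such
# that sum(w * x[pos + offsets]) is the deriv-th derivative (per index
# step) of the local least-squares polynomial at the evaluation point.
sg_weights <- function(offsets, polyorder, deriv) {
  # a truncated edge window may hold fewer points than the polynomial
  # needs; drop the order to keep the fit determined
  polyorder <- min(polyorder, length(offsets) - 1L)
  if (deriv > polyorder) return(rep(0, length(offsets)))
  V <- outer(offsets, 0:polyorder, `^`)      # Vandermonde in the offset
  # pseudo-inverse row for the deriv-th polynomial coefficient
  coef_rows <- solve(crossprod(V), t(V))
  factorial(deriv) * coef_rows[deriv + 1, ]
}

#' Savitzky-Golay filtering / differentiation
#'
#' Local least-squares polynomial convolution. Interior points use the
#' centered window; the `(window-1)/2` points at each edge fit the same
#' polynomial to the truncated one-sided window so the output keeps the
#' full grid length (wavelength-selection indices stay aligned).
#' Derivatives are reported per index step; on the uniform 5 nm grid
#' this is proportional to per-nm and the subsequent SNV removes the
#' constant anyway.
#'
#' @param values numeric vector, `length >= window`.
#' @param config a [preprocess_config()] (only the SG fields are used).
#' @return Filtered vector of the same length.
#' @export
savitzky_golay <- function(values, config = preprocess_config()) {
  w <- config$sg_window
  h <- (w - 1L) %/% 2L
  p <- length(values)
  if (p < w) stop("input shorter than the filter window")
  out <- numeric(p)
  # central convolution
  central <- sg_weights(-h:h, config$sg_polyorder, config$sg_deriv)
  for (i in (h + 1L):(p - h)) {
    out[i] <- sum(central * values[(i - h):(i + h)])
  }
  # truncated one-sided windows at the edges
  for (i in seq_len(h)) {
    off <- (1L - i):h
    wts <- sg_weights(off, config$sg_polyorder, config$sg_deriv)
    out[i] <- sum(wts * values[i + off])
    off <- -h:(p - (p - i + 1L))
    wts <- sg_weights(off, config$sg_polyorder, config$sg_deriv)
    j <- p - i + 1L
    out[j] <- sum(wts * values[j + off])
  }
  out
}

#' Standard Normal Variate normalization
#'
#' Per-spectrum standardization `(x - mean(x)) / sd(x)` with the sample
#' standard deviation (n-1), the convention of common chemometrics
#' software. Removes per-spectrum multiplicative scatter and offset;
#' the output has mean 0 and sample sd 1 exactly.
#'
#' @param values numeric vector of length >= 2 with nonzero variance.
#' @return The standardized vector.
#' @export
snv <- function(values) {
  if (length(values) < 2) stop("SNV needs at least 2 points")
  s <- stats::sd(values)
  if (!is.finite(s) || s <= 0) stop("SNV undefined for a constant spectrum")
  (values - mean(values)) / s
}

#' Full spectral pretreatment
#'
#' Applies the Savitzky-Golay filter, then SNV, in the on-device order.
#' Accepts a single absorbance spectrum, a bare numeric vector, or a
#' whole [spectral_dataset()] (row-wise).
#'
#' @param x absorbance `nir_spectrum`, numeric vector, or
#'   `spectral_dataset`.
#' @param config a [preprocess_config()].
#' @return Same shape as the input, with kind `"preprocessed"` where
#'   applicable.
#' @export
preprocess <- function(x, config = preprocess_config()) {
  if (inherits(x, "spectral_dataset")) {
    Xp <- t(apply(x$X, 1, preprocess, config = config))
    return(spectral_dataset(Xp, x$grid, x$meta, kind = "preprocessed"))
  }
  if (inherits(x, "nir_spectrum")) {
    return(nir_spectrum(preprocess(x$values, config), x$grid,
                        kind = "preprocessed", meta = x$meta))
  }
  out <- savitzky_golay(x, config)
  if (config$snv_enabled) out <- snv(out)
  out
}
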