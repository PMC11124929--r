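#' Wavelength grid for NIR acquisition
#'
#' Constructs the uniform wavelength grid spectra are acquired on. The
#' default acquisition grid of the handheld sensor runs from 1550 nm to
#' 1950 nm in 5 nm steps, giving exactly 81 data points per spectrum --
#' the region where the relevant cannabinoid overtone/combination bands
#' sit within reach of a tunable Fabry-Perot filter module.
#'
#' @param start_nm first wavelength (nm).
#' @param stop_nm last wavelength (nm); must be reachable from
#'   `start_nm` in whole steps (tolerance 1e-9 nm).
#' @param step_nm step size (nm), strictly positive.
#'
#' @return An object of class `nir_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and `values` (the ordered wavelength vector).
#' @examples
#' g <- make_grid()          # 1550--1950 nm, 5 nm: 81 points
#' length(g$values)
#' @export
make_grid <- function(start_nm = 1550, stop_nm = 1950, step_nm = 5) {
  if (!is.numeric(start_nm) || !is.numeric(stop_nm) || !is.numeric(step_nm)) {
    stop("grid endpoints and step must be numeric")
  }
  if (step_nm <= 0) stop("step_nm must be > 0")
  if (stop_nm < start_nm) stop("stop_nm must be >= start_nm")
  span <- stop_nm - start_nm
  n_steps <- span / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-9 / step_nm) {
    stop(sprintf("grid range %g..%g nm is not divisible by step %g nm",
                 start_nm, stop_nm, step_nm))
  }
  n_steps <- round(n_steps)
  values <- start_nm + step_nm * (0:n_steps)
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         values = values),
    class = "nir_grid"
  )
}

#' @export
length.nir_grid <- function(x) length(x$values)

#' @export
print.nir_grid <- function(x, ...) {
  cat(sprintf("<nir_grid> %g..%g nm, step %g nm, %d points\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$values)))
  invisible(x)
}

is_nir_grid <- function(x) inherits(x, "nir_grid")

# two grids are the same acquisition grid if wavelengths agree to 1e-9 nm
same_grid <- function(a, b) {
  length(a$values) == length(b$values) &&
    all(abs(a$values - b$values) < 1e-9)
}
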