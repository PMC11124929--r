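#' Partition the wavelength grid into contiguous intervals
#'
#' Interval PLS works on contiguous blocks of the wavelength grid; with
#' the default interval size of 5 variables on the 5 nm grid each full
#' interval spans 25 nm (5 bins of 5 nm). The 81-point default grid
#' yields 17 intervals, the last holding a single variable.
#'
#' @param grid a [make_grid()] object.
#' @param size variables per interval (default 5).
#' @return List of `interval` objects: `index`, `wavelength_lo`,
#'   `wavelength_hi`, `variable_indices`, `span_nm` (bin-counted width,
#'   `length(variable_indices) * step`).
#' @export
make_intervals <- function(grid, size = 5) {
  stopifnot(is_nir_grid(grid))
  if (size < 1) stop("interval size must be >= 1")
  p <- length(grid$values)
  starts <- seq(1L, p, by = size)
  lapply(seq_along(starts), function(k) {
    idx <- starts[k]:min(starts[k] + size - 1L, p)
    structure(
      list(index = k,
           wavelength_lo = grid$values[idx[1]],
           wavelength_hi = grid$values[idx[length(idx)]],
           variable_indices = idx,
           span_nm = length(idx) * grid$step_nm),
      class = "interval"
    )
  })
}

# cross-validated misclassification for one candidate variable subset;
# the component count is chosen by the inner CV itself (parsimony on
# ties), mirroring how the interval search couples to cross-validation
subset_criterion <- function(X, y, vars, scheme, max_lv) {
  Xs <- X[, vars, drop = FALSE]
  crit <- cross_validate(Xs, y, scheme, max_lv = max_lv,
                         criterion = "misclass")
  min(crit)
}

#' Forward interval-PLS wavelength selection
#'
#' Greedy forward selection over contiguous wavelength intervals:
#' every single interval is scored by cross-validated misclassification
#' of a PLS-DA model restricted to it; the best interval seeds the
#' subset, and intervals are then added one at a time while an addition
#' strictly improves the criterion. Ties prefer the lower-wavelength
#' interval, and the whole search is deterministic given the CV scheme
#' seed. On the sensor's data this is what excludes the packaging-
#' dominated 1680--1735 nm region and the moisture-dominated region
#' above 1830 nm from the classifier.
#'
#' @param X preprocessed spectra matrix (n x p).
#' @param y_classes class labels (factor or +1/-1 code, 2 classes).
#' @param intervals from [make_intervals()].
#' @param scheme a [cv_scheme()].
#' @param max_lv largest component count tried inside the search.
#' @return A `selection_result`: `selected` (intervals, in selection
#'   order), `history` (data.frame: step, interval index, criterion),
#'   `final_variable_mask` (logical, length p).
#' @export
ipls_forward <- function(X, y_classes, intervals, scheme = cv_scheme(),
                         max_lv = 8) {
  X <- as.matrix(X)
  y <- encode_class_code(y_classes)
  if (length(unique(y)) < 2) stop("need both classes for interval selection")
  if (all(apply(X, 2, stats::var) < .Machine$double.eps)) {
    stop("all-constant spectra matrix")
  }
  p <- ncol(X)
  remaining <- seq_along(intervals)
  chosen <- integer(0)
  history <- data.frame(step = integer(0), interval = integer(0),
                        criterion = numeric(0))
  best_crit <- Inf
  repeat {
    crits <- vapply(remaining, function(k) {
      vars <- sort(unlist(lapply(intervals[c(chosen, k)],
                                 `[[`, "variable_indices")))
      subset_criterion(X, y, vars, scheme, max_lv)
    }, numeric(1))
    k_best <- remaining[which.min(crits)]   # which.min: first = lowest wavelength
    c_best <- min(crits)
    improves <- if (!length(chosen)) TRUE else c_best < best_crit
    if (!improves) break
    chosen <- c(chosen, k_best)
    remaining <- setdiff(remaining, k_best)
    best_crit <- c_best
    history <- rbind(history,
                     data.frame(step = length(chosen), interval = k_best,
                                criterion = c_best))
    if (!length(remaining) || best_crit == 0) break
  }
  mask <- rep(FALSE, p)
  for (k in chosen) mask[intervals[[k]]$variable_indices] <- TRUE
  structure(
    list(selected = intervals[chosen], history = history,
         final_variable_mask = mask),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d interval(s), %d variables\n",
              length(x$selected), sum(x$final_variable_mask)))
  for (i in seq_len(nrow(x$history))) {
    iv <- x$selected[[i]]
    cat(sprintf("  step %d: interval %d (%g-%g nm), CV misclass %g\n",
                x$history$step[i], x$history$interval[i],
                iv$wavelength_lo, iv$wavelength_hi, x$history$criterion[i]))
  }
  invisible(x)
}
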