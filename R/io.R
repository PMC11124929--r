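#' Read / write spectra datasets as plain CSV
#'
#' The on-disk dialect is deliberately human-inspectable: the first
#' column `id` carries the spectrum identifier, columns prefixed
#' `meta_` carry per-spectrum metadata (`meta_sample_id`,
#' `meta_module_id`, `meta_spot_id`, `meta_bag`, `meta_thc_wt_pct`,
#' `meta_cbd_wt_pct`, optionally `meta_kind` and `meta_scan`), and
#' every remaining column header is a wavelength in nm. `write_dataset`
#' followed by `read_dataset` reproduces `X` and the metadata up to
#' numeric round-trip.
#'
#' @param path file path of the CSV.
#' @return `read_dataset` returns a [spectral_dataset()];
#'   `write_dataset` returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (!nrow(raw)) stop("empty dataset file: ", path)
  nm <- names(raw)
  meta_cols <- grep("^meta_", nm, value = TRUE)
  wl_cols <- setdiff(nm, c("id", meta_cols))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) {
    stop("non-wavelength data column(s) in header: ",
         paste(wl_cols[is.na(wl)], collapse = ", "))
  }
  X <- matrix(NA_real_, nrow(raw), length(wl_cols))
  for (j in seq_along(wl_cols)) {
    v <- raw[[wl_cols[j]]]
    blank <- !nzchar(trimws(v))
    if (any(blank)) {
      stop(sprintf("row %d has a missing spectral value", which(blank)[1]))
    }
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) {
      stop(sprintf("row %d has a non-numeric spectral value", which(is.na(num))[1]))
    }
    X[, j] <- num
  }
  step <- if (length(wl) > 1) wl[2] - wl[1] else 5
  grid <- make_grid(wl[1], wl[length(wl)], step)
  if (!all(abs(grid$values - wl) < 1e-9)) {
    stop("wavelength header is not a uniform grid")
  }
  getmeta <- function(col, default) {
    key <- paste0("meta_", col)
    if (key %in% nm) raw[[key]] else rep(default, nrow(raw))
  }
  meta <- data.frame(
    sample_id = getmeta("sample_id", raw$id),
    module_id = getmeta("module_id", "m1"),
    spot_id = getmeta("spot_id", "s1"),
    bag = getmeta("bag", "none"),
    thc_wt_pct = suppressWarnings(as.numeric(getmeta("thc_wt_pct", NA))),
    cbd_wt_pct = suppressWarnings(as.numeric(getmeta("cbd_wt_pct", NA))),
    stringsAsFactors = FALSE
  )
  kind <- if ("meta_kind" %in% nm) raw$meta_kind[1] else "absorbance"
  ds <- spectral_dataset(X, grid, meta, kind = kind)
  if ("meta_scan" %in% nm) ds$scan <- as.integer(raw$meta_scan)
  if ("id" %in% nm) ds$id <- raw$id
  ds
}

#' @rdname read_dataset
#' @param ds a [spectral_dataset()].
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  out <- data.frame(
    id = if (!is.null(ds$id)) ds$id else paste0("spec", seq_len(nrow(ds$X))),
    meta_sample_id = ds$meta$sample_id,
    meta_module_id = ds$meta$module_id,
    meta_spot_id = ds$meta$spot_id,
    meta_bag = ds$meta$bag,
    meta_thc_wt_pct = ds$meta$thc_wt_pct,
    meta_cbd_wt_pct = ds$meta$cbd_wt_pct,
    meta_kind = ds$kind,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!is.null(ds$scan)) out$meta_scan <- ds$scan
  spec <- as.data.frame(ds$X)
  names(spec) <- format(ds$grid$values, trim = TRUE, scientific = FALSE)
  out <- cbind(out, spec)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
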