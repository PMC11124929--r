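#' Save / load a calibrated classifier as portable JSON
#'
#' The whole deployable model -- grid, preprocessing configuration,
#' wavelength mask, PLS centering vectors and matrices, class
#' Gaussians and priors, thresholds, diagnostics limits, QC thresholds
#' and the white reference -- is serialized to a single
#' JSON-structured text file with a mandatory `version` field. Numbers
#' are written at full precision so a save/load round trip reproduces
#' classifications bit-for-bit.
#'
#' @param model a [fit_plsda()] model.
#' @param path file path of the model JSON.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the `plsda_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "plsda_model"))
  obj <- list(
    format = "nirclass-plsda",
    version = model$version,
    grid = list(start_nm = model$grid$start_nm, stop_nm = model$grid$stop_nm,
                step_nm = model$grid$step_nm),
    preprocess = unclass(model$preprocess),
    variable_mask = model$variable_mask,
    pls = list(x_mean = model$pls$x_mean, y_mean = model$pls$y_mean,
               W = model$pls$W, P = model$pls$P, Q = model$pls$Q,
               B = model$pls$B, score_variances = model$pls$score_variances,
               n_lv = model$pls$n_lv, n_train = model$pls$n_train),
    gaussians = model$gaussians,
    encoding = unclass(model$encoding),
    prob_threshold = model$prob_threshold,
    diagnostics = unclass(model$diagnostics),
    qc = unclass(model$qc),
    n_outliers_removed = model$n_outliers_removed,
    n_train = model$n_train,
    white_ref = model$white_ref,
    seed = model$seed
  )
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                           matrix = "rowmajor", null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyMatrix = TRUE)
  if (is.null(obj$version)) stop("model file has no version field")
  if (!identical(obj$format, "nirclass-plsda")) {
    stop("not a nirclass model file")
  }
  grid <- make_grid(obj$grid$start_nm, obj$grid$stop_nm, obj$grid$step_nm)
  pls <- structure(
    list(x_mean = obj$pls$x_mean, y_mean = obj$pls$y_mean,
         W = as.matrix(obj$pls$W), P = as.matrix(obj$pls$P),
         Q = matrix(obj$pls$Q, ncol = obj$pls$n_lv),
         B = matrix(obj$pls$B, ncol = 1),
         score_variances = obj$pls$score_variances,
         n_lv = obj$pls$n_lv, n_train = obj$pls$n_train),
    class = "pls_model"
  )
  structure(
    list(version = obj$version, grid = grid,
         preprocess = do.call(preprocess_config, obj$preprocess),
         variable_mask = obj$variable_mask,
         selection = NULL,
         pls = pls,
         gaussians = obj$gaussians,
         encoding = structure(obj$encoding, class = "class_encoding"),
         prob_threshold = obj$prob_threshold,
         diagnostics = structure(obj$diagnostics, class = "diagnostic_limits"),
         cv_criterion = NULL,
         n_outliers_removed = obj$n_outliers_removed,
         n_train = obj$n_train,
         white_ref = obj$white_ref,
         qc = structure(obj$qc, class = "qc_thresholds"),
         seed = obj$seed),
    class = "plsda_model"
  )
}
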