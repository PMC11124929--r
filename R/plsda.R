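#' Class encoding at the legal THC threshold
#'
#' Binary split of samples at a THC content of 0.4 wt%: class 1
#' ("unsuspicious", at or below the threshold, green) and class 2
#' ("suspicious", above it, red). The device uses 0.4 wt% rather than
#' the 0.3 wt% legal limit: it balances the classes and samples between
#' 0.3 and 0.4 wt% are not an enforcement priority. Class 1 is coded +1
#' and class 2 is coded -1 on the class-1 response column.
#'
#' @param thc_threshold class split in wt% THC (default 0.4).
#' @return A `class_encoding` list.
#' @export
class_encoding <- function(thc_threshold = 0.4) {
  structure(list(thc_threshold = thc_threshold,
                 class1 = "unsuspicious", class2 = "suspicious",
                 code_class1 = 1, code_class2 = -1),
            class = "class_encoding")
}

#' Label THC concentrations
#'
#' `"class1"` iff `thc <= threshold` (the threshold itself is legal),
#' `"class2"` otherwise.
#'
#' @param thc_values reference THC contents (wt%), finite, >= 0.
#' @param threshold split in wt% (default 0.4).
#' @return Factor with levels `class1`, `class2`.
#' @export
encode_labels <- function(thc_values, threshold = 0.4) {
  thc_values <- as.numeric(thc_values)
  if (any(!is.finite(thc_values))) stop("THC values must be finite")
  if (any(thc_values < 0)) stop("negative THC concentration")
  factor(ifelse(thc_values <= threshold, "class1", "class2"),
         levels = c("class1", "class2"))
}

# labels (factor/character/±1) -> +1/-1 code on the class-1 column
encode_class_code <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(-1, 1)))
    return(as.numeric(labels))
  }
  lab <- as.character(labels)
  stopifnot(all(lab %in% c("class1", "class2")))
  ifelse(lab == "class1", 1, -1)
}

#' Bayes posterior class probabilities from a predicted value
#'
#' The calibrated discriminant score is turned into class
#' probabilities by modelling the training predicted values of each
#' class as a normal distribution and applying Bayes' theorem:
#' `p_c = pi_c N(y; mu_c, sd_c) / sum_k pi_k N(y; mu_k, sd_k)`.
#' For the binary model the two posteriors sum to 1 exactly.
#'
#' @param y_pred scalar (or vector) predicted class-1 value.
#' @param gaussians list with elements `class1` and `class2`, each a
#'   list `mean`, `sd`, `prior` (priors summing to 1).
#' @return Matrix with columns `p_class1`, `p_class2`.
#' @export
bayes_probability <- function(y_pred, gaussians) {
  if (any(!is.finite(y_pred))) stop("predicted value must be finite")
  g1 <- gaussians$class1; g2 <- gaussians$class2
  # densities can underflow far from both means; work in log space
  l1 <- log(g1$prior) + stats::dnorm(y_pred, g1$mean, g1$sd, log = TRUE)
  l2 <- log(g2$prior) + stats::dnorm(y_pred, g2$mean, g2$sd, log = TRUE)
  m <- pmax(l1, l2)
  w1 <- exp(l1 - m); w2 <- exp(l2 - m)
  p1 <- unname(w1 / (w1 + w2))
  out <- cbind(p1, 1 - p1)
  dimnames(out) <- list(NULL, c("p_class1", "p_class2"))
  out
}

#' Calibrate the on-device PLS-DA classifier
#'
#' The full calibration pipeline of the sensor, applied to a dataset of
#' absorbance spectra with reference THC values:
#' \enumerate{
#'   \item preprocess every spectrum (Savitzky-Golay derivative + SNV);
#'   \item select wavelength intervals by forward iPLS (unless a mask
#'     is supplied or selection is disabled);
#'   \item fit an initial PLS-DA model and screen calibration outliers
#'     by their Q residual and Hotelling T-squared against the 95%
#'     limits (single pass, removal when either limit is exceeded);
#'   \item refit on the cleaned data with the component count chosen by
#'     90/10 cross-validated misclassification (smallest count at the
#'     minimum);
#'   \item fit one normal distribution per class to the training
#'     predicted values and record the class priors.
#' }
#'
#' @param dataset a [spectral_dataset()] of absorbance spectra with
#'   `thc_wt_pct` present; at least 10 spectra per class.
#' @param config a [plsda_config()].
#' @param white_ref optional white-reference intensity spectrum to
#'   embed in the model (needed to classify raw scan triplets).
#' @return An object of class `plsda_model`.
#' @export
fit_plsda <- function(dataset, config = plsda_config(), white_ref = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  thc <- dataset$meta$thc_wt_pct
  if (anyNA(thc)) stop("reference THC values required for calibration")
  enc <- class_encoding(config$thc_threshold)
  labels <- encode_labels(thc, config$thc_threshold)
  if (any(table(labels) < 10)) {
    stop("need at least 10 spectra in each class")
  }
  y <- encode_class_code(labels)

  Xp <- t(apply(dataset$X, 1, preprocess, config = config$preprocess))
  scheme <- cv_scheme(n_folds = config$cv_folds,
                      shuffle_seed = config$seed, stratified = TRUE)

  if (!is.null(config$variable_mask)) {
    mask <- config$variable_mask
    selection <- NULL
  } else if (config$ipls_enabled) {
    intervals <- make_intervals(dataset$grid, size = config$ipls_interval_size)
    selection <- ipls_forward(Xp, labels, intervals, scheme,
                              max_lv = config$max_lv)
    mask <- selection$final_variable_mask
  } else {
    mask <- rep(TRUE, ncol(Xp))
    selection <- NULL
  }
  Xs <- Xp[, mask, drop = FALSE]

  # outlier screen on an initial CV-sized model
  crit0 <- cross_validate(Xs, y, scheme, max_lv = config$max_lv,
                          criterion = "misclass")
  lv0 <- select_n_lv(crit0)
  fit0 <- fit_pls(Xs, y, n_lv = lv0)
  lim <- diagnostic_limits(fit0, Xs, confidence = config$outlier_confidence)
  out_mask <- q_residuals(fit0, Xs) > lim$q_limit |
    hotelling_t2(fit0, Xs) > lim$t2_limit
  keep <- !out_mask
  if (any(tapply(keep, labels, sum) == 0)) {
    stop("outlier removal emptied a class")
  }

  crit <- cross_validate(Xs[keep, , drop = FALSE], y[keep], scheme,
                         max_lv = config$max_lv, criterion = "misclass")
  n_lv <- select_n_lv(crit)
  pls <- fit_pls(Xs[keep, , drop = FALSE], y[keep], n_lv = n_lv)
  lim <- diagnostic_limits(pls, Xs[keep, , drop = FALSE],
                           confidence = config$outlier_confidence)

  yhat <- predict(pls, Xs[keep, , drop = FALSE])[, 1]
  kept_labels <- labels[keep]
  n_kept <- sum(keep)
  gaussians <- list()
  for (cl in c("class1", "class2")) {
    v <- yhat[kept_labels == cl]
    prior <- if (config$equal_priors) 0.5 else length(v) / n_kept
    gaussians[[cl]] <- list(mean = mean(v), sd = stats::sd(v), prior = prior)
  }

  structure(
    list(version = 1L,
         grid = dataset$grid,
         preprocess = config$preprocess,
         variable_mask = mask,
         selection = selection,
         pls = pls,
         gaussians = gaussians,
         encoding = enc,
         prob_threshold = config$prob_threshold,
         diagnostics = lim,
         cv_criterion = crit,
         n_outliers_removed = sum(out_mask),
         n_train = n_kept,
         white_ref = white_ref,
         qc = config$qc,
         seed = config$seed),
    class = "plsda_model"
  )
}

#' Configuration of the PLS-DA calibration pipeline
#'
#' @param thc_threshold class split (wt% THC), default 0.4.
#' @param prob_threshold posterior needed for a certain verdict, in
#'   (0.5, 1); default 0.60 -- a posterior of exactly 0.60 counts as
#'   certain.
#' @param preprocess a [preprocess_config()].
#' @param ipls_enabled run forward iPLS (default TRUE).
#' @param ipls_interval_size variables per interval (default 5).
#' @param variable_mask logical mask to use instead of running iPLS.
#' @param max_lv largest component count assessed (default 8).
#' @param cv_folds folds of the 90/10 scheme (default 10).
#' @param outlier_confidence Q/T-squared limit confidence (default 0.95).
#' @param equal_priors use equal class priors instead of training
#'   proportions (default FALSE).
#' @param qc a [qc_thresholds()] embedded in the model for triplet input.
#' @param seed master seed of every stochastic step (CV shuffles).
#' @return A `plsda_config` list.
#' @export
plsda_config <- function(thc_threshold = 0.4, prob_threshold = 0.60,
                         preprocess = preprocess_config(),
                         ipls_enabled = TRUE, ipls_interval_size = 5,
                         variable_mask = NULL, max_lv = 8, cv_folds = 10,
                         outlier_confidence = 0.95, equal_priors = FALSE,
                         qc = qc_thresholds(), seed = 1) {
  if (prob_threshold <= 0.5 || prob_threshold >= 1) {
    stop("prob_threshold must be in (0.5, 1)")
  }
  structure(list(thc_threshold = thc_threshold,
                 prob_threshold = prob_threshold,
                 preprocess = preprocess, ipls_enabled = ipls_enabled,
                 ipls_interval_size = ipls_interval_size,
                 variable_mask = variable_mask, max_lv = max_lv,
                 cv_folds = cv_folds,
                 outlier_confidence = outlier_confidence,
                 equal_priors = equal_priors, qc = qc,
                 seed = as.integer(seed)),
            class = "plsda_config")
}

#' Classify one spectrum (or raw scan triplet)
#'
#' Runs the on-device evaluation for a single sensor module: for a raw
#' [scan_triplet()], the QC gates, triplet averaging and white-reference
#' absorbance come first (a QC failure is an error carrying the
#' `qc_report`); the absorbance spectrum is then preprocessed, masked to
#' the selected wavelengths, pushed through the PLS regression vector,
#' and the predicted value is converted to Bayes posteriors. The verdict
#' is the class with the larger posterior when that posterior reaches
#' the probability threshold (default 0.60), otherwise `"uncertain"`.
#'
#' @param model a [fit_plsda()] model.
#' @param x an absorbance `nir_spectrum`, a numeric absorbance vector on
#'   the model grid, or a `scan_triplet` of raw intensity scans.
#' @return A `classification_outcome`: `y_pred`, `p_class1`,
#'   `p_class2`, `verdict` (`"unsuspicious"`, `"suspicious"`,
#'   `"uncertain"`).
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "plsda_model"))
  if (inherits(x, "scan_triplet")) {
    rep_qc <- run_qc(x, model$qc)
    if (!rep_qc$passed) {
      cond <- structure(
        class = c("qc_failure", "error", "condition"),
        list(message = paste0("QC failed: ", rep_qc$failure_reason),
             call = sys.call(), qc_report = rep_qc))
      stop(cond)
    }
    if (is.null(model$white_ref)) {
      stop("model carries no white reference; cannot process raw scans")
    }
    wr <- nir_spectrum(model$white_ref, model$grid, kind = "intensity")
    x <- compute_absorbance(average_triplet(x), wr)
  }
  values <- if (inherits(x, "nir_spectrum")) x$values else as.numeric(x)
  if (length(values) != length(model$grid$values)) {
    stop("spectrum is not on the model grid")
  }
  xp <- preprocess(values, model$preprocess)
  y_pred <- predict(model$pls, matrix(xp[model$variable_mask], nrow = 1))[, 1]
  p <- bayes_probability(y_pred, model$gaussians)
  verdict <- verdict_from_posteriors(p[1, 1], p[1, 2], model$prob_threshold,
                                     model$encoding)
  structure(list(y_pred = unname(y_pred),
                 p_class1 = unname(p[1, 1]), p_class2 = unname(p[1, 2]),
                 verdict = verdict),
            class = "classification_outcome")
}

# certain verdict only when the winning posterior reaches the
# threshold; exactly at the threshold counts as certain
verdict_from_posteriors <- function(p1, p2, prob_threshold, encoding) {
  if (max(p1, p2) >= prob_threshold) {
    if (p1 >= p2) encoding$class1 else encoding$class2
  } else {
    "uncertain"
  }
}

#' Tabulate verdicts against reference labels
#'
#' Outcome percentages in the layout of the sensor's validation
#' summary: correct / wrong / uncertain over all items, the same
#' excluding the uncertain predictions (denominator `n - k` for `k`
#' uncertain), a per-class breakdown, and the raw confusion counts. A
#' verdict is correct when `"unsuspicious"` meets a class-1 label or
#' `"suspicious"` meets class 2.
#'
#' @param verdicts character vector of verdicts.
#' @param true_labels class labels (`class1`/`class2` factor).
#' @return An `outcome_summary` list.
#' @export
summarize_outcomes <- function(verdicts, true_labels) {
  verdicts <- as.character(verdicts)
  true_labels <- as.character(true_labels)
  n <- length(verdicts)
  if (!n) stop("no outcomes to summarize")
  if (length(true_labels) != n) stop("verdicts and labels differ in length")
  verdict_class <- ifelse(verdicts == "unsuspicious", "class1",
                          ifelse(verdicts == "suspicious", "class2", NA))
  uncertain <- is.na(verdict_class)
  correct <- !uncertain & verdict_class == true_labels
  wrong <- !uncertain & verdict_class != true_labels
  pct <- function(k, d) if (d > 0) 100 * k / d else NA_real_
  per_class <- lapply(c(class1 = "class1", class2 = "class2"), function(cl) {
    in_cl <- true_labels == cl & !uncertain
    list(correct_pct = pct(sum(correct & true_labels == cl), sum(in_cl)),
         wrong_pct = pct(sum(wrong & true_labels == cl), sum(in_cl)),
         n_certain = sum(in_cl))
  })
  structure(
    list(n = n,
         correct_pct = pct(sum(correct), n),
         wrong_pct = pct(sum(wrong), n),
         uncertain_pct = pct(sum(uncertain), n),
         excluding_uncertain = list(
           correct_pct = pct(sum(correct), n - sum(uncertain)),
           wrong_pct = pct(sum(wrong), n - sum(uncertain)),
           certain_frac_pct = pct(n - sum(uncertain), n)),
         per_class = per_class,
         counts = c(correct = sum(correct), wrong = sum(wrong),
                    uncertain = sum(uncertain))),
    class = "outcome_summary"
  )
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("n = %d spectra\n", x$n))
  cat(sprintf("  correct %.1f%% | wrong %.1f%% | uncertain %.1f%%\n",
              x$correct_pct, x$wrong_pct, x$uncertain_pct))
  cat(sprintf("  excluding uncertain (%.1f%% of spectra): correct %.1f%% | wrong %.1f%%\n",
              x$excluding_uncertain$certain_frac_pct,
              x$excluding_uncertain$correct_pct,
              x$excluding_uncertain$wrong_pct))
  invisible(x)
}

#' THC potency regression (PLS-R)
#'
#' Continuous THC prediction with the same preprocessing as the
#' classifier, as a reference point for why classification (not
#' potency estimation) is the device's task: potency RMSEPs of a few
#' wt% cannot separate classes at a 0.4 wt% threshold. A held-out
#' fraction is split off with the config seed; the component count is
#' chosen by cross-validated RMSECV on the training part.
#'
#' @param dataset a [spectral_dataset()] with `thc_wt_pct` present.
#' @param config a [plsda_config()] (preprocessing/CV/seed fields used).
#' @param holdout_frac held-out fraction for RMSEP/R-squared (default 0.25).
#' @return List: `model` ([fit_pls()] fit), `n_lv`, `rmsep`,
#'   `r_squared`, `holdout` (row indices).
#' @export
fit_potency_plsr <- function(dataset, config = plsda_config(),
                             holdout_frac = 0.25) {
  thc <- dataset$meta$thc_wt_pct
  if (anyNA(thc)) stop("reference THC values required")
  Xp <- t(apply(dataset$X, 1, preprocess, config = config$preprocess))
  n <- nrow(Xp)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(config$seed)
  holdout <- sort(sample.int(n, max(2, round(holdout_frac * n))))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  train <- setdiff(seq_len(n), holdout)
  scheme <- cv_scheme(n_folds = config$cv_folds, shuffle_seed = config$seed,
                      stratified = FALSE)
  crit <- cross_validate(Xp[train, , drop = FALSE], thc[train], scheme,
                         max_lv = config$max_lv, criterion = "rmsecv")
  n_lv <- select_n_lv(crit)
  fit <- fit_pls(Xp[train, , drop = FALSE], thc[train], n_lv = n_lv)
  pred <- predict(fit, Xp[holdout, , drop = FALSE])[, 1]
  list(model = fit, n_lv = n_lv,
       rmsep = rmsep(thc[holdout], pred),
       r_squared = r_squared(thc[holdout], pred),
       holdout = holdout)
}
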