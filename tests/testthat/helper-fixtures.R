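# Shared fixture builders for the suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# SVD pseudo-inverse, independent of any package internals
MASS_pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# a triplet of intensity scans from explicit value vectors
make_triplet <- function(v1, v2, v3, grid = make_grid(1550, 1560, 5),
                         module = "m1") {
  scans <- lapply(list(v1, v2, v3), function(v) {
    nir_spectrum(v, grid, kind = "intensity",
                 meta = spectrum_meta("fix", module_id = module))
  })
  scan_triplet(scans)
}

# random smooth-ish positive spectra matrix for oracle tests
random_spectra <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(n * p, 0.5, 1.5), n, p)
}

# small labeled dataset with one informative wavelength block:
# columns in `signal_cols` carry the class difference, the rest is noise
blocked_class_data <- function(n = 60, p = 20, signal_cols = 6:10,
                               delta = 1, noise = 0.1, seed = 42) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  X <- matrix(stats::rnorm(n * p, 0, noise), n, p)
  X[, signal_cols] <- X[, signal_cols] + outer(y, rep(delta / 2,
                                                      length(signal_cols)))
  list(X = X, y = y, labels = factor(ifelse(y > 0, "class1", "class2"),
                                     levels = c("class1", "class2")))
}

# moderate-size trained classifier reused across tests (built once)
.fixture_env <- new.env(parent = emptyenv())
fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    ds <- simulate_dataset(n_samples = 120, seed = 11)
    .fixture_env$train <- ds
    wr <- nirclass:::white_reference_values(ds$grid)
    .fixture_env$model <- fit_plsda(ds, plsda_config(seed = 11),
                                    white_ref = wr)
  }
  .fixture_env$model
}
fixture_train <- function() {
  fixture_model()
  .fixture_env$train
}

# hand-built classifier around explicit Gaussians, for verdict-logic
# tests that need exact posteriors without a fitted pipeline
toy_plsda_model <- function(mu1 = 1, mu2 = -1, sd1 = 0.5, sd2 = 0.5,
                            prior1 = 0.5, prob_threshold = 0.60) {
  grid <- make_grid(1550, 1560, 5)
  pls <- structure(
    list(x_mean = c(0, 0, 0), y_mean = 0,
         W = matrix(c(1, 0, 0), 3, 1), P = matrix(c(1, 0, 0), 3, 1),
         Q = matrix(1, 1, 1), B = matrix(c(1, 0, 0), 3, 1),
         score_variances = 1, n_lv = 1, n_train = 10),
    class = "pls_model")
  structure(
    list(version = 1L, grid = grid, preprocess = preprocess_config(),
         variable_mask = rep(TRUE, 3), selection = NULL, pls = pls,
         gaussians = list(class1 = list(mean = mu1, sd = sd1, prior = prior1),
                          class2 = list(mean = mu2, sd = sd2,
                                        prior = 1 - prior1)),
         encoding = class_encoding(), prob_threshold = prob_threshold,
         diagnostics = NULL, cv_criterion = NULL,
         n_outliers_removed = 0L, n_train = 10, white_ref = NULL,
         qc = qc_thresholds(), seed = 1L),
    class = "plsda_model")
}

# end-to-end workflow tests run inside a temp dir with a small config
small_config <- function(dir, seed = 81, n = 60) {
  cfg <- default_run_config()
  cfg$seed <- seed
  cfg$simulate$n_samples <- n
  cfg$paths <- list(train_csv = file.path(dir, "train.csv"),
                    model = file.path(dir, "model.json"),
                    input_csv = file.path(dir, "input.csv"),
                    out_prefix = file.path(dir, "run"))
  structure(cfg, class = "run_config")
}
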