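test_that("labels split at the 0.4 wt% THC threshold (threshold is legal)", {
  expect_equal(as.character(encode_labels(0.4)), "class1")
  expect_equal(as.character(encode_labels(0.4000001)), "class2")
  expect_equal(as.character(encode_labels(c(0.02, 24.38))),
               c("class1", "class2"))
  expect_error(encode_labels(-0.1), "negative")
  expect_error(encode_labels(NaN), "finite")
  # custom threshold
  expect_equal(as.character(encode_labels(0.35, threshold = 0.3)), "class2")
})

test_that("Bayes posteriors follow the normal-density ratio and normalize", {
  g <- list(class1 = list(mean = 1, sd = 0.5, prior = 0.5),
            class2 = list(mean = -1, sd = 0.5, prior = 0.5))
  # midpoint with equal priors and sds: exactly (0.5, 0.5)
  expect_equal(unname(bayes_probability(0, g)[1, ]), c(0.5, 0.5))
  # at a mean 10+ sd away from the other class
  expect_gt(bayes_probability(1, g)[1, 1], 0.999)

  # arbitrary parameters against direct density evaluation
  set.seed(61)
  for (rep in 1:20) {
    mu <- rnorm(2, 0, 2); sdv <- runif(2, 0.2, 2); pi1 <- runif(1, 0.05, 0.95)
    y <- rnorm(1, 0, 3)
    gg <- list(class1 = list(mean = mu[1], sd = sdv[1], prior = pi1),
               class2 = list(mean = mu[2], sd = sdv[2], prior = 1 - pi1))
    p <- bayes_probability(y, gg)
    d1 <- pi1 * dnorm(y, mu[1], sdv[1])
    d2 <- (1 - pi1) * dnorm(y, mu[2], sdv[2])
    expect_equal(unname(p[1, 1]), d1 / (d1 + d2), tolerance = 1e-12)
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  # extreme inputs stay normalized (log-space evaluation)
  expect_equal(unname(rowSums(bayes_probability(c(-50, 50), g))), c(1, 1))
  expect_error(bayes_probability(Inf, g), "finite")
})

test_that("verdicts follow the winning posterior and the 60% rule", {
  # engineered model: identity spectrum path, y_pred = first masked value
  m <- toy_plsda_model(mu1 = 1, mu2 = -1, sd1 = 1, sd2 = 1,
                       prob_threshold = 0.60)
  y_at <- function(p1) {
    # invert the symmetric posterior: y with p_class1 = p1
    log(p1 / (1 - p1)) / 2
  }
  probe <- function(y) {
    xp <- c(y, 0, 0)
    p <- bayes_probability(y, m$gaussians)
    nirclass:::verdict_from_posteriors(p[1, 1], p[1, 2], m$prob_threshold,
                                       m$encoding)
  }
  expect_equal(probe(y_at(0.61)), "unsuspicious")
  expect_equal(probe(y_at(0.50)), "uncertain")
  expect_equal(probe(y_at(0.05)), "suspicious")
  # boundary: a posterior of exactly 0.60 counts as certain
  expect_equal(nirclass:::verdict_from_posteriors(0.60, 0.40, 0.60,
                                                  m$encoding),
               "unsuspicious")
  expect_equal(nirclass:::verdict_from_posteriors(0.40, 0.60, 0.60,
                                                  m$encoding),
               "suspicious")

  # monotone in the threshold: raising it never makes an uncertain
  # outcome certain
  for (p1 in c(0.52, 0.58, 0.63, 0.71, 0.95)) {
    v_low <- nirclass:::verdict_from_posteriors(p1, 1 - p1, 0.6,
                                                m$encoding)
    v_high <- nirclass:::verdict_from_posteriors(p1, 1 - p1, 0.8,
                                                 m$encoding)
    if (v_low == "uncertain") expect_equal(v_high, "uncertain")
  }
})

test_that("classify runs the full spectrum path and QC-gates triplets", {
  m <- fixture_model()
  ds <- fixture_train()
  out <- classify(m, ds$X[1, ])
  expect_s3_class(out, "classification_outcome")
  expect_lt(abs(out$p_class1 + out$p_class2 - 1), 1e-12)
  expect_true(out$verdict %in% c("unsuspicious", "suspicious", "uncertain"))

  # hand-composed path equals classify()
  xp <- preprocess(ds$X[1, ], m$preprocess)
  y_manual <- predict(m$pls, matrix(xp[m$variable_mask], nrow = 1))[, 1]
  expect_equal(out$y_pred, unname(y_manual))

  # a moved triplet raises a qc_failure carrying the report
  rec <- simulate_record(sample_spec(5, seed = 77), movement = TRUE)
  err <- tryCatch(classify(m, rec$triplets[[1]]), qc_failure = function(e) e)
  expect_s3_class(err, "qc_failure")
  expect_equal(err$qc_report$failure_reason, "movement")

  # a clean triplet classifies through QC + absorbance
  rec2 <- simulate_record(sample_spec(12, seed = 78, spot_cv = 0))
  out2 <- classify(m, rec2$triplets[[1]])
  expect_equal(out2$verdict, "suspicious")
})

test_that("calibration separates well-separated synthetic classes", {
  ds <- simulate_dataset(n_samples = 80, seed = 62, noise_sd = 2,
                         spot_cv = 0.05)
  m <- fit_plsda(ds, plsda_config(seed = 62))
  Xp <- t(apply(ds$X, 1, preprocess, config = m$preprocess))
  yhat <- predict(m$pls, Xp[, m$variable_mask, drop = FALSE])[, 1]
  labels <- encode_labels(ds$meta$thc_wt_pct)
  train_misclass <- mean(ifelse(yhat > 0, "class1", "class2") != labels)
  expect_lt(train_misclass, 0.05)

  # two regression vectors of a binary model are sign mirrors: coding
  # class 2 as +1 instead of class 1 negates B
  y1 <- ifelse(labels == "class1", 1, -1)
  f1 <- fit_pls(Xp[, m$variable_mask], y1, n_lv = m$pls$n_lv)
  f2 <- fit_pls(Xp[, m$variable_mask], -y1, n_lv = m$pls$n_lv)
  expect_equal(f1$B, -f2$B, tolerance = 1e-10)
})

test_that("class Gaussians are invariant to dataset duplication", {
  ds <- simulate_dataset(n_samples = 40, seed = 63)
  cfg <- plsda_config(seed = 63, ipls_enabled = FALSE,
                      outlier_confidence = 0.999999)
  m1 <- fit_plsda(ds, cfg)
  dup <- spectral_dataset(rbind(ds$X, ds$X), ds$grid,
                          rbind(ds$meta, ds$meta))
  m2 <- fit_plsda(dup, cfg)
  for (cl in c("class1", "class2")) {
    expect_equal(m1$gaussians[[cl]]$mean, m2$gaussians[[cl]]$mean,
                 tolerance = 1e-6)
    # population-consistent check: sample sd on the doubled data uses
    # 2n - 1; compare variances on the population convention
    n1 <- sum(encode_labels(ds$meta$thc_wt_pct) == cl)
    v1 <- m1$gaussians[[cl]]$sd^2 * (n1 - 1) / n1
    v2 <- m2$gaussians[[cl]]$sd^2 * (2 * n1 - 1) / (2 * n1)
    expect_equal(v1, v2, tolerance = 1e-6)
    expect_equal(m1$gaussians[[cl]]$prior, m2$gaussians[[cl]]$prior)
  }
})

test_that("calibration rejects degenerate inputs", {
  ds <- simulate_dataset(n_samples = 40, seed = 64)
  sel <- ds$meta$thc_wt_pct > 0.4
  one_class <- spectral_dataset(ds$X[sel, ], ds$grid, ds$meta[sel, ])
  expect_error(fit_plsda(one_class, plsda_config()), "each class")
  ds_na <- ds
  ds_na$meta$thc_wt_pct[1] <- NA
  expect_error(fit_plsda(ds_na, plsda_config()), "reference THC")
  expect_error(plsda_config(prob_threshold = 0.5), "prob_threshold")
})

test_that("outcome summaries match a manual tally", {
  v <- c("unsuspicious", "unsuspicious", "suspicious")
  lab <- c("class1", "class1", "class2")
  s <- summarize_outcomes(v, lab)
  expect_equal(s$correct_pct, 100)
  expect_equal(s$wrong_pct, 0)
  expect_equal(s$uncertain_pct, 0)

  # 10-item fixture: 5 correct, 3 wrong, 2 uncertain
  v10 <- c("unsuspicious", "suspicious", "uncertain", "suspicious",
           "unsuspicious", "uncertain", "suspicious", "unsuspicious",
           "suspicious", "unsuspicious")
  l10 <- c("class1", "class2", "class1", "class1",
           "class2", "class2", "class2", "class1",
           "class1", "class1")
  s10 <- summarize_outcomes(v10, l10)
  expect_equal(unname(s10$counts), c(5, 3, 2))
  expect_equal(s10$correct_pct, 50)
  expect_equal(s10$uncertain_pct, 20)
  # excluding view divides by n - k uncertain
  expect_equal(s10$excluding_uncertain$correct_pct, 100 * 5 / 8)
  expect_equal(s10$excluding_uncertain$certain_frac_pct, 80)
  expect_error(summarize_outcomes(character(0), character(0)), "no outcomes")
})

test_that("potency PLS-R recovers a noiseless linear world and degrades with noise", {
  ds0 <- simulate_dataset(n_samples = 60, seed = 65, noise_sd = 0,
                          spot_cv = 0, scatter_mult_sd = 0,
                          baseline_sd = 0)
  res0 <- fit_potency_plsr(ds0, plsda_config(seed = 65))
  expect_gt(res0$r_squared, 0.95)

  # RMSEP/R2 formulas on 5 hand predictions
  expect_equal(rmsep(1:5, c(2, 2, 3, 4, 4)), sqrt(2 / 5))
  expect_equal(r_squared(1:5, c(2, 2, 3, 4, 4)), 1 - 2 / 10)

  # Monte-Carlo trend: prediction error grows with scan noise
  errs <- sapply(c(0, 30, 300), function(ns) {
    d <- simulate_dataset(n_samples = 50, seed = 66, noise_sd = ns,
                          spot_cv = 0)
    fit_potency_plsr(d, plsda_config(seed = 66))$rmsep
  })
  expect_true(all(diff(errs) > 0))
})

test_that("model JSON round trip reproduces classifications", {
  m <- fixture_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  ds <- fixture_train()
  for (i in c(1, 10, 50)) {
    o1 <- classify(m, ds$X[i, ])
    o2 <- classify(m2, ds$X[i, ])
    expect_identical(o1$verdict, o2$verdict)
    expect_equal(o1$y_pred, o2$y_pred, tolerance = 1e-12)
    expect_equal(o1$p_class1, o2$p_class1, tolerance = 1e-12)
  }
  expect_error(load_model(withr::local_tempfile(lines = "{}")), "version")
})
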