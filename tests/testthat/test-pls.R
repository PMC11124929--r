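test_that("PLS with one LV on a univariate x equals simple regression", {
  set.seed(31)
  x <- rnorm(25)
  y <- 2 + 3 * x + rnorm(25, 0, 0.2)
  fit <- fit_pls(matrix(x, ncol = 1), y, n_lv = 1)
  ols <- lm(y ~ x)
  expect_equal(predict(fit, matrix(x, ncol = 1))[, 1],
               unname(fitted(ols)), tolerance = 1e-10)
})

test_that("full-rank PLS equals multiple linear regression", {
  set.seed(32)
  for (rep in 1:4) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rnorm(20)
    fit <- fit_pls(X, y, n_lv = 8)
    Xc <- sweep(X, 2, colMeans(X))
    b <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))  # normal equations
    pred_ols <- mean(y) + Xc %*% b
    pred_pls <- predict(fit, X)
    expect_lt(max(abs(pred_pls - pred_ols)) / max(abs(pred_ols)), 1e-8)
  }
})

test_that("a response orthogonal to X gives the null model", {
  X <- matrix(c(1, -1, 1, -1,
                1, 1, -1, -1), 4, 2)
  y <- c(1, 1, 1, 1)             # zero variance => orthogonal to centered X
  fit <- fit_pls(X, y, n_lv = 2)
  expect_equal(unname(fit$B), matrix(0, 2, 1))
  expect_equal(predict(fit, X)[, 1], rep(1, 4))
})

test_that("prediction respects centering and dimensions", {
  set.seed(33)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  fit <- fit_pls(X, y, n_lv = 2)
  expect_equal(predict(fit, fit$x_mean)[1, 1], unname(fit$y_mean))
  expect_error(predict(fit, matrix(0, 1, 4)), "columns")
  expect_error(fit_pls(X, y, n_lv = 9), "exceeds")
  expect_error(fit_pls(X[1, , drop = FALSE], y[1], 1), "at least 2")
})

test_that("training scores are orthogonal and training RMSE is monotone", {
  set.seed(34)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- X %*% rnorm(10) + rnorm(40, 0, 0.5)
  fit <- fit_pls(X, y, n_lv = 6)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  rmse <- vapply(1:6, function(a) {
    sqrt(mean((predict(fit, X, n_lv = a) - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("cross-validation matches a naive refit-per-fold loop", {
  set.seed(35)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- X %*% rnorm(6) + rnorm(40, 0, 0.3)
  scheme <- cv_scheme(n_folds = 5, shuffle_seed = 7, stratified = FALSE)
  got <- cross_validate(X, y, scheme, max_lv = 4, criterion = "rmsecv")

  folds <- nirclass:::cv_folds(40, scheme)
  naive <- sapply(1:4, function(a) {
    pred <- numeric(40)
    for (k in 1:5) {
      te <- folds == k
      f <- fit_pls(X[!te, ], y[!te], n_lv = a)
      pred[te] <- predict(f, X[te, , drop = FALSE])
    }
    sqrt(mean((pred - y)^2))
  })
  expect_equal(unname(got), naive, tolerance = 1e-10)

  # determinism: same scheme, same folds, same curve
  expect_equal(cross_validate(X, y, scheme, max_lv = 4), got)
})

test_that("a noiseless linear response cross-validates to zero error", {
  set.seed(36)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- X %*% c(1, -2, 0.5, 3, -1)
  crit <- cross_validate(X, y, cv_scheme(10, 1, FALSE), max_lv = 5)
  expect_lt(min(crit), 1e-8)
})

test_that("misclassification CV counts match a manual tally and drive LV choice", {
  d <- blocked_class_data(n = 40, p = 8, signal_cols = 1:3, delta = 3,
                          noise = 0.3, seed = 37)
  scheme <- cv_scheme(n_folds = 5, shuffle_seed = 2)
  crit <- cross_validate(d$X, d$y, scheme, max_lv = 3,
                         criterion = "misclass")
  folds <- nirclass:::cv_folds(40, scheme, classes = sign(d$y))
  naive <- sapply(1:3, function(a) {
    wrong <- 0
    for (k in 1:5) {
      te <- folds == k
      f <- fit_pls(d$X[!te, ], d$y[!te], n_lv = a)
      wrong <- wrong + sum(sign(predict(f, d$X[te, , drop = FALSE])) !=
                             sign(d$y[te]))
    }
    wrong
  })
  expect_equal(unname(crit), naive)
  expect_equal(select_n_lv(c(4, 2, 2, 3)), 2)   # parsimony on ties
})

test_that("Q residuals match the brute-force projector", {
  set.seed(38)
  X <- matrix(rnorm(30 * 7), 30, 7)
  y <- X %*% rnorm(7) + rnorm(30, 0, 0.4)
  fit <- fit_pls(X, y, n_lv = 3)
  Xnew <- matrix(rnorm(5 * 7), 5, 7)
  Q <- q_residuals(fit, Xnew)
  P <- fit$P
  # independent oracle: residual of the orthogonal projector onto P
  anti <- diag(7) - P %*% MASS_pinv(P)
  Xc <- sweep(Xnew, 2, fit$x_mean)
  brute <- rowSums((Xc %*% anti)^2)
  expect_equal(Q, brute, tolerance = 1e-10)

  # a point reconstructed from the model subspace has Q = 0
  t_some <- matrix(rnorm(3), 1, 3)
  x_in_span <- fit$x_mean + (t_some %*% t(P))[1, ]
  expect_lt(q_residuals(fit, x_in_span), 1e-16 * sum(x_in_span^2))
})

test_that("Hotelling T2 is zero at the center and scales with score variance", {
  set.seed(39)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rnorm(30)
  fit <- fit_pls(X, y, n_lv = 2)
  expect_equal(hotelling_t2(fit, fit$x_mean)[1], 0)
  # training T2 mean equals the component count (score normalization)
  expect_equal(mean(hotelling_t2(fit, X)), 2 * (30 - 1) / 30,
               tolerance = 1e-8)
})

test_that("diagnostic limits behave like 95% limits on clean data", {
  set.seed(40)
  X <- matrix(rnorm(400 * 10), 400, 10)
  y <- X %*% rnorm(10) + rnorm(400)
  fit <- fit_pls(X, y, n_lv = 3)
  lim <- diagnostic_limits(fit, X, confidence = 0.95)
  expect_gt(lim$q_limit, 0)
  expect_gt(lim$t2_limit, 0)
  frac_q <- mean(q_residuals(fit, X) > lim$q_limit)
  frac_t <- mean(hotelling_t2(fit, X) > lim$t2_limit)
  expect_lt(frac_q, 0.12)
  expect_lt(frac_t, 0.12)
  expect_error(diagnostic_limits(fit, X, confidence = 1.2), "confidence")
})

test_that("error summaries agree with hand computation on 5 points", {
  y <- c(1, 2, 3, 4, 5)
  yh <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  expect_equal(rmsep(y, yh),
               sqrt((0.1^2 + 0.1^2 + 0.2^2 + 0.2^2 + 0.1^2) / 5))
  expect_equal(r_squared(y, yh), 1 - 0.11 / 10)
})
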