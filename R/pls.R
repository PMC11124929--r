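#' Mean-centered PLS regression by NIPALS
#'
#' The numeric engine shared by the potency regression (PLS-R) and the
#' classifier (PLS-DA). X and Y are mean-centered; components are
#' extracted by the NIPALS recursion with deflation of both blocks, and
#' the weights/loadings are collapsed into a single regression matrix
#' `B` so that `Y_hat = (X_new - x_mean) B + y_mean`.
#'
#' @param X numeric matrix n x p (rows = preprocessed spectra).
#' @param Y numeric response: vector or n x m matrix (class code or
#'   concentration).
#' @param n_lv number of latent variables, `<= min(n - 1, p)`.
#' @param tol NIPALS convergence tolerance on the weight vector.
#' @return An object of class `pls_model` with `x_mean`, `y_mean`,
#'   `W` (weights), `P` (X loadings), `Q` (Y loadings), `B`
#'   (regression coefficients), `scores` (training scores T),
#'   `score_variances`, `n_lv`.
#' @export
fit_pls <- function(X, Y, n_lv, tol = 1e-10) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y row counts differ")
  if (n < 2) stop("need at least 2 samples")
  if (n_lv > min(n - 1, p)) {
    stop(sprintf("n_lv = %d exceeds min(n - 1, p) = %d", n_lv, min(n - 1, p)))
  }
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, m, n_lv); Tm <- matrix(0, n, n_lv)
  n_comp <- 0L
  for (a in seq_len(n_lv)) {
    u <- Yc[, which.max(colSums(Yc^2)), drop = TRUE]
    if (sum(u^2) < .Machine$double.eps) break   # Y fully deflated
    w_old <- NULL
    repeat {
      w <- crossprod(Xc, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) {
        w <- rep(0, p)
        break
      }
      w <- w / nw
      tt <- Xc %*% w
      q <- crossprod(Yc, tt)[, 1] / sum(tt^2)
      u <- (Yc %*% q)[, 1] / sum(q^2)
      if (!is.null(w_old) && sqrt(sum((w - w_old)^2)) < tol) break
      if (m == 1) break                          # PLS1: one pass is exact
      w_old <- w
    }
    if (all(w == 0)) break
    tt <- (Xc %*% w)[, 1]
    tss <- sum(tt^2)
    pp <- crossprod(Xc, tt)[, 1] / tss
    qq <- crossprod(Yc, tt)[, 1] / tss
    Xc <- Xc - tcrossprod(tt, pp)
    Yc <- Yc - tcrossprod(tt, qq)
    W[, a] <- w; P[, a] <- pp; Q[, a] <- qq; Tm[, a] <- tt
    n_comp <- a
  }
  # trim unextracted components (Y exhausted or no covariance left)
  keep <- seq_len(max(n_comp, 1L))
  model <- structure(
    list(x_mean = x_mean, y_mean = y_mean,
         W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
         Q = Q[, keep, drop = FALSE], scores = Tm[, keep, drop = FALSE],
         score_variances = apply(Tm[, keep, drop = FALSE], 2, stats::var),
         n_lv = max(n_comp, 1L), n_comp = n_comp, n_train = n),
    class = "pls_model"
  )
  model$B <- regression_coefs(model, model$n_lv)
  model
}

# collapse weights/loadings of the first a components into B (p x m)
regression_coefs <- function(model, a) {
  if (!is.null(model$n_comp) && model$n_comp == 0L) {
    return(matrix(0, length(model$x_mean), nrow(model$Q)))
  }
  W <- model$W[, seq_len(a), drop = FALSE]
  P <- model$P[, seq_len(a), drop = FALSE]
  Q <- model$Q[, seq_len(a), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))   # projection weights
  R %*% t(Q)
}

#' Predict responses from a fitted PLS model
#'
#' @param object a [fit_pls()] model.
#' @param X_new matrix (or vector) with the training column count.
#' @param n_lv predict with the first `n_lv` components (default: all).
#' @param ... unused.
#' @return n x m matrix of predicted responses.
#' @export
predict.pls_model <- function(object, X_new, n_lv = object$n_lv, ...) {
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$x_mean)) {
    stop(sprintf("X_new has %d columns, model expects %d",
                 ncol(X_new), length(object$x_mean)))
  }
  if (n_lv > object$n_lv) stop("n_lv exceeds the fitted component count")
  B <- if (n_lv == object$n_lv) object$B else regression_coefs(object, n_lv)
  sweep(sweep(X_new, 2, object$x_mean) %*% B, 2, object$y_mean, `+`)
}

#' Cross-validation scheme
#'
#' The 90/10 scheme used throughout: 10-fold cross-validation realized
#' as a venetian-blind assignment after a seeded shuffle, stratified by
#' class in discriminant mode so each fold sees both classes.
#'
#' @param n_folds number of folds (default 10, i.e. 90/10).
#' @param shuffle_seed integer seed for the shuffle.
#' @param stratified stratify folds by class label (DA mode).
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(n_folds = 10, shuffle_seed = 1, stratified = TRUE) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(n_folds = as.integer(n_folds),
                 shuffle_seed = as.integer(shuffle_seed),
                 stratified = isTRUE(stratified)),
            class = "cv_scheme")
}

# fold assignment: seeded shuffle then venetian blinds, within class
# strata when requested. Localizes the RNG so callers' streams are
# untouched.
cv_folds <- function(n, scheme, classes = NULL) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  folds <- integer(n)
  set.seed(scheme$shuffle_seed)
  if (scheme$stratified && !is.null(classes)) {
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(scheme$n_folds), length(idx))
    }
  } else {
    idx <- sample.int(n)
    folds[idx] <- rep_len(seq_len(scheme$n_folds), n)
  }
  folds
}

#' Cross-validated model-size criterion
#'
#' For each latent-variable count `1..max_lv`, fits on the training
#' folds and scores the held-out fold, returning the out-of-fold
#' criterion: root-mean-squared error (`"rmsecv"`) for regression, or
#' the misclassification count (`"misclass"`) for discriminant mode
#' where `Y` is the +1/-1 class code and the decision threshold is the
#' centered midpoint 0. Folds are deterministic given the scheme seed.
#'
#' @param X,Y training data (Y a vector / single column).
#' @param scheme a [cv_scheme()].
#' @param max_lv largest component count to assess.
#' @param criterion `"rmsecv"` or `"misclass"`.
#' @return Numeric vector of length `max_lv` (criterion per LV count).
#' @export
cross_validate <- function(X, Y, scheme = cv_scheme(), max_lv = 8,
                           criterion = c("rmsecv", "misclass")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X); y <- as.numeric(Y)
  n <- nrow(X)
  if (n < scheme$n_folds) stop("fewer samples than folds")
  classes <- if (criterion == "misclass") sign(y) else NULL
  folds <- cv_folds(n, scheme, classes)
  max_lv <- min(max_lv, ncol(X), n - ceiling(n / scheme$n_folds) - 1)
  pred <- matrix(NA_real_, n, max_lv)
  for (k in seq_len(scheme$n_folds)) {
    test <- folds == k
    if (!any(test)) next
    if (criterion == "misclass" && length(unique(sign(y[!test]))) < 2) {
      warning("fold ", k, " trains on a single class; fold kept")
    }
    fit <- fit_pls(X[!test, , drop = FALSE], y[!test], n_lv = max_lv)
    for (a in seq_len(max_lv)) {
      # rank-deficient folds may extract fewer components
      pred[test, a] <- predict(fit, X[test, , drop = FALSE],
                               n_lv = min(a, fit$n_lv))
    }
  }
  if (criterion == "rmsecv") {
    apply(pred, 2, function(yh) sqrt(mean((yh - y)^2)))
  } else {
    apply(pred, 2, function(yh) sum(sign(yh) != sign(y)))
  }
}

#' Pick the component count from a CV criterion curve
#'
#' Smallest count among the criterion minima (parsimony tie-break).
#' @param criterion_values per-LV criterion from [cross_validate()].
#' @return Integer LV count.
#' @export
select_n_lv <- function(criterion_values) {
  which(criterion_values == min(criterion_values))[1]
}

#' Q residuals and Hotelling T-squared
#'
#' Model-fit diagnostics for latent-variable models, used to screen
#' calibration outliers. The Q residual is the squared reconstruction
#' residual of the centered spectrum outside the loading subspace; the
#' Hotelling T-squared is the Mahalanobis-type distance inside it,
#' scores scaled by the training score variances. Q uses the orthogonal
#' projection onto the loading subspace; T-squared uses the model's own
#' (weights-based) scores.
#'
#' @param model a [fit_pls()] model.
#' @param X matrix of spectra (training columns).
#' @return Numeric vector, one value per row of `X`.
#' @export
q_residuals <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xc <- sweep(as.matrix(X), 2, model$x_mean)
  E <- Xc - (Xc %*% model$P) %*% solve(crossprod(model$P), t(model$P))
  rowSums(E^2)
}

#' @rdname q_residuals
#' @export
hotelling_t2 <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Xc <- sweep(as.matrix(X), 2, model$x_mean)
  R <- model$W %*% solve(crossprod(model$P, model$W))
  Tn <- Xc %*% R
  rowSums(sweep(Tn^2, 2, model$score_variances, `/`))
}

#' Confidence limits for Q and T-squared
#'
#' Q limit by the Jackson-Mudholkar approximation from the eigenvalues
#' of the training residual covariance; T-squared limit from the
#' F-distribution scaling `A (n - 1) / (n - A) F(conf; A, n - A)`.
#'
#' @param model a [fit_pls()] model.
#' @param X_train the training matrix the model was fitted on.
#' @param confidence confidence level in (0, 1), default 0.95.
#' @return A `diagnostic_limits` list with `q_limit`, `t2_limit`,
#'   `confidence`.
#' @export
diagnostic_limits <- function(model, X_train, confidence = 0.95) {
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)")
  }
  n <- nrow(X_train); A <- model$n_lv
  Xc <- sweep(as.matrix(X_train), 2, model$x_mean)
  E <- Xc - (Xc %*% model$P) %*% solve(crossprod(model$P), t(model$P))
  ev <- eigen(crossprod(E) / (n - 1), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  q_limit <- if (!length(ev)) 0 else {
    th1 <- sum(ev); th2 <- sum(ev^2); th3 <- sum(ev^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (h0 < 1e-3) h0 <- 1e-3
    ca <- stats::qnorm(confidence)
    th1 * (ca * sqrt(2 * th2 * h0^2) / th1 +
             1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  t2_limit <- A * (n - 1) / (n - A) * stats::qf(confidence, A, n - A)
  structure(list(q_limit = q_limit, t2_limit = t2_limit,
                 confidence = confidence),
            class = "diagnostic_limits")
}

#' Prediction-error summaries
#'
#' Root-mean-squared error of prediction and coefficient of
#' determination for a held-out set.
#' @param y_true,y_pred numeric vectors of equal length.
#' @return Scalar.
#' @export
rmsep <- function(y_true, y_pred) sqrt(mean((y_true - y_pred)^2))

#' @rdname rmsep
#' @export
r_squared <- function(y_true, y_pred) {
  1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
}
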