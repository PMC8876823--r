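# Partial least squares (PLS1, NIPALS) and cross-validated RMSECV — the
# shared machinery the wavelength selectors rank channels with. The
# response is the adulteration degree: 0/1 for the 2-class task, the class
# label 0..5 for the 6-class task.

#' Specify a cross-validation scheme
#'
#' @param scheme `"k-fold"` or `"leave-one-out"`.
#' @param k number of folds when k-fold (default 5).
#' @param shuffle_seed integer seed for the fold shuffle; leave-one-out is
#'   a fixed assignment (fold i = sample i) and ignores it.
#' @param folds optional explicit integer fold assignment overriding both.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(scheme = c("k-fold", "leave-one-out"), k = 5,
                    shuffle_seed = 0, folds = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "k-fold" && (!is_count(k) || k < 2))
    stop_fluortea("k must be an integer >= 2", "configuration_error")
  structure(list(scheme = scheme, k = as.integer(k),
                 shuffle_seed = as.integer(shuffle_seed), folds = folds),
            class = "cv_spec")
}

cv_fold_assignment <- function(cv, n) {
  if (!is.null(cv$folds)) {
    if (length(cv$folds) != n)
      stop_fluortea("explicit folds length must equal n", "configuration_error")
    return(as.integer(cv$folds))
  }
  if (cv$scheme == "leave-one-out") return(seq_len(n))
  if (cv$k > n)
    stop_fluortea("k exceeds sample count", "configuration_error")
  with_local_seed(cv$shuffle_seed,
                  sample(rep_len(seq_len(cv$k), n)))
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Columns are mean-centred and, by default, scaled to unit variance
#' inside the fit, which puts coefficient magnitudes on a comparable
#' footing — the property the coefficient-ranking selectors rely on.
#' Zero-variance columns are tolerated (scale clamped to 1; they receive
#' zero weight). Component extraction stops early if the residual
#' covariance vanishes, so the effective number of components may be
#' smaller than requested on degenerate designs.
#'
#' @param X numeric matrix, samples x channels.
#' @param y numeric response vector.
#' @param n_components requested latent variables,
#'   `1 <= n_components <= min(n - 1, p)`.
#' @param scale logical; unit-variance column scaling (default `TRUE`).
#' @return An object of class `pls_model` with `coefficients_b` (on the
#'   original predictor scale), `intercept`, `x_means`, `x_scales`,
#'   `y_mean`, `n_components` (requested) and `n_components_used`.
#' @export
fit_pls <- function(X, y, n_components, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (!is_count(n_components) || n_components < 1 ||
      n_components > min(n - 1, p))
    stop_fluortea("n_components must lie in 1..min(n-1, p)", "configuration_error")
  xm <- colMeans(X)
  xs <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  xs[!is.finite(xs) | xs < 1e-12] <- 1
  Xc <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y)
  yc <- y - ym
  W <- P <- matrix(0, p, n_components)
  Q <- numeric(n_components)
  used <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- Xc %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    pk <- crossprod(Xc, t_sc) / tt
    qk <- sum(t_sc * yc) / tt
    Xc <- Xc - t_sc %*% t(pk)
    yc <- yc - qk * t_sc
    W[, a] <- w; P[, a] <- pk; Q[a] <- qk
    used <- a
  }
  if (used == 0L) {
    b_std <- numeric(p)
  } else {
    Wu <- W[, seq_len(used), drop = FALSE]
    Pu <- P[, seq_len(used), drop = FALSE]
    b_std <- as.numeric(Wu %*% solve(crossprod(Pu, Wu), Q[seq_len(used)]))
  }
  b <- b_std / xs
  structure(list(n_components = as.integer(n_components),
                 n_components_used = used,
                 coefficients_b = b,
                 intercept = ym - sum(b * xm),
                 x_means = xm, x_scales = xs, y_mean = ym,
                 scaled = scale),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix with the same channel count the model was fit on.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(newdata %*% object$coefficients_b + object$intercept)
}

#' Cross-validated root-mean-square error of a PLS model
#'
#' RMSECV = sqrt(mean over all held-out samples of (y - yhat)^2), the
#' model-quality score every wavelength selector minimizes. Deterministic
#' given the fold shuffle seed; the fold shuffle runs in a local RNG scope
#' and leaves the caller's stream untouched.
#'
#' @param X numeric matrix.
#' @param y numeric response.
#' @param n_components latent variables per fold fit.
#' @param cv a `cv_spec`.
#' @param scale passed to [fit_pls()].
#' @return Scalar RMSECV.
#' @export
rmsecv <- function(X, y, n_components, cv = cv_spec(), scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- cv_fold_assignment(cv, n)
  press <- 0
  for (f in unique(folds)) {
    hold <- folds == f
    if (sum(!hold) < n_components + 1)
      stop_fluortea("a fold has fewer than n_components + 1 training samples",
                    "configuration_error")
    fit <- fit_pls(X[!hold, , drop = FALSE], y[!hold], n_components, scale = scale)
    press <- press + sum((y[hold] - predict(fit, X[hold, , drop = FALSE]))^2)
  }
  sqrt(press / n)
}

#' Choose the number of PLS components by parsimony
#'
#' Scans 1..`max_components` and returns the smallest count whose RMSECV
#' lies within 2 % of the global minimum — the usual "don't pay for
#' components that don't earn their keep" rule.
#'
#' @param X numeric matrix.
#' @param y numeric response.
#' @param max_components upper bound (clamped to `min(n - 1, p)` and to
#'   what the smallest training fold supports).
#' @param cv a `cv_spec`.
#' @param scale passed to [fit_pls()].
#' @return Integer component count.
#' @export
choose_components <- function(X, y, max_components = 10, cv = cv_spec(),
                              scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- cv_fold_assignment(cv, n)
  min_train <- min(tabulate(folds, nbins = max(folds)) |>
                     (\(cnt) n - cnt[cnt > 0])())
  max_c <- min(max_components, n - 1, ncol(X), min_train - 1)
  if (max_c < 1)
    stop_fluortea("no admissible component count", "configuration_error")
  errs <- vapply(seq_len(max_c), function(a) rmsecv(X, y, a, cv, scale = scale),
                 numeric(1))
  which(errs <= min(errs) * 1.02)[1]
}
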