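# The four characteristic-wavelength selectors. Each maps a calibration
# matrix X (samples x channels) and response y to a selection_result of
# channel indices plus per-method diagnostics. All are deterministic given
# rng_seed; ties anywhere break toward the lowest channel index.

#' Construct a selection result
#'
#' @param method one of `"SPA"`, `"CARS"`, `"RF"`, `"UVE"`.
#' @param selected integer channel indices (1-based), sorted and unique.
#' @param p total channel count.
#' @param diagnostics method-specific list (RMSECV traces, selection
#'   probabilities, reliability scores, ...).
#' @param rng_seed integer seed the run used.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method, selected, p, diagnostics = list(),
                             rng_seed = NA_integer_) {
  method <- match.arg(method, c("SPA", "CARS", "RF", "UVE"))
  selected <- as.integer(selected)
  if (length(selected) < 1 || anyDuplicated(selected) ||
      is.unsorted(selected) || min(selected) < 1 || max(selected) > p)
    stop_fluortea("selected must be sorted unique indices in 1..p",
                  "validation_error")
  structure(list(method = method, selected = selected,
                 n_selected = length(selected), p = as.integer(p),
                 diagnostics = diagnostics, rng_seed = rng_seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d of %d channels\n",
              x$method, x$n_selected, x$p))
  invisible(x)
}

# Cross-validated RMSE of ordinary multiple linear regression on a channel
# subset — the evaluation model of the successive projections algorithm.
mlr_rmsecv <- function(X, y, folds) {
  press <- 0
  for (f in unique(folds)) {
    hold <- folds == f
    Z <- cbind(1, X[!hold, , drop = FALSE])
    fit <- stats::.lm.fit(Z, y[!hold])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- cbind(1, X[hold, , drop = FALSE]) %*% beta
    press <- press + sum((y[hold] - pred)^2)
  }
  sqrt(press / length(y))
}

#' Successive projections algorithm
#'
#' Forward selection that minimizes collinearity: starting from each
#' candidate column, the chain repeatedly projects all unselected columns
#' onto the orthogonal complement of the span of the selected ones and
#' admits the column of maximal residual norm. Every chain prefix
#' (length 1..`max_k`) from every start is then scored by the RMSECV of a
#' multiple-linear-regression model, and the best-scoring prefix wins
#' (ties: fewer channels, then lower start index). Deterministic.
#'
#' @param X numeric calibration matrix.
#' @param y numeric response.
#' @param max_k maximal chain length, `1 <= max_k <= min(n - 1, p)`.
#' @param cv a `cv_spec` for the prefix evaluation (default 5-fold).
#' @return A `selection_result` with per-start prefix RMSECVs in
#'   `diagnostics$rmse` and the winning start/length.
#' @export
spa_select <- function(X, y, max_k, cv = cv_spec()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (!is_count(max_k) || max_k < 1 || max_k > min(n - 1, p))
    stop_fluortea("max_k must lie in 1..min(n-1, p)", "configuration_error")
  folds <- cv_fold_assignment(cv, n)
  tol <- max(colSums(X^2)) * 1e-12
  chains <- vector("list", p)
  for (s in seq_len(p)) {
    R <- X
    chain <- s
    u <- R[, s] / sqrt(sum(R[, s]^2))
    for (step in seq_len(max_k - 1)) {
      R <- R - u %*% crossprod(u, R)   # deflate all columns by the new basis vector
      norms <- colSums(R^2)
      norms[chain] <- -Inf
      norms[norms < tol] <- -Inf       # exactly collinear twins never enter
      if (all(!is.finite(norms))) break
      nxt <- which.max(norms)          # which.max takes the lowest index on ties
      chain <- c(chain, nxt)
      u <- R[, nxt] / sqrt(sum(R[, nxt]^2))
    }
    chains[[s]] <- chain
  }
  rmse <- matrix(NA_real_, p, max_k)
  for (s in seq_len(p))
    for (k in seq_along(chains[[s]]))
      rmse[s, k] <- mlr_rmsecv(X[, chains[[s]][1:k], drop = FALSE], y, folds)
  best <- which(rmse == min(rmse, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, "col"], best[, "row"]), , drop = FALSE][1, ]
  sel <- sort(chains[[best["row"]]][1:best["col"]])
  selection_result("SPA", sel, p,
                   diagnostics = list(rmse = rmse, chains = chains,
                                      best_start = unname(best["row"]),
                                      best_length = unname(best["col"])))
}

#' Exponentially decreasing retention ratio (CARS schedule)
#'
#' `r_i = a * exp(-k * i)` with `a = (p/2)^(1/(N-1))` and
#' `k = log(p/2)/(N-1)`, fixed by the boundary conditions `r_1 = 1` (all
#' channels retained at the first run) and `r_N = 2/p` (two channels at
#' the last).
#'
#' @param i run index, `1 <= i <= N`.
#' @param N total Monte Carlo runs.
#' @param p channel count, `>= 3`.
#' @return Scalar retention ratio.
#' @export
edf_ratio <- function(i, N, p) {
  if (any(i < 1 | i > N) || p < 3)
    stop_fluortea("need 1 <= i <= N and p >= 3", "configuration_error")
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  a * exp(-k * i)
}

#' Configure competitive adaptive reweighted sampling
#'
#' @param n_runs Monte Carlo runs N (default 50, the canonical published
#'   default).
#' @param sample_ratio fraction of calibration samples drawn per run
#'   (default 0.8).
#' @param cv a `cv_spec` scoring each run's surviving subset.
#' @param n_components latent variables; `NULL` chooses once on the full
#'   data by [choose_components()].
#' @return An object of class `cars_config`.
#' @export
cars_config <- function(n_runs = 50, sample_ratio = 0.8, cv = cv_spec(),
                        n_components = NULL) {
  if (!is_count(n_runs) || n_runs < 2)
    stop_fluortea("n_runs must be an integer >= 2", "configuration_error")
  if (sample_ratio <= 0 || sample_ratio > 1)
    stop_fluortea("sample_ratio must lie in (0, 1]", "configuration_error")
  structure(list(n_runs = as.integer(n_runs), sample_ratio = sample_ratio,
                 cv = cv, n_components = n_components),
            class = "cars_config")
}

#' Competitive adaptive reweighted sampling
#'
#' "Survival of the fittest" over channels: each of N runs fits a PLS
#' model on a random 80 % of the calibration samples, performs the
#' enforced reduction — keeping the `round(p * r_i)` channels of largest
#' absolute regression coefficient, where `r_i` is the exponentially
#' decreasing schedule of [edf_ratio()] (floored at 2 channels) — then the
#' adaptive reweighted draw (coefficient-weighted sampling without
#' replacement, count-preserving), and records the RMSECV of the surviving
#' subset on the full calibration set. The subset with minimal RMSECV over
#' all runs wins (ties: earliest run).
#'
#' @param X numeric calibration matrix with `p >= 3` channels.
#' @param y numeric response.
#' @param config a `cars_config`.
#' @param rng_seed integer seed; fixing it fixes the whole trajectory.
#' @return A `selection_result`; `diagnostics` carries the per-run
#'   retained-count and RMSECV traces and the winning run index.
#' @export
cars_select <- function(X, y, config = cars_config(), rng_seed = 0) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 3) stop_fluortea("CARS needs p >= 3 channels", "configuration_error")
  N <- config$n_runs
  ncomp <- config$n_components %||%
    choose_components(X, y, cv = config$cv)
  n_draw <- max(2, round(config$sample_ratio * n))
  retained_trace <- integer(N)
  rmsecv_trace <- numeric(N)
  subsets <- vector("list", N)
  with_local_seed(rng_seed, {
    retained <- seq_len(p)
    for (i in seq_len(N)) {
      rows <- sample.int(n, n_draw)
      a_use <- min(ncomp, length(retained), n_draw - 1)
      fit <- fit_pls(X[rows, retained, drop = FALSE], y[rows], a_use)
      co <- abs(fit$coefficients_b)
      m_i <- max(2, round(p * edf_ratio(i, N, p)))
      m_i <- min(m_i, length(retained))
      ord <- order(-co, retained)            # ties -> lowest channel index
      keep <- retained[ord[seq_len(m_i)]]
      w <- co[ord[seq_len(m_i)]]
      if (all(w <= 0)) w <- rep(1, m_i)
      # adaptive reweighted draw: without replacement and count-preserving,
      # so the retained set is unchanged as a set (the draw consumes RNG)
      keep <- keep[sample.int(m_i, m_i, prob = pmax(w, .Machine$double.xmin))]
      retained <- sort(keep)
      retained_trace[i] <- length(retained)
      rmsecv_trace[i] <- rmsecv(X[, retained, drop = FALSE], y,
                                min(ncomp, length(retained)), config$cv)
      subsets[[i]] <- retained
    }
  })
  win <- which.min(rmsecv_trace)
  selection_result("CARS", subsets[[win]], p,
                   diagnostics = list(retained_trace = retained_trace,
                                      rmsecv_trace = rmsecv_trace,
                                      winning_run = win,
                                      n_components = ncomp),
                   rng_seed = rng_seed)
}

#' Random frog wavelength selection
#'
#' A random walk over channel subsets. From the current subset V, a
#' candidate V* of size `q* ~ round(N(|V|, 0.3 |V|))` (clamped to
#' `[1, p]`) is proposed by adding uniformly random channels or dropping
#' the weakest-coefficient ones; V* is accepted when its RMSECV does not
#' exceed V's, and otherwise with probability
#' `0.1 * RMSECV(V) / RMSECV(V*)`. A channel's selection probability is
#' its occupancy fraction over the N iterations (the subset standing at
#' the start of each iteration is counted, so the initial subset
#' contributes). Channels with probability `>= threshold` are selected;
#' if fewer than 2 pass, the top 2 by probability are taken.
#'
#' @param X numeric calibration matrix.
#' @param y numeric response.
#' @param n_iterations iterations N.
#' @param q_init initial subset size, drawn uniformly at random.
#' @param threshold selection-probability cut-off in `[0, 1]`.
#' @param cv a `cv_spec`.
#' @param n_components latent variables; `NULL` chooses once up front.
#' @param rng_seed integer seed.
#' @return A `selection_result`; `diagnostics$probability` holds the
#'   per-channel selection probabilities.
#' @export
random_frog_select <- function(X, y, n_iterations = 500, q_init = 10,
                               threshold = 0.25, cv = cv_spec(),
                               n_components = NULL, rng_seed = 0) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (!is_count(q_init) || q_init < 1 || q_init > p)
    stop_fluortea("q_init must lie in 1..p", "configuration_error")
  if (!is_count(n_iterations) || n_iterations < 1)
    stop_fluortea("n_iterations must be >= 1", "configuration_error")
  ncomp <- n_components %||% choose_components(X, y, cv = cv)
  score <- function(V) rmsecv(X[, V, drop = FALSE], y,
                              min(ncomp, length(V)), cv)
  counts <- integer(p)
  accepted <- 0L
  with_local_seed(rng_seed, {
    V <- sort(sample.int(p, q_init))
    rmse_V <- score(V)
    for (i in seq_len(n_iterations)) {
      counts[V] <- counts[V] + 1L
      q_star <- round(stats::rnorm(1, length(V), 0.3 * length(V)))
      q_star <- min(max(q_star, 1), p)
      if (q_star > length(V)) {
        pool <- setdiff(seq_len(p), V)
        V_star <- sort(c(V, sample(pool, q_star - length(V))))
      } else if (q_star < length(V)) {
        a_use <- min(ncomp, length(V), n - 1)
        fit <- fit_pls(X[, V, drop = FALSE], y, a_use)
        ord <- order(-abs(fit$coefficients_b), V)  # keep strongest; ties -> low index
        V_star <- sort(V[ord[seq_len(q_star)]])
      } else V_star <- V
      rmse_star <- score(V_star)
      accept <- rmse_star <= rmse_V ||
        stats::runif(1) < 0.1 * rmse_V / rmse_star
      if (accept) {
        V <- V_star
        rmse_V <- rmse_star
        accepted <- accepted + 1L
      }
    }
  })
  prob <- counts / n_iterations
  sel <- which(prob >= threshold)
  if (length(sel) < 2) {
    ord <- order(-prob, seq_len(p))
    sel <- sort(ord[1:2])
  }
  selection_result("RF", sel, p,
                   diagnostics = list(probability = prob,
                                      n_accepted = accepted,
                                      n_components = ncomp,
                                      threshold = threshold),
                   rng_seed = rng_seed)
}

#' Uninformative variable elimination
#'
#' Appends p artificial noise channels (uniform on `[0, 1]`, scaled to
#' 1e-10 of the data's magnitude so they cannot influence predictions),
#' fits one PLS model per leave-one-out fold on the augmented matrix
#' without column autoscaling (which would re-inflate the noise), and
#' scores every column by its reliability `c_j` = mean over folds of
#' `b_j` / sd over folds of `b_j`. Real channels survive when `|c_j|`
#' exceeds `noise_multiplier` times the largest `|c|` among the noise
#' channels — a threshold calibrated by variables known to be
#' uninformative by construction.
#'
#' @param X numeric calibration matrix, `n >= 3`.
#' @param y numeric response.
#' @param noise_multiplier threshold multiplier (default 1).
#' @param cv a `cv_spec`; the classical formulation is leave-one-out,
#'   the default here.
#' @param n_components latent variables; `NULL` chooses once up front
#'   (5-fold, for speed) on the real channels.
#' @param rng_seed integer seed for the noise matrix.
#' @return A `selection_result`; `diagnostics` carries real and noise
#'   reliabilities and the threshold. A coefficient that is constant
#'   across folds gets reliability `+Inf` with a warning; an empty
#'   selection degrades, with a warning, to the single most reliable
#'   channel.
#' @export
uve_select <- function(X, y, noise_multiplier = 1,
                       cv = cv_spec("leave-one-out"), n_components = NULL,
                       rng_seed = 0) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop_fluortea("UVE needs n >= 3", "configuration_error")
  ncomp <- n_components %||%
    choose_components(X, y, cv = cv_spec("k-fold", 5, shuffle_seed = rng_seed),
                      scale = FALSE)
  noise <- with_local_seed(rng_seed, matrix(stats::runif(n * p), n, p)) *
    (1e-10 * max(abs(X)))
  Xa <- cbind(X, noise)
  folds <- cv_fold_assignment(cv, n)
  B <- matrix(0, length(unique(folds)), 2 * p)
  r <- 0L
  for (f in unique(folds)) {
    r <- r + 1L
    keep <- folds != f
    a_use <- min(ncomp, sum(keep) - 1)
    B[r, ] <- fit_pls(Xa[keep, , drop = FALSE], y[keep], a_use,
                      scale = FALSE)$coefficients_b
  }
  mu <- colMeans(B)
  sdev <- apply(B, 2, stats::sd)
  cj <- mu / sdev
  frozen <- sdev == 0
  if (any(frozen)) {
    warning(sum(frozen), " coefficient(s) constant across folds; reliability set to +Inf")
    cj[frozen] <- ifelse(mu[frozen] == 0, 0, Inf * sign(mu[frozen]))
  }
  c_real <- cj[seq_len(p)]
  c_noise <- cj[p + seq_len(p)]
  thr <- noise_multiplier * max(abs(c_noise))
  sel <- which(abs(c_real) > thr)
  if (length(sel) == 0) {
    warning("UVE threshold eliminated every channel; falling back to the single most reliable one")
    sel <- which.max(abs(c_real))
  }
  selection_result("UVE", sel, p,
                   diagnostics = list(reliability = c_real,
                                      noise_reliability = c_noise,
                                      threshold = thr,
                                      n_components = ncomp),
                   rng_seed = rng_seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
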