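# Independent oracles. Each recomputes a quantity by the most literal
# route available (explicit loops, from-scratch refits), never by calling
# the implementation path it checks.

# ROI mean by a flat loop over pixels.
oracle_roi_mean <- function(cube, roi) {
  rows <- (roi$row_start + 1):roi$row_stop
  cols <- (roi$col_start + 1):roi$col_stop
  p <- dim(cube$data)[3]
  out <- numeric(p)
  for (c in seq_len(p)) {
    acc <- 0
    for (i in rows) for (j in cols) acc <- acc + cube$data[i, j, c]
    out[c] <- acc / (length(rows) * length(cols))
  }
  out
}

# Savitzky-Golay value at one channel by an explicit per-window
# least-squares polynomial fit.
oracle_sg_point <- function(x, i, window, polyorder) {
  h <- (window - 1) / 2
  n <- length(x)
  if (i <= h) {
    idx <- 1:window; at <- i
  } else if (i > n - h) {
    idx <- (n - window + 1):n; at <- i - (n - window)
  } else {
    idx <- (i - h):(i + h); at <- h + 1
  }
  Z <- outer(seq_len(window), 0:polyorder, `^`)
  beta <- qr.solve(Z, x[idx])
  sum(Z[at, ] * beta)
}

# SPA chain from one start by explicit Gram-Schmidt against the selected
# set, recomputed from scratch at every step.
oracle_spa_chain <- function(X, start, max_k) {
  p <- ncol(X)
  chain <- start
  tol <- max(colSums(X^2)) * 1e-12
  while (length(chain) < max_k) {
    Q <- qr.Q(qr(X[, chain, drop = FALSE]))
    norms <- rep(-Inf, p)
    for (j in setdiff(seq_len(p), chain)) {
      r <- X[, j]
      for (k in seq_len(ncol(Q))) r <- r - sum(r * Q[, k]) * Q[, k]
      n2 <- sum(r^2)
      if (n2 >= tol) norms[j] <- n2
    }
    if (all(!is.finite(norms))) break
    chain <- c(chain, which.max(norms))
  }
  chain
}

# Cross-validated MLR RMSE with stats::lm, fold by fold.
oracle_mlr_rmsecv <- function(X, y, folds) {
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  press <- 0
  for (f in unique(folds)) {
    hold <- folds == f
    df_tr <- data.frame(y = y[!hold], X[!hold, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df_tr)
    pred <- stats::predict(fit,
                           newdata = as.data.frame(X[hold, , drop = FALSE]))
    press <- press + sum((y[hold] - pred)^2)
  }
  sqrt(press / length(y))
}

# Full SPA selection by the oracle chain + oracle evaluation.
oracle_spa_select <- function(X, y, max_k, folds) {
  p <- ncol(X)
  best <- NULL
  for (s in seq_len(p)) {
    chain <- oracle_spa_chain(X, s, max_k)
    for (k in seq_along(chain)) {
      r <- oracle_mlr_rmsecv(X[, chain[1:k], drop = FALSE], y, folds)
      cand <- list(rmse = r, sel = sort(chain[1:k]), k = k, s = s)
      if (is.null(best) || r < best$rmse ||
          (r == best$rmse && (k < best$k || (k == best$k && s < best$s))))
        best <- cand
    }
  }
  best
}
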