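# Discriminant modelling and evaluation: stratified 2:1 split, poly-kernel
# SVM, confusion-matrix metrics for the 2-class (pure vs adulterated) and
# 6-class (adulteration degree) tasks, and the PCA diagnostic.

#' Specify a calibration/prediction split
#'
#' @param calibration_fraction fraction of each class assigned to the
#'   calibration partition (default 2/3, the study's 2:1 split).
#' @param stratified logical (default `TRUE`).
#' @param seed integer shuffle seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(calibration_fraction = 2 / 3, stratified = TRUE,
                       seed = 0) {
  if (calibration_fraction <= 0 || calibration_fraction >= 1)
    stop_fluortea("calibration_fraction must lie in (0, 1)", "configuration_error")
  structure(list(calibration_fraction = calibration_fraction,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_spec")
}

#' Specify the SVM classifier
#'
#' The discriminant model is a support vector machine with the polynomial
#' kernel `(gamma * x.z + coef0)^degree` throughout; hyperparameters
#' default to the standard poly-SVM settings (degree 3, coef0 1, C = 1,
#' gamma = 1 / (n_channels * var(training features))), with one-vs-one
#' multiclass coupling.
#'
#' @param degree polynomial degree `>= 1`.
#' @param coef0 kernel offset.
#' @param regularization_c soft-margin cost `> 0`.
#' @param gamma kernel scale, or `NULL` for the variance-based default.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(degree = 3, coef0 = 1, regularization_c = 1,
                            gamma = NULL) {
  if (!is_count(degree) || degree < 1)
    stop_fluortea("degree must be an integer >= 1", "configuration_error")
  if (regularization_c <= 0)
    stop_fluortea("regularization_c must be positive", "configuration_error")
  structure(list(kernel = "poly", degree = as.integer(degree), coef0 = coef0,
                 regularization_c = regularization_c, gamma = gamma,
                 multiclass_strategy = "one-vs-one"),
            class = "classifier_spec")
}

#' Stratified calibration/prediction split
#'
#' Splits each class as close to the calibration fraction as integer
#' rounding allows (48 samples at 2/3 give exactly 32/16); partitions are
#' disjoint, exhaustive, and reproducible from the seed.
#'
#' @param set a `spectrum_set`; every class present must have >= 2 samples.
#' @param spec a `split_spec`.
#' @return List with `spectrum_set`s `$calibration` and `$prediction` and
#'   the index vectors `$calibration_idx`, `$prediction_idx`.
#' @export
stratified_split <- function(set, spec = split_spec()) {
  validate_spectrum_set(set)
  classes <- if (spec$stratified) set$labels else rep(0L, length(set$labels))
  cal_idx <- integer(0)
  for (k in sort(unique(classes))) {
    idx <- which(classes == k)
    if (length(idx) < 2)
      stop_fluortea(sprintf("class %d has fewer than 2 samples", k),
                    "stratification_error")
    n_cal <- round(length(idx) * spec$calibration_fraction)
    n_cal <- min(max(n_cal, 1L), length(idx) - 1L)
    picked <- with_local_seed(spec$seed + k, sample(idx, n_cal))
    cal_idx <- c(cal_idx, picked)
  }
  cal_idx <- sort(cal_idx)
  pred_idx <- setdiff(seq_along(set$labels), cal_idx)
  list(calibration = subset_samples(set, cal_idx),
       prediction = subset_samples(set, pred_idx),
       calibration_idx = cal_idx, prediction_idx = pred_idx)
}

class_response <- function(labels, mode) {
  if (mode == "two-class")
    factor(ifelse(labels == 0L, "pure", "adulterated"),
           levels = c("pure", "adulterated"))
  else
    factor(labels, levels = 0:5)
}

#' Train a poly-kernel SVM on selected channels
#'
#' Restricts the spectra to the selected channels, standardizes features
#' with calibration statistics (poly kernels are scale-sensitive), and
#' fits the SVM. In two-class mode the labels are binarized first
#' (label 0 = pure = positive class).
#'
#' @param train a calibration `spectrum_set`.
#' @param channels integer channel indices (1-based) to use.
#' @param spec a `classifier_spec`.
#' @param mode `"two-class"` or `"six-class"`.
#' @return A `svm_handle` carrying the fitted model, the channel set, the
#'   standardization statistics and the fit time.
#' @export
train_svm <- function(train, channels, spec = classifier_spec(),
                      mode = c("two-class", "six-class")) {
  mode <- match.arg(mode)
  validate_spectrum_set(train)
  if (length(channels) < 1)
    stop_fluortea("channel set must be non-empty", "configuration_error")
  y <- droplevels(class_response(train$labels, mode))
  if (nlevels(y) < 2)
    stop_fluortea("training set holds a single class", "training_error")
  X <- train$intensities[, channels, drop = FALSE]
  centre <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, centre), 2, scale_, "/")
  gamma <- spec$gamma %||% (1 / (ncol(Xs) * max(stats::var(as.vector(Xs)), 1e-12)))
  t0 <- proc.time()[["elapsed"]]
  fit <- e1071::svm(Xs, y, kernel = "polynomial", degree = spec$degree,
                    coef0 = spec$coef0, cost = spec$regularization_c,
                    gamma = gamma, scale = FALSE)
  fit_seconds <- proc.time()[["elapsed"]] - t0
  structure(list(fit = fit, channels = as.integer(channels), mode = mode,
                 centre = centre, scale = scale_, spec = spec,
                 fit_seconds = fit_seconds),
            class = "svm_handle")
}

#' Compute confusion-matrix evaluation metrics
#'
#' In two-class mode (positive = pure, row/column 1): sensitivity =
#' TP / (TP + FN), specificity = TN / (TN + FP), overall accuracy =
#' (TP + TN) / (TP + TN + FP + FN). In six-class mode: class accuracy =
#' correct assignments of a class over that class's tested total, and
#' overall accuracy = trace / total.
#'
#' @param confusion square integer matrix, rows = true class,
#'   columns = predicted class.
#' @param mode `"two-class"` or `"six-class"`.
#' @return Named list of counts and rates.
#' @export
confusion_metrics <- function(confusion, mode = c("two-class", "six-class")) {
  mode <- match.arg(mode)
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  out <- list(confusion = confusion,
              overall_accuracy = sum(diag(confusion)) / total)
  if (mode == "two-class") {
    stopifnot(nrow(confusion) == 2)
    out$TP <- confusion[1, 1]; out$FN <- confusion[1, 2]
    out$FP <- confusion[2, 1]; out$TN <- confusion[2, 2]
    out$sensitivity <- out$TP / (out$TP + out$FN)
    out$specificity <- out$TN / (out$TN + out$FP)
  } else {
    out$class_accuracy <- diag(confusion) / rowSums(confusion)
  }
  out
}

#' Evaluate a trained model on a partition
#'
#' @param model a `svm_handle` from [train_svm()].
#' @param test a non-empty `spectrum_set`.
#' @param partition label recorded in the report (`"calibration"` or
#'   `"prediction"`).
#' @return An `evaluation_report`: confusion matrix, the metric set of
#'   [confusion_metrics()] for the model's mode, and `elapsed_seconds`
#'   covering model fit plus this prediction pass (the preprocessing and
#'   selection stages are timed separately by the grid runner).
#' @export
evaluate_model <- function(model, test,
                           partition = c("prediction", "calibration")) {
  partition <- match.arg(partition)
  stopifnot(inherits(model, "svm_handle"))
  validate_spectrum_set(test)
  if (nrow(test$intensities) == 0)
    stop_fluortea("test set is empty", "validation_error")
  y <- class_response(test$labels, model$mode)
  if (any(!unique(as.character(y)) %in% model$fit$levels))
    warning("test contains classes absent from training; scored as misclassifications")
  X <- sweep(sweep(test$intensities[, model$channels, drop = FALSE],
                   2, model$centre), 2, model$scale, "/")
  t0 <- proc.time()[["elapsed"]]
  pred <- predict(model$fit, X)
  elapsed <- model$fit_seconds + (proc.time()[["elapsed"]] - t0)
  lv <- levels(y)
  confusion <- table(factor(y, levels = lv), factor(pred, levels = lv))
  confusion <- matrix(as.integer(confusion), nrow(confusion),
                      dimnames = dimnames(confusion))
  m <- confusion_metrics(confusion, model$mode)
  structure(c(m, list(mode = model$mode, partition = partition,
                      n = nrow(X), elapsed_seconds = elapsed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, %s partition, n = %d\n",
              x$mode, x$partition, x$n))
  cat(sprintf("  overall accuracy %.2f%%", 100 * x$overall_accuracy))
  if (x$mode == "two-class")
    cat(sprintf(", sensitivity %.2f%%, specificity %.2f%%",
                100 * x$sensitivity, 100 * x$specificity))
  cat("\n")
  invisible(x)
}

#' Principal component diagnostic
#'
#' Mean-centred PCA of the spectra; returns the top-3 score matrix and
#' explained-variance percentages — the standard look at whether the
#' classes occupy distinguishable regions of spectral space before any
#' supervised modelling.
#'
#' @param set a `spectrum_set` with `n >= 4`.
#' @return List with `scores` (n x 3) and `explained_variance_pct`
#'   (length 3, non-increasing).
#' @export
pca_diagnostic <- function(set) {
  validate_spectrum_set(set)
  if (nrow(set$intensities) < 4)
    stop_fluortea("PCA diagnostic needs n >= 4", "configuration_error")
  pc <- stats::prcomp(set$intensities, center = TRUE, scale. = FALSE)
  k <- min(3, ncol(pc$x))
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance_pct = pct[seq_len(k)])
}
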