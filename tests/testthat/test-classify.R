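# Split discipline, SVM behaviour on constructed geometries, the
# confusion-matrix metric identities, and the PCA diagnostic.

test_that("the 2:1 stratified split gives 192/96 overall and 32/16 per class", {
  set <- simulate_set(default_config(21))
  parts <- stratified_split(set, split_spec(seed = 3))
  expect_equal(nrow(parts$calibration$intensities), 192)
  expect_equal(nrow(parts$prediction$intensities), 96)
  expect_equal(as.vector(table(parts$calibration$labels)), rep(32, 6))
  expect_equal(as.vector(table(parts$prediction$labels)), rep(16, 6))
  expect_length(intersect(parts$calibration_idx, parts$prediction_idx), 0)
  expect_setequal(c(parts$calibration_idx, parts$prediction_idx), 1:288)
  # reproducible from the seed
  parts2 <- stratified_split(set, split_spec(seed = 3))
  expect_identical(parts$calibration_idx, parts2$calibration_idx)
})

test_that("halving a two-per-class set gives one sample each side", {
  s <- tiny_set(n_per_class = 2)
  parts <- stratified_split(s, split_spec(0.5, seed = 1))
  expect_equal(as.vector(table(parts$calibration$labels)), rep(1, 6))
  expect_equal(as.vector(table(parts$prediction$labels)), rep(1, 6))
  expect_error(stratified_split(tiny_set(n_per_class = 1), split_spec()),
               class = "stratification_error")
})

make_cloud_set <- function(n = 24, sep = 6, seed = 1) {
  # two linearly separable clouds on a 4-channel grid; labels 0 vs 1
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n / 2 * 4, 2), n / 2),
               matrix(rnorm(n / 2 * 4, 2 + sep), n / 2))
    lab <- rep(c(0L, 1L), each = n / 2)
    spectrum_set(wavelength_grid(seq(500, 800, length.out = 4)),
                 abs(X), lab, lab / 10)
  })
}

test_that("a degree-1 poly SVM separates linearly separable clouds", {
  s <- make_cloud_set()
  m <- train_svm(s, 1:4, classifier_spec(degree = 1), "two-class")
  rep <- evaluate_model(m, s, "calibration")
  expect_equal(rep$overall_accuracy, 1)

  m_hard <- train_svm(s, 1:4, classifier_spec(regularization_c = 1e4), "two-class")
  rep_hard <- evaluate_model(m_hard, s, "calibration")
  expect_equal(rep_hard$confusion[1, 2] + rep_hard$confusion[2, 1], 0)
  expect_error(train_svm(subset_samples(s, 1:12), 1:4,
                         classifier_spec(), "two-class"),
               class = "training_error")
})

test_that("calibration accuracy dominates prediction accuracy on average", {
  gap <- vapply(1:10, function(s) {
    set <- simulate_set(default_config(500 + s))
    parts <- stratified_split(set, split_spec(seed = s))
    m <- train_svm(parts$calibration, 1:104, classifier_spec(), "six-class")
    cal <- evaluate_model(m, parts$calibration, "calibration")$overall_accuracy
    prd <- evaluate_model(m, parts$prediction, "prediction")$overall_accuracy
    cal - prd
  }, numeric(1))
  expect_gt(mean(gap), 0)
})

test_that("confusion metrics reproduce the hand-worked counts", {
  m <- confusion_metrics(matrix(c(9, 2, 1, 18), 2), "two-class")
  # rows = truth: TP=9 FN=1 / FP=2 TN=18
  expect_equal(m$TP, 9); expect_equal(m$FN, 1)
  expect_equal(m$FP, 2); expect_equal(m$TN, 18)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$overall_accuracy, 27 / 30)

  perfect <- diag(c(4, 5, 6))
  mm <- confusion_metrics(perfect, "six-class")
  expect_equal(mm$overall_accuracy, 1)
  expect_equal(unname(mm$class_accuracy), rep(1, 3))

  # a 22-sample class with 16 correct scores 72.73 %
  c6 <- diag(rep(10, 6)); c6[5, 5] <- 16; c6[5, 2] <- 6
  mm6 <- confusion_metrics(c6, "six-class")
  expect_equal(round(100 * unname(mm6$class_accuracy[5]), 2), 72.73)
})

test_that("reports are invariant to test-sample order", {
  s <- make_cloud_set(n = 20, sep = 2, seed = 3)
  m <- train_svm(s, 1:4, classifier_spec(), "two-class")
  r1 <- evaluate_model(m, s, "prediction")
  perm <- sample(20)
  r2 <- evaluate_model(m, subset_samples(s, perm), "prediction")
  r1$elapsed_seconds <- r2$elapsed_seconds <- 0
  expect_equal(r1, r2)
})

test_that("pca diagnostic: rank-1 data, ordering, isotropic calibration", {
  set.seed(11)
  u <- rnorm(30); v <- abs(rnorm(8))
  s <- spectrum_set(wavelength_grid(seq(500, 900, length.out = 8)),
                    abs(outer(u, v)), rep(0L, 30), rep(0, 30))
  d <- pca_diagnostic(s)
  expect_equal(d$explained_variance_pct[1], 100)
  expect_equal(d$explained_variance_pct[2:3], c(0, 0), tolerance = 1e-8)

  s2 <- tiny_set(n_per_class = 5, p = 10, seed = 2)
  d2 <- pca_diagnostic(s2)
  expect_true(all(diff(d2$explained_variance_pct) <= 0))
  expect_true(all(d2$explained_variance_pct >= 0 &
                  d2$explained_variance_pct <= 100))

  pcts <- t(vapply(1:20, function(s) {
    X <- withr::with_seed(600 + s, matrix(rnorm(2000 * 10), 2000))
    ss <- spectrum_set(wavelength_grid(seq(500, 900, length.out = 10)),
                       X, rep(0L, 2000), rep(0, 2000), preprocessed = TRUE)
    pca_diagnostic(ss)$explained_variance_pct
  }, numeric(3)))
  expect_true(all(pcts >= 8 & pcts <= 12))
})
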