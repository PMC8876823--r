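# Grid orchestration: every preprocessing x selector x task-mode
# combination, run leakage-free (all fitted statistics from the
# calibration partition only) and reproducibly (per-combination seed
# fan-out from one global seed).

#' Assemble a grid run configuration
#'
#' @param set a raw `spectrum_set` (e.g. from [simulate_set()] or
#'   [read_spectra_table()]).
#' @param preprocess character vector of preprocessing methods out of
#'   `c("RAW", "SNV", "MSC", "SG")`.
#' @param selectors character vector out of
#'   `c("none", "spa", "cars", "rf", "uve")`.
#' @param modes character vector out of `c("two-class", "six-class")`.
#' @param classifier a `classifier_spec`.
#' @param split a `split_spec`; its seed is derived from `global_seed` so
#'   the whole grid shares one 2:1 partition.
#' @param global_seed integer master seed; per-combination selector seeds
#'   are fanned out from it by hashing the combination name.
#' @param selector_settings named list of per-method overrides:
#'   `spa_max_k`, `cars_n_runs`, `rf_iterations`, `rf_q_init`,
#'   `rf_threshold`, `uve_multiplier`, `pls_max_components`, `cv_k`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(set, preprocess = c("RAW", "SNV", "MSC", "SG"),
                       selectors = c("none", "spa", "cars", "rf", "uve"),
                       modes = c("two-class", "six-class"),
                       classifier = classifier_spec(),
                       split = NULL, global_seed = 0,
                       selector_settings = list()) {
  validate_spectrum_set(set)
  preprocess <- match.arg(toupper(preprocess), c("RAW", "SNV", "MSC", "SG"),
                          several.ok = TRUE)
  selectors <- match.arg(tolower(selectors),
                         c("none", "spa", "cars", "rf", "uve"),
                         several.ok = TRUE)
  modes <- match.arg(modes, c("two-class", "six-class"), several.ok = TRUE)
  if (length(preprocess) < 1 || length(selectors) < 1)
    stop_fluortea("need at least one preprocessing and one selector entry",
                  "configuration_error")
  s <- utils::modifyList(grid_settings(), selector_settings)
  split <- split %||% split_spec(seed = derive_seed(global_seed, "split"))
  structure(list(set = set, preprocess = preprocess, selectors = selectors,
                 modes = modes, classifier = classifier, split = split,
                 global_seed = as.integer(global_seed), settings = s),
            class = "run_config")
}

#' Default per-selector grid settings
#'
#' @return Named list of the package defaults: SPA chain bound 25, CARS
#'   50 Monte Carlo runs, random frog 500 iterations from a 10-channel
#'   start with occupancy threshold 0.25, UVE multiplier 1, at most 10
#'   PLS components, 5-fold cross-validation.
#' @export
grid_settings <- function() {
  list(spa_max_k = 25, cars_n_runs = 50, rf_iterations = 500,
       rf_q_init = 10, rf_threshold = 0.25, uve_multiplier = 1,
       pls_max_components = 10, cv_k = 5)
}

select_channels <- function(X, y, selector, settings, seed) {
  cv <- cv_spec("k-fold", settings$cv_k, shuffle_seed = seed)
  switch(selector,
    none = NULL,
    spa = spa_select(X, y, max_k = min(settings$spa_max_k, nrow(X) - 1, ncol(X)),
                     cv = cv),
    cars = cars_select(X, y, cars_config(n_runs = settings$cars_n_runs, cv = cv),
                       rng_seed = seed),
    rf = random_frog_select(X, y, n_iterations = settings$rf_iterations,
                            q_init = min(settings$rf_q_init, ncol(X)),
                            threshold = settings$rf_threshold, cv = cv,
                            rng_seed = seed),
    uve = uve_select(X, y, noise_multiplier = settings$uve_multiplier,
                     rng_seed = seed))
}

#' Run one preprocessing x selector x mode combination
#'
#' The leakage discipline: the MSC reference is the calibration mean; the
#' wavelength selector sees calibration rows only; SVM standardization
#' statistics come from the calibration partition. Nothing fitted ever
#' touches the prediction rows.
#'
#' @param calibration,prediction raw `spectrum_set` partitions.
#' @param pre_method preprocessing method name.
#' @param selector selector name (`"none"` for all channels).
#' @param mode `"two-class"` or `"six-class"`.
#' @param classifier a `classifier_spec`.
#' @param settings selector settings list (see [run_config()]).
#' @param seed integer seed for this combination.
#' @return List with the `selection_result` (or `NULL`), the trained
#'   model, and `evaluation_report`s for both partitions.
#' @export
run_combo <- function(calibration, prediction, pre_method, selector,
                      mode, classifier = classifier_spec(),
                      settings = list(), seed = 0) {
  settings <- utils::modifyList(grid_settings(), settings)
  pspec <- preprocess_spec(pre_method)
  cal_pp <- preprocess(calibration, pspec,
                       msc_reference = colMeans(calibration$intensities))
  pred_pp <- preprocess(prediction, pspec,
                        msc_reference = colMeans(calibration$intensities))
  y_cal <- if (mode == "two-class") as.numeric(calibration$labels != 0L)
           else as.numeric(calibration$labels)
  selection <- select_channels(cal_pp$intensities, y_cal, selector,
                               settings, seed)
  channels <- if (is.null(selection)) seq_len(ncol(cal_pp$intensities))
              else selection$selected
  model <- train_svm(cal_pp, channels, classifier, mode)
  list(selection = selection, channels = channels, model = model,
       reports = list(
         calibration = evaluate_model(model, cal_pp, "calibration"),
         prediction = evaluate_model(model, pred_pp, "prediction")))
}

#' Run the full model grid
#'
#' Splits once (2:1 stratified), then runs every combination of
#' preprocessing, selector and mode, evaluating both partitions. A failing
#' combination is caught, marked `failed` in the report, and does not
#' disturb the rest of the grid. Fully reproducible from `global_seed`.
#'
#' @param config a `run_config`.
#' @return A `grid_report`: a data frame with one row per (preprocess,
#'   selector, mode, partition), carrying `n_selected`, the 2-class rates
#'   or per-class accuracies, and `elapsed_seconds`. The per-combination
#'   `selection_result`s are attached as `attr(, "selections")`.
#' @export
run_grid <- function(config) {
  stopifnot(inherits(config, "run_config"))
  parts <- stratified_split(config$set, config$split)
  rows <- list()
  selections <- list()
  for (pre in config$preprocess) for (sel in config$selectors)
    for (mode in config$modes) {
      tag <- paste(pre, sel, mode, sep = "|")
      seed <- derive_seed(config$global_seed, tag)
      res <- tryCatch(
        run_combo(parts$calibration, parts$prediction, pre, sel, mode,
                  config$classifier, config$settings, seed),
        error = function(e) e)
      if (inherits(res, "error")) {
        message("grid combination ", tag, " failed: ", conditionMessage(res))
        for (part in c("calibration", "prediction"))
          rows[[length(rows) + 1L]] <- grid_row(pre, sel, mode, part,
                                                NULL, NA_integer_, TRUE)
        next
      }
      selections[[tag]] <- res$selection
      for (part in c("calibration", "prediction"))
        rows[[length(rows) + 1L]] <- grid_row(pre, sel, mode, part,
                                              res$reports[[part]],
                                              length(res$channels), FALSE)
    }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "selections") <- selections
  class(report) <- c("grid_report", class(report))
  report
}

grid_row <- function(pre, sel, mode, partition, rep, n_channels, failed) {
  base <- data.frame(preprocess = pre, selector = sel, mode = mode,
                     partition = partition, n_selected = n_channels,
                     sensitivity = NA_real_, specificity = NA_real_,
                     accuracy = NA_real_,
                     acc_class_0 = NA_real_, acc_class_1 = NA_real_,
                     acc_class_2 = NA_real_, acc_class_3 = NA_real_,
                     acc_class_4 = NA_real_, acc_class_5 = NA_real_,
                     elapsed_seconds = NA_real_, failed = failed,
                     stringsAsFactors = FALSE)
  if (!is.null(rep)) {
    base$accuracy <- rep$overall_accuracy
    base$elapsed_seconds <- rep$elapsed_seconds
    if (mode == "two-class") {
      base$sensitivity <- rep$sensitivity
      base$specificity <- rep$specificity
    } else {
      base[paste0("acc_class_", 0:5)] <- as.list(rep$class_accuracy)
    }
  }
  base
}

#' Render a grid report as a publication-style CSV table
#'
#' Two-class style: method, number of channels, sensitivity, specificity,
#' accuracy (and optionally time); six-class style: per-class accuracies
#' for the six adulteration degrees plus the overall accuracy.
#' Percentages are rendered with two decimals (round-half-even).
#'
#' @param report a `grid_report`.
#' @param style `"two-class"` or `"six-class"`.
#' @param path optional output CSV path.
#' @param include_time include the `elapsed_seconds` column (default
#'   `TRUE`); exclude it when byte-identical output across reruns matters.
#' @return The formatted data frame, invisibly if written to `path`.
#' @export
report_table <- function(report, style = c("two-class", "six-class"),
                         path = NULL, include_time = TRUE) {
  style <- match.arg(style)
  rows <- report[report$mode == style, , drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no rows of the requested mode; emitting empty table")
  }
  pct <- function(x) ifelse(is.na(x), "",
                            paste0(formatC(round(100 * x, 2), format = "f",
                                           digits = 2), "%"))
  out <- data.frame(Preprocessing = rows$preprocess, Method = rows$selector,
                    Partition = rows$partition, Number = rows$n_selected,
                    stringsAsFactors = FALSE)
  if (style == "two-class") {
    out$Sensitivity <- pct(rows$sensitivity)
    out$Specificity <- pct(rows$specificity)
    out$Accuracy <- pct(rows$accuracy)
  } else {
    for (k in 0:5)
      out[[paste0("Class", k * 10, "pct")]] <- pct(rows[[paste0("acc_class_", k)]])
    out$OverallAccuracy <- pct(rows$accuracy)
  }
  if (include_time) out$Time <- rows$elapsed_seconds
  out$Failed <- rows$failed
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
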