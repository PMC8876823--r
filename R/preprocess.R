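# Row-wise spectral pretreatments: standard normal variate, multiplicative
# scatter correction, and Savitzky-Golay smoothing. Each maps a
# spectrum_set to a spectrum_set on the same grid.

#' Specify a preprocessing method
#'
#' @param method one of `"RAW"`, `"SNV"`, `"MSC"`, `"SG"`.
#' @param sg_window odd Savitzky-Golay window length (default 7, the
#'   classical "7-point" smoother).
#' @param sg_polyorder polynomial degree, `< sg_window` (default 2).
#' @param msc_reference `"mean-of-set"` or an explicit reference spectrum.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("RAW", "SNV", "MSC", "SG"),
                            sg_window = 7, sg_polyorder = 2,
                            msc_reference = "mean-of-set") {
  method <- match.arg(toupper(method[1]), c("RAW", "SNV", "MSC", "SG"))
  if (!is_count(sg_window) || sg_window < 3 || sg_window %% 2 == 0)
    stop_fluortea("sg_window must be an odd integer >= 3", "configuration_error")
  if (!is_count(sg_polyorder) || sg_polyorder < 0 || sg_polyorder >= sg_window)
    stop_fluortea("sg_polyorder must satisfy 0 <= order < window",
                  "configuration_error")
  structure(list(method = method, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 msc_reference = msc_reference),
            class = "preprocess_spec")
}

#' Standard normal variate transform
#'
#' Centres and scales each spectrum to mean 0 and unit standard deviation
#' (sample sd, denominator n-1), removing per-sample multiplicative scatter
#' and additive offset.
#'
#' @param set a `spectrum_set` with >= 2 channels.
#' @return A preprocessed `spectrum_set`.
#' @export
snv <- function(set) {
  validate_spectrum_set(set)
  X <- set$intensities
  if (ncol(X) < 2)
    stop_fluortea("SNV needs >= 2 channels", "configuration_error")
  m <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  bad <- which(s == 0)
  if (length(bad))
    stop_fluortea(paste0("zero-variance spectrum for sample(s): ",
                         paste(set$sample_ids[bad], collapse = ", ")),
                  "degenerate_spectrum_error")
  spectrum_set(set$grid, (X - m) / s, set$labels, set$fractions,
               set$sample_ids, preprocessed = TRUE)
}

#' Multiplicative scatter correction
#'
#' Fits each spectrum to the reference by ordinary least squares,
#' `row ~ a + b * reference`, and returns `(row - a) / b`, inverting the
#' per-sample gain and offset the scatter model attributes to particle-size
#' effects.
#'
#' @param set a `spectrum_set`.
#' @param reference `"mean-of-set"` (default) or a numeric reference
#'   spectrum of channel length. Inside the modelling pipeline the
#'   reference is always the calibration-partition mean, so no information
#'   flows from the prediction partition.
#' @return A preprocessed `spectrum_set`.
#' @export
msc <- function(set, reference = "mean-of-set") {
  validate_spectrum_set(set)
  X <- set$intensities
  ref <- if (identical(reference, "mean-of-set")) colMeans(X) else as.numeric(reference)
  if (length(ref) != ncol(X))
    stop_fluortea("reference length must equal channel count", "configuration_error")
  if (stats::sd(ref) == 0)
    stop_fluortea("reference spectrum is constant", "configuration_error")
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  out <- X
  for (i in seq_len(nrow(X))) {
    b <- sum((X[i, ] - mean(X[i, ])) * rc) / denom
    if (abs(b) < 1e-12)
      stop_fluortea(paste0("degenerate MSC fit (b ~ 0) for sample ",
                           set$sample_ids[i]), "degenerate_spectrum_error")
    a <- mean(X[i, ]) - b * mean(ref)
    out[i, ] <- (X[i, ] - a) / b
  }
  spectrum_set(set$grid, out, set$labels, set$fractions, set$sample_ids,
               preprocessed = TRUE)
}

#' Savitzky-Golay smoothing
#'
#' Sliding-window local polynomial least-squares smoothing of each
#' spectrum along the channel axis. Interior channels take the value of
#' the degree-`polyorder` polynomial fitted to the centred window; edge
#' channels take the boundary polynomial fitted to the first/last full
#' window evaluated at their positions, so the grid is never shortened.
#'
#' @param set a `spectrum_set`.
#' @param window odd window length, `<=` channel count.
#' @param polyorder polynomial degree, `< window`.
#' @return A preprocessed `spectrum_set`.
#' @export
sg_smooth <- function(set, window = 7, polyorder = 2) {
  validate_spectrum_set(set)
  if (!is_count(window) || window %% 2 == 0 || window < 3)
    stop_fluortea("window must be an odd integer >= 3", "configuration_error")
  if (!is_count(polyorder) || polyorder < 0 || polyorder >= window)
    stop_fluortea("polyorder must satisfy 0 <= order < window", "configuration_error")
  if (window > ncol(set$intensities))
    stop_fluortea("window exceeds channel count", "configuration_error")
  sm <- t(apply(set$intensities, 1, signal::sgolayfilt,
                p = polyorder, n = window))
  spectrum_set(set$grid, sm, set$labels, set$fractions, set$sample_ids,
               preprocessed = TRUE)
}

#' Apply a preprocessing specification
#'
#' Dispatches to the identity (RAW), [snv()], [msc()] or [sg_smooth()].
#'
#' @param set a `spectrum_set`.
#' @param spec a `preprocess_spec`.
#' @param msc_reference optional reference spectrum overriding the spec's
#'   (the pipeline passes the calibration mean here).
#' @return A `spectrum_set`.
#' @export
preprocess <- function(set, spec, msc_reference = NULL) {
  stopifnot(inherits(spec, "preprocess_spec"))
  switch(spec$method,
    RAW = set,
    SNV = snv(set),
    MSC = msc(set, if (is.null(msc_reference)) spec$msc_reference else msc_reference),
    SG = sg_smooth(set, spec$sg_window, spec$sg_polyorder),
    stop_fluortea(paste0("unknown method ", spec$method), "configuration_error"))
}
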