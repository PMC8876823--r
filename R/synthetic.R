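# Synthetic fluorescence-like mixture spectra with the statistical structure
# the downstream analysis assumes: two visually similar chlorophyll-shaped
# endmembers mixed linearly by mass fraction, observed through per-sample
# gain/offset/drift artefacts plus channel noise.

#' Specify an endmember (pure-component) spectrum
#'
#' An endmember is a non-negative baseline plus a sum of Gaussian emission
#' peaks. The default authentic-tea shape carries the landmarks of
#' chlorophyll fluorescence: a low, broad green-region bump (500-650 nm),
#' a reabsorption trough just short of the red emission band, and the
#' bimodal near-infrared peaks around 690 and 735 nm.
#'
#' @param name character label.
#' @param peaks list of `c(centre_nm, width_nm, amplitude)` triples;
#'   centres within the grid range, widths positive, amplitudes
#'   non-negative.
#' @param baseline_level non-negative scalar.
#' @return An object of class `endmember_spec`.
#' @export
endmember_spec <- function(name, peaks, baseline_level = 0) {
  if (length(peaks) < 1)
    stop_fluortea("endmember needs at least one peak", "validation_error")
  for (p in peaks) {
    if (length(p) != 3 || p[2] <= 0 || p[3] < 0)
      stop_fluortea("each peak is c(centre, width > 0, amplitude >= 0)",
                    "validation_error")
    if (p[1] < 475 || p[1] > 1000)
      stop_fluortea("peak centres must lie within the grid range", "validation_error")
  }
  if (baseline_level < 0)
    stop_fluortea("baseline_level must be non-negative", "validation_error")
  structure(list(name = name, peaks = peaks, baseline_level = baseline_level),
            class = "endmember_spec")
}

#' Specify the per-sample measurement-artefact model
#'
#' The four artefact magnitudes the pretreatments are designed to remove:
#' i.i.d. additive channel noise, a per-sample multiplicative gain about 1
#' (scatter), a per-sample additive offset (baseline shift), and a
#' per-sample linear baseline drift per nm (tilt). All in the intensity
#' units of the endmembers (peak amplitude ~1 under the defaults).
#'
#' @param additive_sd,mult_scale_sd,offset_sd,baseline_slope_sd
#'   non-negative scalars.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0, mult_scale_sd = 0, offset_sd = 0,
                        baseline_slope_sd = 0) {
  v <- c(additive_sd, mult_scale_sd, offset_sd, baseline_slope_sd)
  if (any(!is.finite(v)) || any(v < 0))
    stop_fluortea("noise magnitudes must be finite and non-negative",
                  "validation_error")
  structure(list(additive_sd = additive_sd, mult_scale_sd = mult_scale_sd,
                 offset_sd = offset_sd, baseline_slope_sd = baseline_slope_sd),
            class = "noise_model")
}

#' Specify the mixture design
#'
#' @param fractions distinct adulterant mass fractions in `[0, 1]`
#'   (default the study design 0, 0.1, ..., 0.5).
#' @param n_per_class samples per fraction (default 48, giving 288 total).
#' @return An object of class `mixture_design`.
#' @export
mixture_design <- function(fractions = seq(0, 0.5, by = 0.1), n_per_class = 48) {
  if (anyDuplicated(fractions) || any(fractions < 0 | fractions > 1))
    stop_fluortea("fractions must be distinct and within [0, 1]", "design_error")
  if (!is_count(n_per_class) || n_per_class < 1)
    stop_fluortea("n_per_class must be a positive integer", "design_error")
  structure(list(fractions = as.numeric(fractions),
                 n_per_class = as.integer(n_per_class)),
            class = "mixture_design")
}

#' Assemble a synthetic-set configuration
#'
#' @param grid a `wavelength_grid`.
#' @param pure,adulterant `endmember_spec`s for the authentic tea and the
#'   adulterant.
#' @param design a `mixture_design`.
#' @param noise a `noise_model`.
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid, pure, adulterant, design, noise, seed) {
  stopifnot(inherits(grid, "wavelength_grid"),
            inherits(pure, "endmember_spec"),
            inherits(adulterant, "endmember_spec"),
            inherits(design, "mixture_design"),
            inherits(noise, "noise_model"))
  structure(list(grid = grid, pure = pure, adulterant = adulterant,
                 design = design, noise = noise, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Evaluate an endmember spectrum on a grid
#'
#' Value at wavelength `w` is
#' `baseline + sum_peaks amplitude * exp(-(w - centre)^2 / (2 width^2))`.
#'
#' @param spec an `endmember_spec`.
#' @param grid a `wavelength_grid`.
#' @return Non-negative numeric vector, one value per channel.
#' @export
endmember_spectrum <- function(spec, grid) {
  stopifnot(inherits(spec, "endmember_spec"), inherits(grid, "wavelength_grid"))
  w <- grid$wavelengths_nm
  v <- rep(spec$baseline_level, length(w))
  for (p in spec$peaks)
    v <- v + p[3] * exp(-(w - p[1])^2 / (2 * p[2]^2))
  v
}

#' Simulate a labelled mixture spectrum set
#'
#' For a sample with adulterant fraction `f`, the noiseless spectrum is the
#' linear blend `(1 - f) * pure + f * adulterant`. The observed spectrum is
#' `gain * clean + offset + slope * (w - w_min) +` channel noise, with
#' `gain ~ N(1, mult_scale_sd)`, `offset ~ N(0, offset_sd)`,
#' `slope ~ N(0, baseline_slope_sd)` and channel noise i.i.d.
#' `N(0, additive_sd)`; negative values are clipped to zero (fluorescence
#' is physically non-negative). One RNG stream seeded from `config$seed` is
#' consumed in a fixed, documented order — per sample: gain, offset, slope,
#' then the channel-noise vector — so the output is bitwise reproducible.
#'
#' Labels follow the mixing-design mapping (label = fraction x 10), which
#' restricts usable fractions to 0, 0.1, ..., 0.5.
#'
#' @param config a `synthetic_config`.
#' @return A validated `spectrum_set` of
#'   `length(fractions) * n_per_class` samples.
#' @export
simulate_set <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  des <- config$design
  if (any(des$fractions < 0 | des$fractions > 1))
    stop_fluortea("fractions outside [0,1]", "design_error")
  w <- config$grid$wavelengths_nm
  p <- length(w)
  e_pure <- endmember_spectrum(config$pure, config$grid)
  e_adu <- endmember_spectrum(config$adulterant, config$grid)
  n <- length(des$fractions) * des$n_per_class
  X <- matrix(0, n, p)
  labels <- integer(n)
  fractions <- numeric(n)
  ids <- character(n)
  nm <- config$noise
  with_local_seed(config$seed, {
    r <- 0L
    for (f in des$fractions) {
      clean <- (1 - f) * e_pure + f * e_adu
      lab <- as.integer(round(f * 10))
      for (j in seq_len(des$n_per_class)) {
        r <- r + 1L
        gain <- stats::rnorm(1, 1, nm$mult_scale_sd)
        offset <- stats::rnorm(1, 0, nm$offset_sd)
        slope <- stats::rnorm(1, 0, nm$baseline_slope_sd)
        eps <- stats::rnorm(p, 0, nm$additive_sd)
        X[r, ] <- pmax(0, gain * clean + offset + slope * (w - w[1]) + eps)
        labels[r] <- lab
        fractions[r] <- f
        ids[r] <- sprintf("f%02d_%03d", lab, j)
      }
    }
  })
  spectrum_set(config$grid, X, labels, fractions, ids)
}

#' Default synthetic configuration emulating the tea-adulteration study
#'
#' Encodes the study conditions: six Benshan mass fractions 0-50 % in 10 %
#' steps, 48 samples each (288 total), on the 104-channel 475-1000 nm grid.
#' The two endmembers share the chlorophyll-like shape (low 500-650 nm
#' region, trough just below the red emission band, bimodal peaks near 690
#' and 735 nm) and differ only by small amplitude/width shifts, so the
#' noiseless class means are pairwise correlated above 0.99 — classes a
#' naked eye could not tell apart, which is what makes the discrimination
#' task non-trivial. Noise magnitudes are set so the pure-vs-adulterated
#' task is nearly saturated while the 6-level task is not, mirroring the
#' difficulty ordering of the original measurements.
#'
#' @param seed integer RNG seed for [simulate_set()].
#' @return A `synthetic_config`.
#' @export
#' @examples
#' set <- simulate_set(default_config(1))
#' set
default_config <- function(seed) {
  grid <- default_grid()
  pure <- endmember_spec("tieguanyin", list(
    c(590, 70, 0.22), c(690, 5, 1.00), c(735, 16, 0.80)), baseline_level = 0.02)
  adulterant <- endmember_spec("benshan", list(
    c(590, 70, 0.25), c(690, 5, 0.92), c(735, 17, 0.88)), baseline_level = 0.02)
  synthetic_config(
    grid, pure, adulterant,
    design = mixture_design(),
    noise = noise_model(additive_sd = 0.003, mult_scale_sd = 0.01,
                        offset_sd = 0.003, baseline_slope_sd = 5e-6),
    seed = seed)
}
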