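# Data model: wavelength grid, labelled spectra, hypercubes, ROIs, and the
# table readers/writers feeding the pipeline.

#' Construct a wavelength grid
#'
#' The channel axis every spectrum in the workflow lives on. The instrument
#' the workflow emulates covers 475-1000 nm in 104 channels; the exact
#' channel spacing is unpublished, so [default_grid()] assumes equal spacing.
#'
#' @param wavelengths_nm strictly increasing numeric vector of channel
#'   centres in nanometres, all within `[475, 1000]`.
#' @return An object of class `wavelength_grid`.
#' @export
#' @examples
#' g <- default_grid()
#' length(g$wavelengths_nm)  # 104
wavelength_grid <- function(wavelengths_nm) {
  w <- as.numeric(wavelengths_nm)
  if (length(w) < 2 || anyNA(w))
    stop_fluortea("wavelength grid needs >= 2 finite values", "format_error")
  if (any(diff(w) <= 0))
    stop_fluortea("wavelengths must be strictly increasing", "format_error")
  if (min(w) < 475 || max(w) > 1000)
    stop_fluortea("wavelengths must lie within [475, 1000] nm", "format_error")
  structure(list(wavelengths_nm = w), class = "wavelength_grid")
}

#' Default 104-channel grid spanning 475-1000 nm
#'
#' @return A `wavelength_grid` of 104 equally spaced channel centres from
#'   475 to 1000 nm inclusive.
#' @export
default_grid <- function() {
  wavelength_grid(seq(475, 1000, length.out = 104))
}

#' Construct a labelled spectrum set
#'
#' The canonical container: an `n x p` intensity matrix on a shared
#' wavelength grid, with per-sample class label, adulterant mass fraction
#' and id. Labels follow the study's mixing design: label `k` corresponds
#' to adulterant fraction `k/10`, for `k` in 0..5 (0 = pure Tieguanyin,
#' 5 = 50 % Benshan by mass).
#'
#' @param grid a `wavelength_grid`.
#' @param intensities numeric matrix, rows = samples, columns = channels.
#'   Raw intensities must be finite and non-negative; set
#'   `preprocessed = TRUE` for transformed spectra, which may be negative.
#' @param labels integer vector of class ids in 0..5.
#' @param fractions numeric vector of adulterant mass fractions; must equal
#'   `labels / 10`.
#' @param sample_ids character vector of opaque sample identifiers
#'   (defaults to `s1, s2, ...`).
#' @param preprocessed logical; relaxes the non-negativity invariant.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(grid, intensities, labels, fractions,
                         sample_ids = NULL, preprocessed = FALSE) {
  stopifnot(inherits(grid, "wavelength_grid"))
  intensities <- as.matrix(intensities)
  dimnames(intensities) <- NULL
  n <- nrow(intensities)
  if (is.null(sample_ids)) sample_ids <- if (n) paste0("s", seq_len(n)) else character(0)
  set <- structure(
    list(grid = grid, intensities = intensities,
         labels = as.integer(labels), fractions = as.numeric(fractions),
         sample_ids = as.character(sample_ids), preprocessed = preprocessed),
    class = "spectrum_set")
  validate_spectrum_set(set)
  set
}

#' Validate a spectrum set's invariants
#'
#' Checks dimensional consistency, finiteness, non-negativity of raw
#' intensities, and the label-fraction mapping of the mixing design
#' (label k paired with fraction k/10).
#'
#' @param set a `spectrum_set`.
#' @return `set`, invisibly; errors on violation.
#' @export
validate_spectrum_set <- function(set) {
  n <- nrow(set$intensities)
  if (ncol(set$intensities) != length(set$grid$wavelengths_nm))
    stop_fluortea("intensity columns do not match grid length", "validation_error")
  if (length(set$labels) != n || length(set$fractions) != n ||
      length(set$sample_ids) != n)
    stop_fluortea("labels/fractions/sample_ids length must equal sample count",
                  "validation_error")
  if (n == 0) return(invisible(set))
  if (!all(is.finite(set$intensities)))
    stop_fluortea("intensities must be finite", "validation_error")
  if (!isTRUE(set$preprocessed) && any(set$intensities < 0))
    stop_fluortea("raw intensities must be non-negative", "validation_error")
  if (any(set$labels < 0L | set$labels > 5L))
    stop_fluortea("labels must lie in 0..5", "validation_error")
  if (any(abs(set$fractions - set$labels / 10) > 1e-12))
    stop_fluortea("fractions must equal label/10 (mixing-design mapping)",
                  "validation_error")
  invisible(set)
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d samples x %d channels (%.1f-%.1f nm)%s\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$grid$wavelengths_nm), max(x$grid$wavelengths_nm),
              if (isTRUE(x$preprocessed)) ", preprocessed" else ""))
  if (nrow(x$intensities))
    print(table(label = x$labels))
  invisible(x)
}

#' Subset a spectrum set by sample index
#'
#' @param set a `spectrum_set`.
#' @param idx integer sample indices to keep.
#' @return A `spectrum_set` with the selected rows.
#' @export
subset_samples <- function(set, idx) {
  spectrum_set(set$grid, set$intensities[idx, , drop = FALSE],
               set$labels[idx], set$fractions[idx], set$sample_ids[idx],
               preprocessed = isTRUE(set$preprocessed))
}

# Table layout: column 1 sample_id, column 2 label, column 3 fraction,
# remaining columns intensities with wavelength-nm headers. Values are
# written with 17 significant digits so the read/write round trip is
# bit-for-bit on doubles.

#' Read a labelled spectra table (CSV)
#'
#' @param path path to a CSV whose header carries `sample_id,label,fraction`
#'   followed by numeric wavelength columns.
#' @param preprocessed logical, passed through to [spectrum_set()].
#' @return A validated `spectrum_set`; channel order follows the file.
#' @export
read_spectra_table <- function(path, preprocessed = FALSE) {
  if (!file.exists(path))
    stop_fluortea(paste0("file not found: ", path), "io_error")
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 4 ||
      !identical(names(df)[1:3], c("sample_id", "label", "fraction")))
    stop_fluortea("header must start with sample_id,label,fraction", "format_error")
  wl_txt <- names(df)[-(1:3)]
  wl <- suppressWarnings(as.numeric(wl_txt))
  if (anyNA(wl))
    stop_fluortea("wavelength headers must be parseable as numbers", "format_error")
  if (anyDuplicated(wl))
    stop_fluortea("duplicate wavelength headers", "format_error")
  n <- nrow(df)
  parse_num <- function(txt, col_name) {
    v <- suppressWarnings(as.numeric(txt))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      stop_fluortea(sprintf("non-numeric cell at row %d, column '%s'",
                            row, col_name), "parse_error")
    }
    v
  }
  labels <- if (n) parse_num(df$label, "label") else integer(0)
  if (n && any(labels != round(labels) | labels < 0 | labels > 5))
    stop_fluortea("label outside 0..5", "validation_error")
  fractions <- if (n) parse_num(df$fraction, "fraction") else numeric(0)
  ints <- matrix(0, n, length(wl))
  for (j in seq_along(wl))
    ints[, j] <- if (n) parse_num(df[[j + 3]], wl_txt[j]) else numeric(0)
  spectrum_set(wavelength_grid(wl), ints, as.integer(labels), fractions,
               df$sample_id, preprocessed = preprocessed)
}

#' Write a labelled spectra table (CSV)
#'
#' Inverse of [read_spectra_table()]; numeric values are serialized at full
#' double precision so the round trip is exact.
#'
#' @param set a `spectrum_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(set, path) {
  validate_spectrum_set(set)
  fmt <- function(x) sprintf("%.17g", x)
  header <- c("sample_id", "label", "fraction", fmt(set$grid$wavelengths_nm))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_fluortea(paste0("cannot open for writing: ", path), "io_error"))
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  n <- nrow(set$intensities)
  if (n) {
    body <- cbind(set$sample_ids, as.character(set$labels),
                  fmt(set$fractions),
                  matrix(fmt(set$intensities), n))
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Construct a hyperspectral cube
#'
#' @param data 3-D numeric array, `rows x cols x channels`.
#' @param grid a `wavelength_grid` whose length equals the spectral axis.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (length(dim(data)) != 3)
    stop_fluortea("cube data must be a 3-D array", "validation_error")
  if (dim(data)[3] != length(grid$wavelengths_nm))
    stop_fluortea("cube spectral axis does not match grid", "validation_error")
  structure(list(data = data, grid = grid), class = "hypercube")
}

#' Construct a rectangular region of interest
#'
#' Pixel bounds are 0-based and half-open on both axes: the ROI covers rows
#' `row_start .. row_stop - 1` and columns `col_start .. col_stop - 1`.
#'
#' @param row_start,row_stop,col_start,col_stop integer bounds.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(row_start, row_stop, col_start, col_stop) {
  b <- c(row_start, row_stop, col_start, col_stop)
  if (!all(vapply(b, is_count, logical(1))))
    stop_fluortea("ROI bounds must be integers", "bounds_error")
  if (row_start >= row_stop || col_start >= col_stop)
    stop_fluortea("ROI must satisfy start < stop on both axes", "bounds_error")
  if (row_start < 0 || col_start < 0)
    stop_fluortea("ROI bounds must be non-negative", "bounds_error")
  structure(list(row_start = as.integer(row_start), row_stop = as.integer(row_stop),
                 col_start = as.integer(col_start), col_stop = as.integer(col_stop)),
            class = "rect_roi")
}

#' Mean spectrum over a rectangular region of interest
#'
#' Reduces an imaged sample to one spectrum: channel `c` of the result is
#' the arithmetic mean of the cube over the ROI pixels at channel `c` —
#' the standard ROI reduction when a whole-sample mean spectrum stands in
#' for the imaged sample.
#'
#' @param cube a `hypercube`.
#' @param roi a `rect_roi` lying within the cube extents.
#' @return Numeric vector of length `n_channels`.
#' @export
roi_mean_spectrum <- function(cube, roi) {
  stopifnot(inherits(cube, "hypercube"), inherits(roi, "rect_roi"))
  d <- dim(cube$data)
  if (roi$row_stop > d[1] || roi$col_stop > d[2])
    stop_fluortea("ROI exceeds cube extents", "bounds_error")
  block <- cube$data[(roi$row_start + 1):roi$row_stop,
                     (roi$col_start + 1):roi$col_stop, , drop = FALSE]
  apply(block, 3, mean)
}

#' Read an ENVI-format hyperspectral cube
#'
#' Minimal read-only support for the ENVI header + flat-binary layout
#' (BSQ/BIL/BIP interleaves; data types 1, 2, 4, 5, 12). Wavelengths are
#' taken from the header's `wavelength` field.
#'
#' @param hdr_path path to the `.hdr` header; the body is looked up by
#'   dropping the extension (or at `img_path`).
#' @param img_path optional explicit path to the binary body.
#' @return A `hypercube`.
#' @export
read_envi <- function(hdr_path, img_path = NULL) {
  if (!file.exists(hdr_path))
    stop_fluortea(paste0("header not found: ", hdr_path), "io_error")
  raw_lines <- readLines(hdr_path, warn = FALSE)
  # join braced multi-line values onto their key's line
  entries <- character(0)
  buf <- ""
  for (ln in raw_lines) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    open <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    close <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (open > close) next
    entries <- c(entries, buf)
    buf <- ""
  }
  get_field <- function(key, required = TRUE) {
    hit <- grep(paste0("^\\s*", key, "\\s*="), entries, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) {
      if (required) stop_fluortea(paste0("ENVI header missing '", key, "'"), "format_error")
      return(NULL)
    }
    val <- sub("^[^=]*=\\s*", "", hit[1])
    trimws(gsub("[{}]", "", val))
  }
  samples <- as.integer(get_field("samples"))
  lines_n <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  dtype <- as.integer(get_field("data type"))
  interleave <- tolower(get_field("interleave"))
  byte_order <- get_field("byte order", required = FALSE)
  endian <- if (!is.null(byte_order) && as.integer(byte_order) == 1) "big" else "little"
  wl_txt <- get_field("wavelength", required = FALSE)
  wl <- if (is.null(wl_txt)) seq(475, 1000, length.out = bands) else
    as.numeric(strsplit(wl_txt, ",")[[1]])
  if (is.null(img_path)) {
    base <- sub("\\.hdr$", "", hdr_path, ignore.case = TRUE)
    cand <- c(base, paste0(base, c(".img", ".dat", ".bsq", ".bil", ".bip")))
    img_path <- cand[file.exists(cand)][1]
    if (is.na(img_path))
      stop_fluortea("ENVI binary body not found next to header", "io_error")
  }
  spec <- switch(as.character(dtype),
    "1" = list(what = "integer", size = 1, signed = FALSE),
    "2" = list(what = "integer", size = 2, signed = TRUE),
    "4" = list(what = "numeric", size = 4, signed = TRUE),
    "5" = list(what = "numeric", size = 8, signed = TRUE),
    "12" = list(what = "integer", size = 2, signed = FALSE),
    stop_fluortea(paste0("unsupported ENVI data type ", dtype), "format_error"))
  n_vals <- samples * lines_n * bands
  raw <- readBin(img_path, spec$what, n = n_vals, size = spec$size,
                 signed = spec$signed, endian = endian)
  if (length(raw) != n_vals)
    stop_fluortea("ENVI body shorter than header implies", "format_error")
  # ENVI files are band/row-major with samples (columns) varying fastest
  arr <- switch(interleave,
    bsq = aperm(array(raw, c(samples, lines_n, bands)), c(2, 1, 3)),
    bil = aperm(array(raw, c(samples, bands, lines_n)), c(3, 1, 2)),
    bip = aperm(array(raw, c(bands, samples, lines_n)), c(3, 2, 1)),
    stop_fluortea(paste0("unsupported interleave '", interleave, "'"), "format_error"))
  hypercube(arr, wavelength_grid(wl))
}
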