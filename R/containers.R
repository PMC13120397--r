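#' Spectrum set container
#'
#' A `spectrum_set` bundles a samples x bands reflectance matrix with its
#' wavelength grid (nm) and per-sample identifiers. All preprocessing,
#' selection and modelling functions in the package operate on this
#' container or on its bare matrix.
#'
#' @param X numeric matrix, samples in rows, bands in columns. Finite.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, length `ncol(X)`.
#' @param sample_ids character vector of length `nrow(X)`; defaults to
#'   `"s1", "s2", ...`.
#' @return An object of class `spectrum_set`: a list with elements `X`,
#'   `wavelengths`, `sample_ids`.
#' @export
spectrum_set <- function(X, wavelengths, sample_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(X) != length(wavelengths)) {
    stop("ncol(X) [", ncol(X), "] must match length(wavelengths) [",
         length(wavelengths), "]")
  }
  if (any(!is.finite(X))) stop("spectrum_set: X contains non-finite values")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(X)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(X)) {
    stop("length(sample_ids) must equal nrow(X)")
  }
  rownames(X) <- sample_ids
  structure(list(X = X, wavelengths = wavelengths, sample_ids = sample_ids),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("spectrum_set:", nrow(x$X), "samples x", ncol(x$X), "bands (",
      format(min(x$wavelengths), digits = 6), "-",
      format(max(x$wavelengths), digits = 6), "nm )\n")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$X)

#' Subset a spectrum set by sample and/or band index
#'
#' @param x a `spectrum_set`.
#' @param samples integer/logical index of rows to keep (default all).
#' @param bands integer/logical index of bands to keep (default all).
#' @return A `spectrum_set` with the requested rows/columns.
#' @export
subset_spectra <- function(x, samples = NULL, bands = NULL) {
  stopifnot(inherits(x, "spectrum_set"))
  if (is.null(samples)) samples <- seq_len(nrow(x$X))
  if (is.null(bands)) bands <- seq_len(ncol(x$X))
  spectrum_set(x$X[samples, bands, drop = FALSE],
               x$wavelengths[bands],
               x$sample_ids[samples])
}

#' Single-spectrum container
#'
#' @param reflectance numeric vector of reflectance values.
#' @param wavelengths numeric vector of wavelengths (nm), same length.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(reflectance, wavelengths) {
  reflectance <- as.numeric(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (length(reflectance) != length(wavelengths)) {
    stop("reflectance and wavelengths must have the same length")
  }
  if (any(!is.finite(reflectance))) stop("spectrum: non-finite reflectance")
  structure(list(reflectance = reflectance, wavelengths = wavelengths),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("spectrum:", length(x$reflectance), "bands (",
      format(min(x$wavelengths), digits = 6), "-",
      format(max(x$wavelengths), digits = 6), "nm )\n")
  invisible(x)
}

#' Hyperspectral cube container
#'
#' Holds a rows x cols x bands data cube from a line-scan imager, either as
#' raw digital numbers (`kind = "raw"`) or as reflectance after white/dark
#' correction (`kind = "reflectance"`).
#'
#' @param values 3-D numeric array, dimensions rows x cols x bands.
#' @param wavelengths band-centre wavelengths in nm, strictly increasing.
#' @param kind `"raw"` or `"reflectance"`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(values, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  wavelengths <- as.numeric(wavelengths)
  if (dim(values)[3] != length(wavelengths)) {
    stop("third array dimension must match length(wavelengths)")
  }
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (kind == "reflectance" && any(!is.finite(values))) {
    stop("reflectance cube contains non-finite values")
  }
  structure(list(values = values, wavelengths = wavelengths, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat("hypercube [", x$kind, "]:", d[1], "x", d[2], "pixels x", d[3], "bands\n")
  invisible(x)
}

#' White/dark reference frames for reflectance correction
#'
#' Reference scans of the ~99% whiteboard and the lens-cap dark frame. Frames
#' may be full cubes matching the sample scan, or single-line scans
#' (1 x cols x bands, or a cols x bands matrix) that are broadcast along the
#' row (scan) axis, as line-scan imagers record them once per acquisition.
#'
#' @param white,dark numeric arrays: rows x cols x bands, 1 x cols x bands,
#'   or cols x bands matrices.
#' @return An object of class `reference_frames`.
#' @export
reference_frames <- function(white, dark) {
  norm_ref <- function(a, nm) {
    if (is.matrix(a)) a <- array(a, dim = c(1L, dim(a)))
    if (length(dim(a)) != 3L) stop(nm, " must be a 3-D array or a matrix")
    a
  }
  white <- norm_ref(white, "white")
  dark <- norm_ref(dark, "dark")
  if (!identical(dim(white), dim(dark))) {
    stop("white and dark frames must have identical dimensions")
  }
  structure(list(white = white, dark = dark), class = "reference_frames")
}

#' Write a spectrum set to CSV
#'
#' Layout: header `sample_id,<wl1>,<wl2>,...` with wavelengths printed at two
#' decimals; one row per sample.
#'
#' @param x a `spectrum_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  df <- data.frame(sample_id = x$sample_ids, x$X, check.names = FALSE)
  names(df) <- c("sample_id", sprintf("%.2f", x$wavelengths))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum set from CSV
#'
#' @param path CSV written by [write_spectra_csv()] (header
#'   `sample_id,<wl...>`).
#' @return A `spectrum_set`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be 'sample_id'")
  wl <- as.numeric(names(df)[-1])
  if (any(is.na(wl))) stop("non-numeric wavelength column headers")
  spectrum_set(as.matrix(df[, -1, drop = FALSE]), wl, df$sample_id)
}

#' Read a reference-value vector from CSV
#'
#' Accepts either a single-column file or a two-column `sample_id,value`
#' layout; values are analyte mass fractions in percent.
#'
#' @param path CSV path.
#' @return Named numeric vector (names are sample ids when present).
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) == 1L) {
    y <- as.numeric(df[[1]])
  } else {
    y <- as.numeric(df[[2]])
    names(y) <- as.character(df[[1]])
  }
  if (any(is.na(y))) stop("reference CSV contains non-numeric values")
  y
}
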