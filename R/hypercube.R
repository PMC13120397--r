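#' White/dark reflectance correction of a raw hypercube
#'
#' Converts raw digital numbers to reflectance with the standard two-point
#' calibration \deqn{I = (I_O - B) / (W - B)} where \eqn{I_O} is the raw scan,
#' \eqn{W} the whiteboard scan and \eqn{B} the dark scan. Single-line
#' reference frames are broadcast along the row (scan) axis.
#'
#' @param raw a `hypercube` with `kind == "raw"`.
#' @param refs a [reference_frames()] object. Shapes must match the cube's
#'   cols x bands; rows either match or equal 1.
#' @return A `hypercube` with `kind == "reflectance"`, same wavelengths.
#' @details The white-minus-dark denominator is guarded: any element smaller
#'   than `1e-9` of the white-dark data range is an error naming the first
#'   offending band, rather than being clamped — a near-zero denominator
#'   indicates an acquisition fault that silent clamping would hide.
#' @export
reflectance_correct <- function(raw, refs) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_frames"))
  if (raw$kind != "raw") stop("cube has kind '", raw$kind, "'; expected 'raw'")
  d <- dim(raw$values)
  dw <- dim(refs$white)
  if (!identical(dw[2:3], d[2:3])) {
    stop("reference frames (cols x bands ", dw[2], "x", dw[3],
         ") do not match cube (", d[2], "x", d[3], ")")
  }
  if (!(dw[1] == d[1] || dw[1] == 1L)) {
    stop("reference frames must have the cube's row count or a single line")
  }
  white <- refs$white
  dark <- refs$dark
  if (dw[1] == 1L && d[1] > 1L) {
    idx <- rep(1L, d[1])
    white <- white[idx, , , drop = FALSE]
    dark <- dark[idx, , , drop = FALSE]
  }
  denom <- white - dark
  eps <- 1e-9 * max(abs(range(denom)), 1e-300)
  if (any(denom <= eps)) {
    bad <- which(apply(denom <= eps, 3, any))[1]
    stop("white - dark is <= epsilon at band ", bad, " (",
         format(raw$wavelengths[bad], digits = 6),
         " nm); check the reference scans")
  }
  vals <- (raw$values - dark) / denom
  hypercube(vals, raw$wavelengths, kind = "reflectance")
}

#' Otsu threshold of a grayscale image
#'
#' Histogram threshold maximizing the between-class variance over a 256
#' equal-width-bin histogram spanning `[min, max]` of the image. The
#' threshold is reported as the left edge of the first bin of the upper
#' class; ties are broken toward the lowest threshold.
#'
#' @param image finite numeric matrix (or vector) with at least two distinct
#'   values.
#' @param n_bins number of histogram bins (default 256).
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  if (any(!is.finite(v))) stop("image contains non-finite values")
  lo <- min(v); hi <- max(v)
  if (lo == hi) stop("constant image: no separable classes")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  # findInterval with rightmost.closed puts hi into the last bin
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  n <- length(v)
  cum_n <- cumsum(counts)
  cum_s <- cumsum(counts * mids)
  tot_s <- cum_s[n_bins]
  # split before bin k (k = 2..n_bins): lower class = bins < k
  k <- 2:n_bins
  n0 <- cum_n[k - 1L]
  n1 <- n - n0
  s0 <- cum_s[k - 1L]
  valid <- n0 > 0 & n1 > 0
  var_b <- rep(-Inf, length(k))
  mu0 <- s0[valid] / n0[valid]
  mu1 <- (tot_s - s0[valid]) / n1[valid]
  var_b[valid] <- (n0[valid] / n) * (n1[valid] / n) * (mu0 - mu1)^2
  best <- k[which.max(var_b)]
  edges[best]
}

#' Segment the sample region using a guide band
#'
#' Extracts the single-band image nearest `guide_nm`, thresholds it with
#' [otsu_threshold()], and labels above-threshold pixels as sample (1) —
#' the seeds sit brighter than the black dish background at the guide
#' wavelength — and the rest as background (0).
#'
#' @param cube a reflectance `hypercube`.
#' @param guide_nm guide wavelength in nm (default 1290); must lie within
#'   the cube's wavelength range.
#' @return Integer 0/1 matrix of the cube's spatial shape, with the chosen
#'   band index and threshold attached as attributes `band` and `threshold`.
#' @export
segment_guide_band <- function(cube, guide_nm = 1290) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") {
    stop("segmentation expects a reflectance cube; run reflectance_correct()")
  }
  wl <- cube$wavelengths
  if (guide_nm < min(wl) || guide_nm > max(wl)) {
    stop("guide wavelength ", guide_nm, " nm outside cube range [",
         min(wl), ", ", max(wl), "]")
  }
  band <- which.min(abs(wl - guide_nm))
  img <- cube$values[, , band]
  thr <- otsu_threshold(img)
  mask <- matrix(as.integer(img > thr), nrow = nrow(img))
  attr(mask, "band") <- band
  attr(mask, "threshold") <- thr
  mask
}

#' Mean spectrum over a binary mask
#'
#' Per band, the arithmetic mean of reflectance over `mask == 1` pixels —
#' the region-of-interest mean spectrum of one scan.
#'
#' @param cube a reflectance `hypercube`.
#' @param mask 0/1 matrix matching the cube's spatial shape, with at least
#'   one valid pixel.
#' @return A [spectrum()].
#' @export
mask_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  if (!identical(dim(mask), d[1:2])) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match cube spatial shape ", d[1], "x", d[2])
  }
  sel <- which(mask == 1)
  if (length(sel) == 0L) stop("empty mask: no valid pixels")
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  spectrum(colMeans(flat[sel, , drop = FALSE]), cube$wavelengths)
}

#' Average replicate scan spectra
#'
#' Elementwise mean across replicate scans of the same physical sample
#' (three scans per sample in the reference acquisition protocol).
#'
#' @param spectra list of [spectrum()] objects on identical wavelength grids.
#' @return A [spectrum()].
#' @export
average_replicates <- function(spectra) {
  if (length(spectra) == 0L) stop("need at least one spectrum")
  if (!all(vapply(spectra, inherits, logical(1), "spectrum"))) {
    stop("all elements must be spectrum objects")
  }
  wl <- spectra[[1]]$wavelengths
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wavelengths, wl))) {
      stop("replicate spectra are on different wavelength grids")
    }
  }
  refl <- rowMeans(vapply(spectra, function(s) s$reflectance,
                          numeric(length(wl))))
  spectrum(refl, wl)
}

#' Trim a spectrum set to a wavelength window
#'
#' Keeps exactly the bands whose stored wavelength lies in the closed
#' interval `[low_nm, high_nm]` (exact comparisons on the stored grid, no
#' nearest-value snapping), preserving band order. Used to discard the
#' low-signal edges of the detector range before modelling.
#'
#' @param x a `spectrum_set`.
#' @param low_nm,high_nm window bounds in nm, `low_nm < high_nm`.
#'   Defaults 940 and 1670.
#' @return A trimmed `spectrum_set`.
#' @export
trim_bands <- function(x, low_nm = 940, high_nm = 1670) {
  stopifnot(inherits(x, "spectrum_set"))
  if (!(low_nm < high_nm)) stop("low_nm must be < high_nm")
  keep <- which(x$wavelengths >= low_nm & x$wavelengths <= high_nm)
  if (length(keep) == 0L) {
    stop("no bands retained in [", low_nm, ", ", high_nm, "] nm")
  }
  subset_spectra(x, bands = keep)
}
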