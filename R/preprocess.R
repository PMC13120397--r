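#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed on a reference spectrum by ordinary least
#' squares, x ~ a * ref + b, and corrected to (x - b) / a. This removes
#' per-sample multiplicative and additive scatter caused by differences in
#' particle size and packing. The reference defaults to the column mean of
#' the fitting set and is returned so that prediction-set rows can be
#' corrected against the calibration reference (no information leakage).
#'
#' @param x a `spectrum_set`.
#' @param reference optional numeric vector (length = bands) to correct
#'   against; defaults to `colMeans(x$X)`, which requires at least 2 samples.
#' @return A `spectrum_set` with attributes `reference` (the spectrum used)
#'   and `coefficients` (per-row `(a, b)`).
#' @export
msc <- function(x, reference = NULL) {
  stopifnot(inherits(x, "spectrum_set"))
  X <- x$X
  if (is.null(reference)) {
    if (nrow(X) < 2L) stop("MSC needs >= 2 samples to form a mean reference")
    reference <- colMeans(X)
  }
  reference <- as.numeric(reference)
  if (length(reference) != ncol(X)) stop("reference length must equal bands")
  rc <- reference - mean(reference)
  srr <- sum(rc^2)
  if (srr <= 0) stop("zero-variance reference spectrum")
  # closed-form simple regression of each row on the reference:
  # a = cov(x, ref)/var(ref); the row-mean term vanishes against centred rc
  a <- as.numeric(X %*% rc) / srr
  b <- rowMeans(X) - a * mean(reference)
  bad <- which(abs(a) < 1e-12)
  if (length(bad)) {
    stop("MSC slope is zero for sample(s): ",
         paste(x$sample_ids[bad], collapse = ", "))
  }
  Xc <- (X - b) / a
  out <- spectrum_set(Xc, x$wavelengths, x$sample_ids)
  attr(out, "reference") <- reference
  attr(out, "coefficients") <- cbind(a = a, b = b)
  out
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing of each spectrum over a centred
#' moving window; the terminal windows are handled by evaluating the local
#' polynomial fit at the off-centre edge points, so the output has the same
#' length as the input.
#'
#' @param x a `spectrum_set`.
#' @param window odd window length >= 5, `<=` bands. Default 11.
#' @param polyorder polynomial order, `>= 2` and `< window`. Default 2.
#' @return A smoothed `spectrum_set`.
#' @export
savitzky_golay <- function(x, window = 11L, polyorder = 2L) {
  stopifnot(inherits(x, "spectrum_set"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window < 5L) stop("window must be odd and >= 5")
  if (polyorder < 2L || polyorder >= window) {
    stop("polyorder must be >= 2 and < window")
  }
  if (window > ncol(x$X)) stop("window exceeds number of bands")
  Xs <- t(apply(x$X, 1, signal::sgolayfilt, p = polyorder, n = window))
  spectrum_set(Xs, x$wavelengths, x$sample_ids)
}

#' First derivative of reflectance with respect to wavelength
#'
#' Finite-difference slope dR/dlambda in per-nm units: central differences
#' at interior bands, one-sided differences at the two edges; output has the
#' same number of bands as the input so band bookkeeping for wavelength
#' selection is preserved.
#'
#' @param x a `spectrum_set` with >= 3 bands on a strictly increasing grid.
#' @return A `spectrum_set` of derivatives (units: reflectance per nm).
#' @export
first_derivative <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  wl <- x$wavelengths
  p <- length(wl)
  if (p < 3L) stop("first derivative needs >= 3 bands")
  if (any(diff(wl) <= 0)) stop("wavelength grid must be strictly increasing")
  X <- x$X
  D <- matrix(0, nrow(X), p)
  D[, 1] <- (X[, 2] - X[, 1]) / (wl[2] - wl[1])
  D[, p] <- (X[, p] - X[, p - 1]) / (wl[p] - wl[p - 1])
  i <- 2:(p - 1)
  D[, i] <- sweep(X[, i + 1, drop = FALSE] - X[, i - 1, drop = FALSE], 2,
                  wl[i + 1] - wl[i - 1], "/")
  spectrum_set(D, wl, x$sample_ids)
}

#' Standard normal variate transformation
#'
#' Standardizes each spectrum individually: subtract the row mean, divide by
#' the row standard deviation (denominator n - 1). Removes per-sample
#' multiplicative scatter without a reference spectrum.
#'
#' @param x a `spectrum_set`; every row must have nonzero standard deviation.
#' @return A `spectrum_set` whose rows have mean 0 and sd 1.
#' @export
snv <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  X <- x$X
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  bad <- which(sdv <= 0 | !is.finite(sdv))
  if (length(bad)) {
    stop("constant spectrum (zero sd) for sample(s): ",
         paste(x$sample_ids[bad], collapse = ", "))
  }
  spectrum_set((X - mu) / sdv, x$wavelengths, x$sample_ids)
}

#' Preprocessing specification
#'
#' @param method one of `"RAW"`, `"MSC"`, `"SG"`, `"FD"`, `"SNV"`.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters, used only when
#'   `method == "SG"`.
#' @return A `preprocess_spec` list.
#' @export
preprocess_spec <- function(method = c("RAW", "MSC", "SG", "FD", "SNV"),
                            sg_window = 11L, sg_polyorder = 2L) {
  method <- match.arg(toupper(method), c("RAW", "MSC", "SG", "FD", "SNV"))
  structure(list(method = method, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder)),
            class = "preprocess_spec")
}

#' Apply a preprocessing method with calibration-fitted state
#'
#' Uniform dispatch over the preprocessing methods so the experiment grid
#' can iterate them. Stateful methods (currently MSC, whose reference
#' spectrum is fitted on the calibration set) fit their state on the first
#' call and reuse it when `fitted_state` is supplied, so prediction-set rows
#' are corrected against the calibration reference.
#'
#' @param x a `spectrum_set`.
#' @param spec a [preprocess_spec()] (or a method name string).
#' @param fitted_state state returned by a previous call on the calibration
#'   set, or `NULL` to fit.
#' @return A list with elements `data` (the transformed `spectrum_set`) and
#'   `state` (to pass back in for prediction rows).
#' @export
apply_preprocess <- function(x, spec, fitted_state = NULL) {
  if (is.character(spec)) spec <- preprocess_spec(spec)
  stopifnot(inherits(spec, "preprocess_spec"))
  out <- switch(spec$method,
    RAW = list(data = x, state = list(method = "RAW")),
    SG = list(data = savitzky_golay(x, spec$sg_window, spec$sg_polyorder),
              state = list(method = "SG", window = spec$sg_window,
                           polyorder = spec$sg_polyorder)),
    FD = list(data = first_derivative(x), state = list(method = "FD")),
    SNV = list(data = snv(x), state = list(method = "SNV")),
    MSC = {
      ref <- if (is.null(fitted_state)) NULL else fitted_state$reference
      corrected <- msc(x, reference = ref)
      list(data = corrected,
           state = list(method = "MSC",
                        reference = attr(corrected, "reference")))
    },
    stop("unknown preprocessing method: ", spec$method))
  if (!is.null(fitted_state) && fitted_state$method != spec$method) {
    stop("fitted_state is for method ", fitted_state$method,
         ", not ", spec$method)
  }
  out
}
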