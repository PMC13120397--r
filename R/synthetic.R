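#' Configuration for the synthetic spectra generator
#'
#' Defaults emulate the statistical structure of near-infrared reflectance
#' of seed samples on a 940-1670 nm grid: analyte-linked Gaussian
#' absorption features near the C-H/O-H overtone bands at 1150, 1210, 1340
#' and 1450 nm, a few co-varying interferent constituents (water and
#' carbohydrate matrix bands), per-sample multiplicative/additive scatter,
#' linear baseline drift in absorbance and white measurement noise.
#'
#' @param n_samples number of samples (default 200).
#' @param wavelengths wavelength grid in nm (default 472 points uniform on
#'   940-1670 nm).
#' @param analyte_peaks data.frame-like list of analyte peak `center` (nm),
#'   `width` (Gaussian sd, nm) and `amplitude` (absorbance per unit % of
#'   analyte).
#' @param n_interferents number of interferent Gaussians (default 3); their
#'   positions/widths/amplitudes are drawn once per dataset, their
#'   concentrations per sample.
#' @param y_range analyte range in % (default `c(0.30, 0.69)`).
#' @param scatter_mult_range,scatter_add_range per-sample multiplicative and
#'   additive scatter ranges (defaults `c(0.8, 1.2)`, `c(-0.05, 0.05)`).
#' @param baseline_slope_range absorbance baseline slope range per nm
#'   (default `c(-5e-5, 5e-5)`).
#' @param noise_sd white-noise standard deviation in reflectance units
#'   (default 0.005); must be `>= 0`.
#' @param r0 scatter-free peak reflectance level (default 0.9).
#' @param seed integer seed; the generator is a pure function of
#'   config + seed.
#' @return A `synthetic_spectra_config` list.
#' @export
synthetic_spectra_config <- function(
    n_samples = 200L,
    wavelengths = seq(940, 1670, length.out = 472L),
    analyte_peaks = data.frame(center = c(1150, 1210, 1340, 1450),
                               width = c(25, 20, 25, 30),
                               amplitude = c(0.8, 0.6, 0.7, 1.0)),
    n_interferents = 3L,
    y_range = c(0.30, 0.69),
    scatter_mult_range = c(0.8, 1.2),
    scatter_add_range = c(-0.05, 0.05),
    baseline_slope_range = c(-5e-5, 5e-5),
    noise_sd = 0.005, r0 = 0.9, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(y_range <= 0)) stop("y_range must be positive")
  analyte_peaks <- as.data.frame(analyte_peaks)
  if (any(analyte_peaks$center < min(wavelengths)) ||
      any(analyte_peaks$center > max(wavelengths))) {
    stop("analyte peaks must lie within the wavelength range")
  }
  structure(list(n_samples = as.integer(n_samples),
                 wavelengths = as.numeric(wavelengths),
                 analyte_peaks = analyte_peaks,
                 n_interferents = as.integer(n_interferents),
                 y_range = y_range,
                 scatter_mult_range = scatter_mult_range,
                 scatter_add_range = scatter_add_range,
                 baseline_slope_range = baseline_slope_range,
                 noise_sd = noise_sd, r0 = r0, seed = as.integer(seed)),
            class = "synthetic_spectra_config")
}

#' Generate synthetic seed reflectance spectra with known truth
#'
#' Reference values `y` are drawn uniform on `y_range`. Absorbance follows a
#' Beer-Lambert construction
#' \deqn{A(\lambda) = y \sum_g a_g G_g(\lambda) + \sum_m c_m I_m(\lambda)
#'   + s (\lambda - \lambda_{min})}
#' (analyte Gaussians, interferent Gaussians with per-sample concentrations,
#' linear baseline), reflectance is `r0 * exp(-A)`, and per-sample
#' multiplicative/additive scatter plus white noise act in the measured
#' reflectance domain — which is exactly the distortion family MSC and SNV
#' assume.
#'
#' @param cfg a [synthetic_spectra_config()].
#' @return List with `spectra` (a `spectrum_set`), `y` (reference vector, %),
#'   and `truth` (list: `informative_band_indices` — bands within one
#'   half-width of an analyte centre —, per-sample `scatter` parameters,
#'   interferent description, and `clean` noise/scatter-free reflectance).
#' @export
generate_spectra <- function(cfg = synthetic_spectra_config()) {
  stopifnot(inherits(cfg, "synthetic_spectra_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  wl <- cfg$wavelengths
  n <- cfg$n_samples
  p <- length(wl)
  y <- stats::runif(n, cfg$y_range[1], cfg$y_range[2])

  gauss <- function(center, width) exp(-(wl - center)^2 / (2 * width^2))
  analyte_profile <- rep(0, p)
  for (g in seq_len(nrow(cfg$analyte_peaks))) {
    pk <- cfg$analyte_peaks[g, ]
    analyte_profile <- analyte_profile + pk$amplitude * gauss(pk$center, pk$width)
  }

  # interferent geometry drawn once per dataset
  n_int <- cfg$n_interferents
  int_centers <- if (n_int > 0) stats::runif(n_int, 980, 1600) else numeric()
  int_widths <- if (n_int > 0) stats::runif(n_int, 30, 60) else numeric()
  int_amps <- if (n_int > 0) stats::runif(n_int, 0.05, 0.15) else numeric()
  int_profiles <- if (n_int > 0) {
    vapply(seq_len(n_int),
           function(m) int_amps[m] * gauss(int_centers[m], int_widths[m]),
           numeric(p))
  } else matrix(0, p, 0)
  int_conc <- matrix(stats::runif(n * max(n_int, 1L)), n, max(n_int, 1L))
  if (n_int == 0) int_conc <- matrix(0, n, 0)

  slopes <- stats::runif(n, cfg$baseline_slope_range[1],
                         cfg$baseline_slope_range[2])
  absorb <- outer(y, analyte_profile) +
    int_conc %*% t(int_profiles) +
    outer(slopes, wl - min(wl))
  clean <- cfg$r0 * exp(-absorb)

  a_sc <- stats::runif(n, cfg$scatter_mult_range[1], cfg$scatter_mult_range[2])
  b_sc <- stats::runif(n, cfg$scatter_add_range[1], cfg$scatter_add_range[2])
  noise <- matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p)
  X <- clean * a_sc + b_sc + noise

  centers <- cfg$analyte_peaks$center
  widths <- cfg$analyte_peaks$width
  informative <- sort(unique(unlist(lapply(seq_along(centers), function(g) {
    which(abs(wl - centers[g]) <= widths[g] / 2)
  }))))
  list(spectra = spectrum_set(X, wl),
       y = y,
       truth = list(informative_band_indices = informative,
                    scatter = data.frame(a = a_sc, b = b_sc, slope = slopes),
                    interferents = data.frame(center = int_centers,
                                              width = int_widths,
                                              amplitude = int_amps),
                    analyte_profile = analyte_profile,
                    clean = clean))
}

#' Synthesize a raw hypercube scene with known segmentation truth
#'
#' Builds a dark-background scene with one bright circular sample region
#' (the Petri-dish geometry of a line-scan acquisition): inside the disk the
#' reflectance equals `sample_spectrum`, outside it equals `bg_level`. Raw
#' digital numbers are synthesized by inverting the two-point reflectance
#' calibration, `IO = B + I * (W - B)`, with pixel noise added on the
#' reflectance scale, so that correct -> segment -> extract recovers the
#' input spectrum.
#'
#' @param sample_spectrum a [spectrum()]: in-disk reflectance per band.
#' @param rows,cols spatial scene size in pixels (defaults 64 x 64).
#' @param disk_radius_px radius of the sample disk (default 20); the disk
#'   must fit in the frame.
#' @param bg_level constant background reflectance (default 0.05); must stay
#'   below the in-disk reflectance at the guide band or segmentation truth
#'   is unverifiable.
#' @param guide_nm wavelength used for that feasibility check (default 1290).
#' @param pixel_noise_sd per-pixel reflectance noise sd (default 0.002).
#' @param white_dn,dark_dn digital-number levels of the white and dark
#'   reference lines (defaults 3000 and 120).
#' @param seed integer seed.
#' @return List with `raw` (a raw `hypercube`), `refs` (single-line
#'   [reference_frames()], broadcast along rows), and `truth_mask` (0/1
#'   matrix of the planted disk).
#' @export
generate_hypercube <- function(sample_spectrum, rows = 64L, cols = 64L,
                               disk_radius_px = 20L, bg_level = 0.05,
                               guide_nm = 1290, pixel_noise_sd = 0.002,
                               white_dn = 3000, dark_dn = 120, seed = 1L) {
  stopifnot(inherits(sample_spectrum, "spectrum"))
  wl <- sample_spectrum$wavelengths
  nb <- length(wl)
  cx <- (cols + 1) / 2; cy <- (rows + 1) / 2
  if (disk_radius_px >= min(cx, cy)) stop("disk does not fit in the frame")
  gb <- which.min(abs(wl - guide_nm))
  if (bg_level >= sample_spectrum$reflectance[gb]) {
    stop("bg_level >= in-disk reflectance at the guide band; ",
         "segmentation truth would be unverifiable")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  dist2 <- outer(seq_len(rows), seq_len(cols),
                 function(r, c) (r - cy)^2 + (c - cx)^2)
  mask <- matrix(as.integer(dist2 <= disk_radius_px^2), rows, cols)
  refl <- array(bg_level, dim = c(rows, cols, nb))
  in_disk <- which(mask == 1)
  flat <- matrix(refl, rows * cols, nb)
  flat[in_disk, ] <- matrix(sample_spectrum$reflectance, length(in_disk), nb,
                            byrow = TRUE)
  if (pixel_noise_sd > 0) {
    flat <- flat + matrix(stats::rnorm(rows * cols * nb, sd = pixel_noise_sd),
                          rows * cols, nb)
  }
  refl <- array(flat, dim = c(rows, cols, nb))
  # single-line references with a mild band-dependent white response
  white_line <- array(rep(white_dn * (1 + 0.05 * sin(seq_len(nb) / nb * pi)),
                          each = cols),
                      dim = c(1L, cols, nb))
  dark_line <- array(dark_dn, dim = c(1L, cols, nb))
  refs <- reference_frames(white_line, dark_line)
  denom <- white_line[rep(1L, rows), , , drop = FALSE] -
    dark_line[rep(1L, rows), , , drop = FALSE]
  raw_vals <- dark_dn + refl * denom
  list(raw = hypercube(raw_vals, wl, kind = "raw"),
       refs = refs,
       truth_mask = mask)
}

#' Generate a minimal regression fixture with planted informative columns
#'
#' `X` is standard normal; `y` is a fixed-weight linear combination of the
#' informative columns plus white noise. The minimal ground-truth problem
#' for wavelength-selection and model unit tests.
#'
#' @param n_samples,n_bands fixture dimensions.
#' @param informative integer indices (1-based) of the informative columns.
#' @param noise_sd sd of the additive noise on `y`.
#' @param seed integer seed.
#' @return List with `spectra` (`spectrum_set`, unit wavelength grid), `y`,
#'   and `truth` (informative indices and their weights).
#' @export
generate_regression_fixture <- function(n_samples, n_bands, informative,
                                        noise_sd = 0.01, seed = 1L) {
  informative <- as.integer(informative)
  if (!length(informative)) stop("informative index list must be non-empty")
  if (any(informative < 1L | informative > n_bands)) {
    stop("informative indices out of range")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(n_samples * n_bands), n_samples, n_bands)
  w <- rep(c(1, -0.8, 1.2, -1, 0.9), length.out = length(informative))
  y <- as.numeric(X[, informative, drop = FALSE] %*% w) +
    stats::rnorm(n_samples, sd = noise_sd)
  list(spectra = spectrum_set(X, seq_len(n_bands)),
       y = y,
       truth = list(informative_band_indices = informative, weights = w))
}
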