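test_that("reflectance correction implements the two-point calibration", {
  wl <- c(1000, 1100, 1200)
  dims <- c(4L, 5L, 3L)
  white <- array(100, dims)
  dark <- array(20, dims)
  # pixel equal to the white frame -> reflectance 1 everywhere
  raw <- hypercube(white, wl, kind = "raw")
  out <- reflectance_correct(raw, reference_frames(white, dark))
  expect_equal(out$kind, "reflectance")
  expect_true(all(out$values == 1))
  expect_identical(out$wavelengths, wl)
  # pixel equal to the dark frame -> 0
  out0 <- reflectance_correct(hypercube(dark, wl, kind = "raw"),
                              reference_frames(white, dark))
  expect_true(all(out0$values == 0))
  # midpoint arithmetic: (60 - 20) / (100 - 20) = 0.5
  out5 <- reflectance_correct(hypercube(array(60, dims), wl, kind = "raw"),
                              reference_frames(white, dark))
  expect_true(all(abs(out5$values - 0.5) < 1e-12))
})

test_that("reflectance correction is invariant to a common positive rescale", {
  set.seed(42)
  dims <- c(3L, 4L, 5L)
  wl <- seq(1000, 1400, length.out = 5)
  white <- array(runif(prod(dims), 90, 110), dims)
  dark <- array(runif(prod(dims), 5, 15), dims)
  io <- dark + array(runif(prod(dims)), dims) * (white - dark)
  r1 <- reflectance_correct(hypercube(io, wl, "raw"),
                            reference_frames(white, dark))
  r2 <- reflectance_correct(hypercube(io * 3.7, wl, "raw"),
                            reference_frames(white * 3.7, dark * 3.7))
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("single-line reference frames broadcast along the scan axis", {
  wl <- c(1000, 1100)
  rows <- 6L; cols <- 3L
  white_line <- matrix(c(100, 120, 90, 100, 120, 90), cols, 2)
  dark_line <- matrix(10, cols, 2)
  io <- array(55, c(rows, cols, 2))
  out <- reflectance_correct(hypercube(io, wl, "raw"),
                             reference_frames(white_line, dark_line))
  manual <- sweep(array(45, c(rows, cols, 2)), c(2, 3), white_line - 10, "/")
  expect_equal(out$values, manual, tolerance = 1e-12)
})

test_that("near-zero white-dark denominator errors naming the band", {
  wl <- c(1000, 1100)
  white <- array(c(100, 100, 100, 100, 20.0000000001, 20, 20, 20), c(2, 2, 2))
  dark <- array(20, c(2, 2, 2))
  raw <- hypercube(array(50, c(2, 2, 2)), wl, "raw")
  expect_error(reflectance_correct(raw, reference_frames(white, dark)),
               "band 2")
})

test_that("otsu threshold separates a perfectly bimodal image", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  thr <- otsu_threshold(img)
  expect_true(all(img[img == 10] < thr))
  expect_true(all(img[img == 200] > thr))
})

test_that("otsu equals the exhaustive between-class-variance maximizer", {
  # two-Gaussian mixture of the kind a guide-band image produces
  set.seed(7)
  v <- c(rnorm(500, 0.1, 0.05), rnorm(500, 0.7, 0.05))
  expect_equal(otsu_threshold(v), brute_force_otsu(v))
  # 20 seeded images with varying separation and class balance
  for (s in 1:20) {
    set.seed(s)
    n1 <- sample(100:900, 1)
    v <- c(rnorm(n1, 0.2, 0.08), rnorm(1000 - n1, 0.75, 0.1))
    expect_equal(otsu_threshold(v), brute_force_otsu(v))
  }
})

test_that("otsu weights classes by their proportions (two occupied bins)", {
  v <- c(rep(0, 25), rep(1, 75))
  expect_equal(otsu_threshold(v), brute_force_otsu(v))
  expect_error(otsu_threshold(rep(3, 10)), "constant")
})

test_that("guide-band segmentation recovers a planted disk exactly", {
  wl <- seq(1200, 1400, length.out = 8)
  scene <- generate_hypercube(spectrum(rep(0.6, 8), wl), rows = 48L,
                              cols = 48L, disk_radius_px = 15L,
                              bg_level = 0.05, pixel_noise_sd = 0.01,
                              seed = 11L)
  cube <- reflectance_correct(scene$raw, scene$refs)
  mask <- segment_guide_band(cube, 1290)
  expect_identical(unname(as.vector(mask)), as.vector(scene$truth_mask))
})

test_that("guide band picks the nearest wavelength and validates range", {
  wl <- c(1288.9, 1290.5, 1292.1)
  vals <- array(rep(c(0.1, 0.5, 0.9), each = 4), c(2, 2, 3))
  vals[1, 1, ] <- vals[1, 1, ] + 0.3   # some contrast so otsu works
  cube <- hypercube(vals, wl, "reflectance")
  mask <- segment_guide_band(cube, 1290)
  expect_identical(attr(mask, "band"), 2L)
  expect_error(segment_guide_band(cube, 900), "outside")
  # uniform background: constant guide image propagates the otsu error
  flat <- hypercube(array(0.05, c(4, 4, 3)), wl, "reflectance")
  expect_error(segment_guide_band(flat, 1290), "constant")
})

test_that("mask mean spectrum averages valid pixels only", {
  wl <- c(1000, 1100)
  vals <- array(0, c(2, 2, 2))
  vals[, , 1] <- matrix(c(1, 3, 2, 4), 2, 2)   # band 0: [[1,2],[3,4]]
  vals[, , 2] <- matrix(c(5, 7, 6, 8), 2, 2)
  cube <- hypercube(vals, wl, "reflectance")
  mask <- matrix(c(1L, 1L, 0L, 0L), 2, 2)      # first column valid
  sp <- mask_mean_spectrum(cube, mask)
  expect_equal(sp$reflectance, c(2, 6))
  # all-ones mask equals the spatial mean per band
  all1 <- matrix(1L, 2, 2)
  expect_equal(mask_mean_spectrum(cube, all1)$reflectance,
               c(mean(vals[, , 1]), mean(vals[, , 2])))
  expect_error(mask_mean_spectrum(cube, matrix(0L, 2, 2)), "empty mask")
})

test_that("mask mean matches a brute-force pixel loop on random data", {
  set.seed(3)
  vals <- array(runif(6 * 5 * 4), c(6, 5, 4))
  cube <- hypercube(vals, c(1000, 1010, 1020, 1030), "reflectance")
  mask <- matrix(rbinom(30, 1, 0.5), 6, 5)
  if (sum(mask) == 0) mask[1, 1] <- 1L
  expect_equal(mask_mean_spectrum(cube, mask)$reflectance,
               loop_mask_mean(vals, mask), tolerance = 1e-12)
})

test_that("replicate averaging is the elementwise mean", {
  wl <- c(1000, 1100)
  s1 <- spectrum(c(0.2, 0.4), wl)
  s2 <- spectrum(c(0.4, 0.6), wl)
  expect_equal(average_replicates(list(s1))$reflectance, c(0.2, 0.4))
  expect_equal(average_replicates(list(s1, s2))$reflectance, c(0.3, 0.5))
  set.seed(9)
  reps <- lapply(1:3, function(i) spectrum(runif(2), wl))
  expect_equal(average_replicates(reps)$reflectance,
               (reps[[1]]$reflectance + reps[[2]]$reflectance +
                  reps[[3]]$reflectance) / 3)
  expect_error(average_replicates(list(s1, spectrum(c(0.1, 0.2),
                                                    c(1000, 1200)))),
               "different wavelength grids")
})

test_that("band trimming keeps the closed interval on the stored grid", {
  wl <- c(930, 940, 1000, 1670, 1680)
  x <- spectrum_set(matrix(runif(10), 2, 5), wl)
  tr <- trim_bands(x, 940, 1670)
  expect_equal(tr$wavelengths, c(940, 1000, 1670))
  # full-range trim is the identity
  expect_equal(trim_bands(x, 930, 1680)$X, x$X)
  # count on a uniform 512-point grid equals the direct count
  wl2 <- seq(900, 1700, length.out = 512)
  x2 <- spectrum_set(matrix(0.5, 1, 512), wl2)
  expect_equal(length(trim_bands(x2, 940, 1670)$wavelengths),
               sum(wl2 >= 940 & wl2 <= 1670))
  expect_error(trim_bands(x, 941, 999), "no bands retained")
})

test_that("ENVI write/read round-trips cubes in every interleave", {
  set.seed(5)
  wl <- c(1000.25, 1100.5, 1200.75)
  vals <- array(runif(4 * 6 * 3), c(4, 6, 3))
  cube <- hypercube(vals, wl, "reflectance")
  for (il in c("bsq", "bil", "bip")) {
    base <- file.path(tempdir(), paste0("cube_", il))
    write_envi(cube, base, interleave = il, data_type = 5L)
    back <- read_envi(paste0(base, ".hdr"), kind = "reflectance")
    expect_equal(back$values, vals, tolerance = 1e-12)
    expect_equal(back$wavelengths, wl, tolerance = 1e-6)
  }
  # float32 storage loses only single precision
  base <- file.path(tempdir(), "cube_f32")
  write_envi(cube, base, data_type = 4L)
  back <- read_envi(paste0(base, ".hdr"), kind = "reflectance")
  expect_equal(back$values, vals, tolerance = 1e-6)
})
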