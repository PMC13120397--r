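make_set <- function(X, wl = NULL) {
  if (is.null(wl)) wl <- seq(1000, by = 2, length.out = ncol(X))
  spectrum_set(X, wl)
}

test_that("MSC inverts per-row affine scatter against the reference", {
  set.seed(1)
  ref <- 0.5 + 0.2 * sin(seq(0, 3, length.out = 40))
  X <- rbind(ref,                 # identical to reference: unchanged
             2 * ref + 0.3,       # pure affine distortion: recovered exactly
             1.1 * ref - 0.05)
  out <- msc(make_set(X), reference = ref)
  expect_equal(out$X[1, ], ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(out$X[2, ], ref, tolerance = 1e-12, ignore_attr = TRUE)
  cf <- attr(out, "coefficients")
  expect_equal(unname(cf[2, ]), c(2, 0.3), tolerance = 1e-12)
})

test_that("MSC slopes/intercepts match the normal-equations oracle", {
  set.seed(10)
  X <- matrix(runif(10 * 50, 0.3, 0.9), 10, 50)
  out <- msc(make_set(X))
  ref <- colMeans(X)
  cf <- attr(out, "coefficients")
  for (i in 1:10) {
    fit <- lm(X[i, ] ~ ref)
    expect_equal(unname(cf[i, "a"]), unname(coef(fit)[2]), tolerance = 1e-9)
    expect_equal(unname(cf[i, "b"]), unname(coef(fit)[1]), tolerance = 1e-9)
  }
  expect_error(msc(make_set(X), reference = rep(1, 50)), "zero-variance")
})

test_that("Savitzky-Golay reproduces low-order polynomials exactly", {
  lambda <- seq_len(60)
  q <- 2 * lambda^2 - 3 * lambda + 1
  out <- savitzky_golay(make_set(rbind(q, q), wl = lambda), 11L, 2L)
  expect_lt(max(abs(out$X[1, ] - q)), 1e-8)
  # constant row unchanged, including the edges
  cst <- savitzky_golay(make_set(matrix(0.7, 1, 30)), 11L, 2L)
  expect_equal(cst$X[1, ], rep(0.7, 30), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("Savitzky-Golay interior points equal the local least-squares fit", {
  set.seed(4)
  x <- cumsum(rnorm(50, sd = 0.1))
  out <- savitzky_golay(make_set(matrix(x, 1)), 11L, 2L)
  for (i in c(6, 17, 30, 45)) {
    expect_equal(out$X[1, i], local_polyfit_at(x, i, 11L, 2L),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(savitzky_golay(make_set(matrix(x, 1)), 51L, 2L), "window")
})

test_that("Savitzky-Golay is linear in its input", {
  set.seed(6)
  x <- rnorm(40); y <- rnorm(40)
  sg <- function(v) savitzky_golay(make_set(matrix(v, 1)), 11L, 2L)$X[1, ]
  expect_equal(sg(2.5 * x - 1.3 * y), 2.5 * sg(x) - 1.3 * sg(y),
               tolerance = 1e-10)
})

test_that("first derivative uses central/one-sided stencils in per-nm units", {
  wl <- c(1000, 1002, 1005, 1009, 1010)
  x <- 0.002 * wl
  out <- first_derivative(spectrum_set(matrix(x, 1), wl))
  expect_equal(out$X[1, ], rep(0.002, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant row -> all zero
  out0 <- first_derivative(spectrum_set(matrix(1, 1, 5), wl))
  expect_true(all(out0$X == 0))
  # random row on a non-uniform grid vs the explicit stencil
  set.seed(8)
  v <- runif(5)
  d <- first_derivative(spectrum_set(matrix(v, 1), wl))$X[1, ]
  expect_equal(d[1], (v[2] - v[1]) / (wl[2] - wl[1]))
  expect_equal(d[5], (v[5] - v[4]) / (wl[5] - wl[4]))
  for (i in 2:4) {
    expect_equal(d[i], (v[i + 1] - v[i - 1]) / (wl[i + 1] - wl[i - 1]))
  }
})

test_that("SNV standardizes each row with the n-1 convention", {
  out <- snv(make_set(matrix(c(1, 2, 3), 1)))
  expect_equal(out$X[1, ], c(-1, 0, 1), ignore_attr = TRUE)
  set.seed(2)
  X <- matrix(runif(5 * 20), 5, 20)
  out2 <- snv(make_set(X))
  expect_true(all(abs(rowMeans(out2$X)) < 1e-12))
  expect_true(all(abs(apply(out2$X, 1, sd) - 1) < 1e-12))
  # idempotence
  expect_equal(snv(out2)$X, out2$X, tolerance = 1e-12)
  Xc <- X; Xc[3, ] <- 0.4
  expect_error(snv(make_set(Xc)), "s3")
})

test_that("derivative of SNV flattens a constant-plus-ramp spectrum", {
  wl <- seq(1000, 1100, by = 2)
  X <- rbind(0.5 + 0.001 * wl, 0.2 + 0.001 * wl)
  out <- first_derivative(snv(spectrum_set(X, wl)))
  expect_lt(diff(range(out$X[1, ])), 1e-10)
})

test_that("apply_preprocess dispatches and replays calibration state", {
  set.seed(12)
  X <- matrix(runif(8 * 30, 0.3, 0.8), 8, 30)
  x <- make_set(X)
  raw <- apply_preprocess(x, "RAW")
  expect_identical(raw$data$X, x$X)
  sg1 <- apply_preprocess(x, preprocess_spec("SG", 11L, 2L))$data
  expect_equal(sg1$X, savitzky_golay(x, 11L, 2L)$X)
  # MSC on prediction rows must use the calibration reference
  cal <- make_set(X[1:5, ])
  prd <- make_set(X[6:8, ])
  st <- apply_preprocess(cal, "MSC")
  prd_out <- apply_preprocess(prd, "MSC", fitted_state = st$state)$data
  oracle <- msc(prd, reference = colMeans(X[1:5, ]))
  expect_equal(prd_out$X, oracle$X, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(prd_out$X, msc(prd)$X)))
  expect_error(apply_preprocess(x, preprocess_spec("SG"),
                                fitted_state = st$state), "MSC")
})

test_that("MSC and SNV remove planted affine scatter", {
  # 50 copies of one clean spectrum distorted only by per-sample scatter
  gen <- generate_spectra(synthetic_spectra_config(
    n_samples = 2L, noise_sd = 0, seed = 33))
  base <- gen$truth$clean[1, ]
  set.seed(33)
  a <- runif(50, 0.8, 1.2)
  b <- runif(50, -0.05, 0.05)
  X <- outer(a, base) + b
  x <- spectrum_set(X, gen$spectra$wavelengths)
  pre_sd <- apply(X, 2, sd)
  for (method in c("MSC", "SNV")) {
    post <- apply_preprocess(x, method)$data$X
    expect_true(all(apply(post, 2, sd) <= 0.2 * pre_sd + 1e-10),
                label = paste(method, "scatter removal"))
  }
})
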