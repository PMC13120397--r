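test_that("EDF retention schedule has the forced endpoints", {
  p <- 100L; N <- 50L
  r1 <- edf_ratio(1, N, p)
  expect_equal(as.numeric(r1), 1, tolerance = 1e-12)
  expect_equal(attr(r1, "count"), p)
  rN <- edf_ratio(N, N, p)
  expect_equal(as.numeric(rN), 2 / p, tolerance = 1e-12)
  expect_equal(attr(rN, "count"), 2L)
  # closed-form recomputation at p = 472, N = 50, i = 25
  a <- (472 / 2)^(1 / 49); k <- log(472 / 2) / 49
  expect_equal(as.numeric(edf_ratio(25, 50, 472)), a * exp(-k * 25),
               tolerance = 1e-14)
  expect_error(edf_ratio(1, 1, 100), "N must be >= 2")
})

test_that("CARS recovers planted informative bands", {
  fx <- generate_regression_fixture(200, 100, c(10, 30, 50, 70, 90),
                                    noise_sd = 0.01, seed = 3)
  res <- cars_select(fx$spectra, fx$y, cars_config(seed = 3))
  hits <- sum(fx$truth$informative_band_indices %in% res$selected_indices)
  expect_gte(hits, 4)
})

test_that("CARS bookkeeping: monotone subset sizes, argmin choice, determinism", {
  fx <- generate_regression_fixture(80, 40, c(5, 20, 35), noise_sd = 0.05,
                                    seed = 2)
  cfg <- cars_config(n_iterations = 25L, seed = 7)
  res <- cars_select(fx$spectra, fx$y, cfg)
  expect_true(all(diff(res$per_iteration$subset_size) <= 0))
  expect_identical(res$chosen_iteration,
                   which.min(res$per_iteration$rmsecv))
  expect_identical(res$selected_indices, sort(unique(res$selected_indices)))
  res2 <- cars_select(fx$spectra, fx$y, cfg)
  expect_identical(res, res2)
  expect_error(cars_select(fx$spectra, rep(1, 80), cfg), "zero variance")
})

test_that("SPA projection step picks the max orthogonal residual", {
  # duplicated column has zero projection: never chosen while others remain
  set.seed(1)
  base <- matrix(rnorm(20 * 4), 20, 4)
  X <- cbind(base, base[, 1])
  expect_false(spa_projection_step(X, 1L) == 5L)
  # mutually orthogonal columns: largest remaining norm wins
  Q <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  Xo <- Q %*% diag(c(1, 5, 3))
  expect_identical(spa_projection_step(Xo, 1L), 2L)
  # seeded matrix vs brute-force least-squares residual norms
  set.seed(14)
  Xr <- matrix(rnorm(20 * 10), 20, 10)
  sel <- c(3L, 8L)
  cand <- setdiff(1:10, sel)
  norms <- vapply(cand, function(j) projection_residual_norm(Xr, sel, j),
                  numeric(1))
  expect_identical(spa_projection_step(Xr, sel), cand[which.max(norms)])
  # exhausted chain signals NA
  expect_true(is.na(spa_projection_step(cbind(base, base), 1:4)))
})

test_that("SPA finds planted columns in an orthogonal design", {
  set.seed(21)
  Q <- qr.Q(qr(matrix(rnorm(40 * 10), 40, 10))) * 3
  y <- 2 * Q[, 2] - 1.5 * Q[, 7]
  res <- spa_select(spectrum_set(Q, 1:10), y,
                    spa_config(max_vars = 5L, seed = 21))
  expect_true(all(c(2L, 7L) %in% res$selected_indices))
  expect_lt(res$min_rmse, 1e-8)
  # selected columns are linearly independent
  G <- crossprod(Q[, res$selected_indices, drop = FALSE])
  expect_equal(qr(G)$rank, length(res$selected_indices))
})

test_that("SPA reported minimum RMSE matches an independent MLR refit", {
  set.seed(30)
  fx <- generate_regression_fixture(60, 30, c(4, 17, 25), noise_sd = 0.1,
                                    seed = 30)
  cfg <- spa_config(max_vars = 8L, seed = 30)
  res <- spa_select(fx$spectra, fx$y, cfg)
  # reconstruct the seeded validation split the selector used
  n <- 60L
  set.seed(cfg$seed)
  val <- sort(sample(n, max(1L, round(cfg$validation_fraction * n))))
  tr <- setdiff(seq_len(n), val)
  sub <- res$selected_indices
  fit <- lm(fx$y[tr] ~ fx$spectra$X[tr, sub, drop = FALSE])
  beta <- coef(fit)
  pred <- cbind(1, fx$spectra$X[val, sub, drop = FALSE]) %*% beta
  expect_equal(res$min_rmse, sqrt(mean((fx$y[val] - pred)^2)),
               tolerance = 1e-10)
  small <- generate_regression_fixture(20, 30, c(4, 17), noise_sd = 0.1,
                                       seed = 31)
  expect_error(spa_select(small$spectra, small$y,
                          spa_config(max_vars = 25L)),
               "< samples")
})

test_that("selection results serialize to JSON and back", {
  fx <- generate_regression_fixture(60, 20, c(3, 11), noise_sd = 0.05,
                                    seed = 6)
  res <- cars_select(fx$spectra, fx$y,
                     cars_config(n_iterations = 10L, seed = 6))
  path <- file.path(tempdir(), "sel.json")
  write_selection_json(res, path)
  back <- read_selection_json(path)
  expect_identical(back$selected_indices, res$selected_indices)
  expect_identical(back$method, "CARS")
  expect_equal(nrow(back$per_iteration), 10L)
})
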