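# small architecture used where the full default would be wasteful
tiny_spec <- function(residual = TRUE) {
  network_spec(branch_channels = 4L, fusion_channels = 8L,
               residual_enabled = residual, pooled_length = 16L,
               fc_sizes = c(32L, 8L, 1L))
}

test_that("forward pass honours the batch/shape contract", {
  net <- build_network(network_spec(), 472L, seed = 1)
  X <- matrix(rnorm(4 * 472), 4, 472)
  out <- specpoly:::msnet_forward(net, X)$out
  expect_identical(dim(out), c(4L, 1L))
  expect_error(build_network(network_spec(), 10L), "kernel")
})

test_that("zeroed residual block reduces to the identity skip", {
  net <- build_network(tiny_spec(TRUE), 40L, seed = 2)
  for (nm in c("res1_W", "res1_b", "res2_W", "res2_b")) {
    net$params[[nm]][] <- 0
  }
  X <- matrix(rnorm(3 * 40), 3, 40)
  fw <- specpoly:::msnet_forward(net, X, training = TRUE)
  # recompute the block input with the same primitives and parameters
  p <- net$params
  A0 <- array(X, dim = c(3, 40, 1))
  branches <- lapply(1:3, function(i) {
    cv <- specpoly:::conv1d_forward(A0, p[[paste0("br", i, "_W")]],
                                    p[[paste0("br", i, "_b")]],
                                    net$spec$branch_kernels[i])
    bn <- specpoly:::bn_forward(cv$out, p[[paste0("br", i, "_bn")]], TRUE)
    specpoly:::relu_forward(bn$out)$out
  })
  concat <- array(0, dim = c(3, 40, 12))
  for (i in 1:3) concat[, , ((i - 1) * 4 + 1):(i * 4)] <- branches[[i]]
  fus <- specpoly:::conv1d_forward(concat, p$fus_W, p$fus_b, 3L)
  blk_in <- specpoly:::maxpool2_forward(
    specpoly:::relu_forward(fus$out)$out)$out
  # with zero conv weights the batch-normalized block output is zero, so
  # the skip passes blk_in through the final ReLU unchanged
  expect_equal(fw$block_out, blk_in, tolerance = 1e-12)
})

test_that("parameter count matches the layer-by-layer formula", {
  bc <- 16L; fc <- 32L; P <- 64L
  net <- build_network(network_spec(), 472L, seed = 1)
  expected <-
    sum((c(13, 9, 5) * 1 + 1) * bc) +      # branch convs
    3 * (2 * bc) +                          # branch batch-norm scale/shift
    (3 * (3 * bc) + 1) * fc +               # fusion conv
    (3 * fc + 1) * fc + 2 * fc +            # res conv1 + bn
    (3 * fc + 1) * fc + 2 * fc +            # res conv2 + bn
    (fc * P + 1) * 256 +                    # fc1
    (256 + 1) * 64 +                        # fc2
    (64 + 1) * 1                            # fc3
  expect_identical(n_params(net), as.integer(expected))
})

test_that("training is deterministic given seed and data", {
  set.seed(99)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(40)
  cfg <- train_config(epochs = 5L, batch_size = 8L, seed = 3)
  t1 <- train_network(build_network(tiny_spec(), 30L), X, y, cfg)
  t2 <- train_network(build_network(tiny_spec(), 30L), X, y, cfg)
  Xt <- matrix(rnorm(5 * 30), 5, 30)
  expect_identical(predict(t1, Xt), predict(t2, Xt))
  expect_identical(t1$history, t2$history)
})

test_that("the network fits a noiseless spectral target", {
  # capacity check on generator spectra (200 samples x 60 bands, no noise or
  # scatter): the clean analyte-to-reflectance map must be fit to well under
  # 10% of the target sd. Smooth spectra are the intended input family; a
  # dense linear map of i.i.d. bands is not representable through max
  # pooling, which discards within-pair band identity of uncorrelated inputs.
  cfg <- synthetic_spectra_config(
    n_samples = 200L, wavelengths = seq(940, 1670, length.out = 60),
    n_interferents = 0L, scatter_mult_range = c(1, 1),
    scatter_add_range = c(0, 0), baseline_slope_range = c(0, 0),
    noise_sd = 0, seed = 7)
  gen <- generate_spectra(cfg)
  tr <- train_network(build_network(network_spec(), 60L), gen$spectra,
                      gen$y, train_config(epochs = 120L,
                                          early_stop_patience = 120L,
                                          seed = 7))
  resid <- predict(tr, gen$spectra) - gen$y
  expect_lt(sqrt(mean(resid^2)), 0.1 * sd(gen$y))
})

test_that("early stopping keeps the best validation loss in bounds", {
  set.seed(5)
  X <- matrix(rnorm(60 * 25), 60, 25)
  y <- as.numeric(X %*% rnorm(25)) + rnorm(60, sd = 0.1)
  tr <- train_network(build_network(tiny_spec(), 25L), X, y,
                      train_config(epochs = 30L, batch_size = 8L, seed = 5))
  h <- tr$history
  expect_lte(min(h$val_loss), h$val_loss[1])
  expect_lte(tr$best_epoch, nrow(h))
  expect_gte(tr$best_epoch, 1L)
})

test_that("grad_cam obeys the normalization contract and zero path", {
  set.seed(31)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(40)
  tr <- train_network(build_network(tiny_spec(), 30L), X, y,
                      train_config(epochs = 4L, batch_size = 8L, seed = 2))
  sal <- grad_cam(tr, X[1, ])
  expect_length(sal, 30L)
  expect_true(all(sal >= 0 & sal <= 1))
  expect_equal(max(sal), 1)
  # zeroed output head kills every gradient: degenerate all-zero map
  tr0 <- tr
  tr0$net$params$fc3_W[] <- 0
  expect_identical(grad_cam(tr0, X[1, ]), rep(0, 30))
  expect_error(grad_cam(tr, X[1, 1:10]), "does not match")
})

test_that("adaptive pooling bins follow the floor/ceil partition", {
  # downsampling: 6 -> 3 averages disjoint pairs
  S <- specpoly:::adaptive_pool_matrix(6L, 3L)
  expect_equal(S[, 1], c(0.5, 0.5, 0, 0, 0, 0))
  expect_equal(S[, 3], c(0, 0, 0, 0, 0.5, 0.5))
  # upsampling by duplication: 2 -> 4 repeats each position twice
  S2 <- specpoly:::adaptive_pool_matrix(2L, 4L)
  expect_equal(S2[, 1], c(1, 0))
  expect_equal(S2[, 4], c(0, 1))
  expect_true(all(colSums(S2) == 1))
})
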