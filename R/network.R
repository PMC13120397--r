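#' Multi-scale 1-D network architecture specification
#'
#' Describes the multi-scale residual convolutional network (MS-RCNN) and
#' its ablation without the identity skip (MS-CNN). The input spectrum
#' passes three parallel same-padded convolution branches with kernels
#' 13/9/5 (long-, mid-, short-range spectral dependencies), each followed by
#' batch norm and ReLU; the branches are concatenated on the channel axis,
#' fused by a kernel-3 convolution with ReLU and 2x max pooling, then pass a
#' block of two same-padded 3x1 convolutions with batch norm (ReLU after the
#' first). With `residual_enabled` the block input is added back before the
#' final ReLU. Adaptive average pooling unifies the sequence length to
#' `pooled_length`, and three fully connected layers emit the scalar
#' prediction.
#'
#' @param branch_kernels odd kernel sizes of the parallel branches
#'   (default `c(13, 9, 5)`).
#' @param branch_channels channels per branch (default 16).
#' @param fusion_channels channels after the fusion convolution (default 32).
#' @param residual_enabled `TRUE` for MS-RCNN, `FALSE` for the MS-CNN
#'   ablation; this flag is the only difference between the two.
#' @param pooled_length adaptive-pooling output length (default 64).
#' @param fc_sizes sizes of the three fully connected layers
#'   (default `c(256, 64, 1)`; the last must be 1).
#' @return A `network_spec` list.
#' @export
network_spec <- function(branch_kernels = c(13L, 9L, 5L),
                         branch_channels = 16L, fusion_channels = 32L,
                         residual_enabled = TRUE, pooled_length = 64L,
                         fc_sizes = c(256L, 64L, 1L)) {
  branch_kernels <- as.integer(branch_kernels)
  if (any(branch_kernels %% 2L == 0L)) stop("branch kernels must be odd")
  if (length(fc_sizes) != 3L || fc_sizes[3] != 1L) {
    stop("fc_sizes must be three layers ending in 1")
  }
  if (pooled_length < 1L) stop("pooled_length must be >= 1")
  structure(list(branch_kernels = branch_kernels,
                 branch_channels = as.integer(branch_channels),
                 fusion_channels = as.integer(fusion_channels),
                 residual_enabled = isTRUE(residual_enabled),
                 pooled_length = as.integer(pooled_length),
                 fc_sizes = as.integer(fc_sizes)),
            class = "network_spec")
}

#' Build an untrained multi-scale network
#'
#' Allocates seeded He-initialized weights for the architecture described by
#' a [network_spec()].
#'
#' @param spec a [network_spec()].
#' @param n_bands input spectrum length; must be at least the largest branch
#'   kernel.
#' @param seed initialization seed (default 1).
#' @return An object of class `msnet`: the spec, `n_bands`, a `params`
#'   list of weight matrices and batch-norm states.
#' @export
build_network <- function(spec, n_bands, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  n_bands <- as.integer(n_bands)
  if (n_bands < max(spec$branch_kernels)) {
    stop("n_bands (", n_bands, ") smaller than the largest kernel (",
         max(spec$branch_kernels), ")")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  bc <- spec$branch_channels
  fc_ch <- spec$fusion_channels
  P <- spec$pooled_length
  params <- list()
  for (i in seq_along(spec$branch_kernels)) {
    k <- spec$branch_kernels[i]
    params[[paste0("br", i, "_W")]] <- he_init(k, bc, fan_in = k)
    params[[paste0("br", i, "_b")]] <- rep(0, bc)
    params[[paste0("br", i, "_bn")]] <- bn_state_new(bc)
  }
  cin_fus <- length(spec$branch_kernels) * bc
  params$fus_W <- he_init(3L * cin_fus, fc_ch, fan_in = 3L * cin_fus)
  params$fus_b <- rep(0, fc_ch)
  params$res1_W <- he_init(3L * fc_ch, fc_ch, fan_in = 3L * fc_ch)
  params$res1_b <- rep(0, fc_ch)
  params$res1_bn <- bn_state_new(fc_ch)
  params$res2_W <- he_init(3L * fc_ch, fc_ch, fan_in = 3L * fc_ch)
  params$res2_b <- rep(0, fc_ch)
  params$res2_bn <- bn_state_new(fc_ch)
  d_flat <- fc_ch * P
  sz <- spec$fc_sizes
  params$fc1_W <- he_init(d_flat, sz[1], fan_in = d_flat)
  params$fc1_b <- rep(0, sz[1])
  params$fc2_W <- he_init(sz[1], sz[2], fan_in = sz[1])
  params$fc2_b <- rep(0, sz[2])
  params$fc3_W <- he_init(sz[2], sz[3], fan_in = sz[2])
  params$fc3_b <- rep(0, sz[3])
  structure(list(spec = spec, n_bands = n_bands, params = params),
            class = "msnet")
}

#' Number of trainable parameters of a network
#'
#' Counts weights, biases and batch-norm scale/shift vectors (running
#' statistics are not trainable).
#'
#' @param net an `msnet`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  stopifnot(inherits(net, "msnet"))
  total <- 0L
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    if (is.list(p)) {
      total <- total + length(p$gamma) + length(p$beta)
    } else {
      total <- total + length(p)
    }
  }
  total
}

# Full forward pass. X: (batch x n_bands) matrix of (standardized) spectra.
# Returns the scalar outputs, caches for backward, and possibly-updated
# batch-norm states.
msnet_forward <- function(net, X, training = FALSE, bn_momentum = 0.1) {
  spec <- net$spec
  p <- net$params
  B <- nrow(X); L <- ncol(X)
  A0 <- array(X, dim = c(B, L, 1L))
  caches <- list()
  branches <- vector("list", length(spec$branch_kernels))
  for (i in seq_along(spec$branch_kernels)) {
    k <- spec$branch_kernels[i]
    cv <- conv1d_forward(A0, p[[paste0("br", i, "_W")]],
                         p[[paste0("br", i, "_b")]], k)
    bn <- bn_forward(cv$out, p[[paste0("br", i, "_bn")]], training, bn_momentum)
    p[[paste0("br", i, "_bn")]] <- bn$state
    rl <- relu_forward(bn$out)
    branches[[i]] <- rl$out
    caches[[paste0("br", i)]] <- list(conv = cv$cache, bn = bn$cache,
                                      relu = rl$cache)
  }
  bc <- spec$branch_channels
  nb <- length(spec$branch_kernels)
  concat <- array(0, dim = c(B, L, nb * bc))
  for (i in seq_len(nb)) {
    concat[, , ((i - 1L) * bc + 1L):(i * bc)] <- branches[[i]]
  }
  fus <- conv1d_forward(concat, p$fus_W, p$fus_b, 3L)
  fus_rl <- relu_forward(fus$out)
  mp <- maxpool2_forward(fus_rl$out)
  blk_in <- mp$out
  r1 <- conv1d_forward(blk_in, p$res1_W, p$res1_b, 3L)
  r1bn <- bn_forward(r1$out, p$res1_bn, training, bn_momentum)
  p$res1_bn <- r1bn$state
  r1rl <- relu_forward(r1bn$out)
  r2 <- conv1d_forward(r1rl$out, p$res2_W, p$res2_b, 3L)
  r2bn <- bn_forward(r2$out, p$res2_bn, training, bn_momentum)
  p$res2_bn <- r2bn$state
  pre_act <- if (spec$residual_enabled) r2bn$out + blk_in else r2bn$out
  blk_rl <- relu_forward(pre_act)
  block_out <- blk_rl$out
  ap <- adaptive_avgpool_forward(block_out, spec$pooled_length)
  flat <- matrix(ap$out, B, spec$fusion_channels * spec$pooled_length)
  f1 <- dense_forward(flat, p$fc1_W, p$fc1_b)
  f1rl <- relu_forward(f1$out)
  f2 <- dense_forward(f1rl$out, p$fc2_W, p$fc2_b)
  f2rl <- relu_forward(f2$out)
  f3 <- dense_forward(f2rl$out, p$fc3_W, p$fc3_b)
  caches$fus <- fus$cache; caches$fus_relu <- fus_rl$cache
  caches$mp <- mp$cache
  caches$r1 <- r1$cache; caches$r1bn <- r1bn$cache; caches$r1relu <- r1rl$cache
  caches$r2 <- r2$cache; caches$r2bn <- r2bn$cache
  caches$blk_relu <- blk_rl$cache
  caches$ap <- ap$cache
  caches$f1 <- f1$cache; caches$f1relu <- f1rl$cache
  caches$f2 <- f2$cache; caches$f2relu <- f2rl$cache
  caches$f3 <- f3$cache
  caches$dims <- c(B = B, L = L)
  list(out = f3$out, caches = caches, params = p, block_out = block_out)
}

# Backward through the head (fc stack + adaptive pool) only; returns the
# gradient at the residual-block output plus head parameter grads.
msnet_head_backward <- function(dOut, caches) {
  g <- list()
  b3 <- dense_backward(dOut, caches$f3)
  g$fc3_W <- b3$dW; g$fc3_b <- b3$db
  d <- relu_backward(b3$dA, caches$f2relu)
  b2 <- dense_backward(d, caches$f2)
  g$fc2_W <- b2$dW; g$fc2_b <- b2$db
  d <- relu_backward(b2$dA, caches$f1relu)
  b1 <- dense_backward(d, caches$f1)
  g$fc1_W <- b1$dW; g$fc1_b <- b1$db
  dims_ap <- caches$ap$dimA
  dflat <- array(b1$dA, dim = c(dims_ap[1], caches$ap$P, dims_ap[3]))
  d_block <- adaptive_avgpool_backward(dflat, caches$ap)
  list(d_block = d_block, grads = g)
}

# Full backward pass; returns parameter grads named like the params.
msnet_backward <- function(net, dOut, caches) {
  spec <- net$spec
  head <- msnet_head_backward(dOut, caches)
  g <- head$grads
  d <- relu_backward(head$d_block, caches$blk_relu)
  d_skip <- if (spec$residual_enabled) d else 0
  b <- bn_backward(d, caches$r2bn)
  g$res2_bn <- list(gamma = b$dgamma, beta = b$dbeta)
  b2 <- conv1d_backward(b$dA, caches$r2)
  g$res2_W <- b2$dW; g$res2_b <- b2$db
  d <- relu_backward(b2$dA, caches$r1relu)
  b <- bn_backward(d, caches$r1bn)
  g$res1_bn <- list(gamma = b$dgamma, beta = b$dbeta)
  b1 <- conv1d_backward(b$dA, caches$r1)
  g$res1_W <- b1$dW; g$res1_b <- b1$db
  d_blk_in <- b1$dA + d_skip
  d <- maxpool2_backward(d_blk_in, caches$mp)
  d <- relu_backward(d, caches$fus_relu)
  bf <- conv1d_backward(d, caches$fus)
  g$fus_W <- bf$dW; g$fus_b <- bf$db
  bc <- spec$branch_channels
  for (i in seq_along(spec$branch_kernels)) {
    d_br <- bf$dA[, , ((i - 1L) * bc + 1L):(i * bc), drop = FALSE]
    ci <- caches[[paste0("br", i)]]
    d2 <- relu_backward(d_br, ci$relu)
    bb <- bn_backward(d2, ci$bn)
    g[[paste0("br", i, "_bn")]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    bcv <- conv1d_backward(bb$dA, ci$conv)
    g[[paste0("br", i, "_W")]] <- bcv$dW
    g[[paste0("br", i, "_b")]] <- bcv$db
  }
  g
}

#' Training configuration for the multi-scale networks
#'
#' @param epochs maximum epochs (default 300).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate Adam step size (default 1e-3).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping, with best-weights restore (default 30).
#' @param val_fraction fraction of the calibration set held out internally
#'   for early stopping, in (0, 0.5) (default 0.15).
#' @param seed seed controlling initialization, the validation split and
#'   minibatch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300L, batch_size = 16L,
                         learning_rate = 1e-3, early_stop_patience = 30L,
                         val_fraction = 0.15, seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 0.5) {
    stop("val_fraction must be in (0, 0.5)")
  }
  if (epochs < 1L || batch_size < 1L || learning_rate <= 0) {
    stop("epochs, batch_size and learning_rate must be positive")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a multi-scale network on calibration spectra
#'
#' Mean-squared-error loss minimized by Adam over seeded shuffled
#' minibatches. Inputs are standardized per band and the response z-scored,
#' both fitted on the training portion only and inverted at prediction. An
#' internal validation split drives early stopping with best-weights
#' restore. The whole run is a deterministic function of data + seed.
#'
#' @param net an `msnet` from [build_network()] (its weights are re-seeded
#'   from `cfg$seed` for reproducibility).
#' @param X_cal calibration spectra (`spectrum_set` or matrix); needs at
#'   least `2 * batch_size` rows.
#' @param y_cal calibration reference values.
#' @param cfg a [train_config()].
#' @return An object of class `trained_network`: the fitted `msnet`,
#'   standardization state, per-epoch `history` (train/val loss on the
#'   standardized scale), `best_epoch`.
#' @export
train_network <- function(net, X_cal, y_cal, cfg = train_config()) {
  stopifnot(inherits(net, "msnet"))
  if (inherits(X_cal, "spectrum_set")) X_cal <- X_cal$X
  X_cal <- as.matrix(X_cal); y_cal <- as.numeric(y_cal)
  n <- nrow(X_cal)
  if (ncol(X_cal) != net$n_bands) {
    stop("X has ", ncol(X_cal), " bands; network expects ", net$n_bands)
  }
  if (n < 2L * cfg$batch_size) {
    stop("calibration set must hold at least 2 * batch_size samples")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  n_val <- max(1L, round(cfg$val_fraction * n))
  val <- sort(sample(n, n_val))
  tr <- setdiff(seq_len(n), val)

  x_mean <- colMeans(X_cal[tr, , drop = FALSE])
  x_sd <- apply(X_cal[tr, , drop = FALSE], 2, stats::sd)
  x_sd[x_sd == 0 | !is.finite(x_sd)] <- 1
  y_mean <- mean(y_cal[tr])
  y_sd <- stats::sd(y_cal[tr])
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  Xs <- sweep(sweep(X_cal, 2, x_mean), 2, x_sd, "/")
  ys <- (y_cal - y_mean) / y_sd

  net <- build_network(net$spec, net$n_bands, seed = cfg$seed)
  params <- net$params
  opt <- adam_new(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_ema = numeric())
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  wait <- 0L; val_ema <- NA_real_

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    train_loss <- 0; n_seen <- 0L
    for (s in seq(1L, length(ord), by = cfg$batch_size)) {
      rows <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
      if (length(rows) < 2L) next  # batch norm needs >= 2 rows
      net$params <- params
      fw <- msnet_forward(net, Xs[rows, , drop = FALSE], training = TRUE)
      params <- fw$params  # running BN stats updated
      err <- fw$out[, 1] - ys[rows]
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; lower the learning rate")
      }
      train_loss <- train_loss + loss * length(rows)
      n_seen <- n_seen + length(rows)
      dOut <- matrix(2 * err / length(rows), ncol = 1L)
      grads <- msnet_backward(net, dOut, fw$caches)
      upd <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- upd$params; opt <- upd$opt
    }
    # batch-norm recalibration: running minibatch averages lag the weights,
    # so set the normalization statistics to their exact values over the
    # training portion before any eval-mode forward pass
    net$params <- params
    recal <- msnet_forward(net, Xs[tr, , drop = FALSE], training = TRUE,
                           bn_momentum = 1)
    params <- recal$params
    net$params <- params
    val_out <- msnet_forward(net, Xs[val, , drop = FALSE],
                             training = FALSE)$out[, 1]
    val_loss <- mean((val_out - ys[val])^2)
    # the raw per-epoch validation loss on a small split is noisy; the
    # stopping criterion tracks its exponential moving average so a single
    # transient dip cannot freeze an undertrained model
    val_ema <- if (epoch == 1L) val_loss else 0.7 * val_ema + 0.3 * val_loss
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss /
                                           max(n_seen, 1L),
                                         val_loss = val_loss,
                                         val_ema = val_ema))
    if (val_ema < best_val - 1e-12) {
      best_val <- val_ema; best_params <- params; best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  net$params <- best_params
  structure(list(net = net, x_mean = x_mean, x_sd = x_sd,
                 y_mean = y_mean, y_sd = y_sd,
                 history = history, best_epoch = best_epoch,
                 config = cfg),
            class = "trained_network")
}

#' @export
predict.trained_network <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_set")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_sd, "/")
  out <- msnet_forward(object$net, Xs, training = FALSE)$out[, 1]
  out * object$y_sd + object$y_mean
}

#' Grad-CAM band saliency for a trained network
#'
#' Gradient-weighted class activation mapping adapted to 1-D regression:
#' the gradient of the scalar output with respect to the residual-block
#' output feature maps is spatially averaged per channel to give channel
#' weights; the ReLU of the weighted sum of feature maps is linearly
#' interpolated back to the input band length and max-normalized to 1. An
#' all-zero map (e.g. a zeroed output head) is returned as zeros.
#'
#' @param trained a `trained_network`.
#' @param x a [spectrum()] or numeric vector of length `n_bands`.
#' @return Numeric saliency vector in `[0, 1]`, length = input bands.
#' @export
grad_cam <- function(trained, x) {
  stopifnot(inherits(trained, "trained_network"))
  if (inherits(x, "spectrum")) x <- x$reflectance
  x <- as.numeric(x)
  L <- trained$net$n_bands
  if (length(x) != L) {
    stop("spectrum length ", length(x), " does not match network input ", L)
  }
  xs <- (x - trained$x_mean) / trained$x_sd
  fw <- msnet_forward(trained$net, matrix(xs, nrow = 1L), training = FALSE)
  head <- msnet_head_backward(matrix(1, 1, 1), fw$caches)
  A <- fw$block_out[1, , ]            # positions x channels
  G <- head$d_block[1, , ]
  w <- colMeans(G)
  cam <- as.numeric(A %*% w)
  cam[cam < 0] <- 0
  if (max(cam) <= 0) return(rep(0, L))
  # interpolate from block resolution back to band resolution
  L2 <- length(cam)
  sal <- if (L2 == 1L) rep(cam, L) else {
    stats::approx(x = seq(1, L, length.out = L2), y = cam,
                  xout = seq_len(L))$y
  }
  sal[sal < 0] <- 0
  sal / max(sal)
}

# --- Adam optimizer over the nested parameter list ----------------------

adam_new <- function(params) {
  zeros_like <- function(p) {
    if (is.list(p)) list(gamma = p$gamma * 0, beta = p$beta * 0) else p * 0
  }
  list(m = lapply(params, zeros_like), v = lapply(params, zeros_like),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  upd1 <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + opt$eps)
    list(p = p, m = m, v = v)
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.list(g)) {  # batch-norm gamma/beta; running stats untouched
      for (fld in c("gamma", "beta")) {
        r <- upd1(params[[nm]][[fld]], g[[fld]], opt$m[[nm]][[fld]],
                  opt$v[[nm]][[fld]])
        params[[nm]][[fld]] <- r$p
        opt$m[[nm]][[fld]] <- r$m
        opt$v[[nm]][[fld]] <- r$v
      }
    } else {
      r <- upd1(params[[nm]], g, opt$m[[nm]], opt$v[[nm]])
      params[[nm]] <- r$p
      opt$m[[nm]] <- r$m
      opt$v[[nm]] <- r$v
    }
  }
  list(params = params, opt = opt)
}
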