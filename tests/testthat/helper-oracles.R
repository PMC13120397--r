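# Independent oracles used across the suite. Each re-derives the quantity it
# checks by the most naive route available (loops, lm(), closed forms) and
# never calls the code path under test.

# Exhaustive Otsu: build the 256-bin histogram, then score every candidate
# split with plain sums over bins; ties toward the lowest threshold.
brute_force_otsu <- function(v, n_bins = 256L) {
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  best_var <- -Inf
  best_k <- NA_integer_
  for (k in 2:n_bins) {
    lower <- seq_len(k - 1L)
    n0 <- sum(counts[lower]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[lower] * mids[lower]) / n0
    mu1 <- sum(counts[-lower] * mids[-lower]) / n1
    vb <- (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
    if (vb > best_var + 1e-15) {
      best_var <- vb
      best_k <- k
    }
  }
  edges[best_k]
}

# Per-band ROI mean by an explicit pixel loop.
loop_mask_mean <- function(values, mask) {
  nb <- dim(values)[3]
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    acc <- 0; cnt <- 0
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (mask[i, j] == 1) {
        acc <- acc + values[i, j, b]
        cnt <- cnt + 1
      }
    }
    out[b] <- acc / cnt
  }
  out
}

# Centered-window local polynomial fit evaluated at the window centre.
local_polyfit_at <- function(x, i, window, polyorder) {
  h <- (window - 1L) %/% 2L
  idx <- (i - h):(i + h)
  t <- idx - i
  fit <- stats::lm(x[idx] ~ stats::poly(t, polyorder, raw = TRUE))
  unname(stats::predict(fit, newdata = data.frame(t = 0)))
}

# Residual norm of one candidate column against the span of selected columns,
# via lm residuals.
projection_residual_norm <- function(Xcols, selected, candidate) {
  fit <- stats::lm.fit(Xcols[, selected, drop = FALSE],
                       Xcols[, candidate])
  sqrt(sum(fit$residuals^2))
}

# Small utility: a reflectance cube with prescribed constant spectrum inside
# a rectangle and background elsewhere.
make_test_cube <- function(rows, cols, wavelengths, fg, bg = 0.05,
                           fg_rows = NULL, fg_cols = NULL) {
  nb <- length(wavelengths)
  vals <- array(bg, dim = c(rows, cols, nb))
  if (is.null(fg_rows)) fg_rows <- seq_len(rows %/% 2)
  if (is.null(fg_cols)) fg_cols <- seq_len(cols %/% 2)
  for (b in seq_len(nb)) vals[fg_rows, fg_cols, b] <- fg[b]
  hypercube(vals, wavelengths, kind = "reflectance")
}
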