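#' Fit a univariate partial least squares regression (NIPALS)
#'
#' Extracts latent variables that maximize the covariance between the
#' (internally centred) spectral matrix and the response, then collapses
#' them into a per-band regression coefficient vector. Deterministic.
#'
#' @param X numeric matrix (samples x bands) or a `spectrum_set`.
#' @param y numeric response vector (analyte %, length = samples).
#' @param A number of latent variables, `1 <= A <= rank(X_centred)`.
#' @param scale logical; z-score the columns before fitting (default FALSE,
#'   the usual choice for reflectance spectra on a common scale).
#' @return An object of class `plsr_model` with elements `coefficients`
#'   (per-band vector `b`), `x_mean`, `x_scale`, `y_mean`, `weights` `W`,
#'   `loadings` `P`, `q` (y-loadings) and `A`. Predictions are
#'   `(X - x_mean)/x_scale %*% b + y_mean`.
#' @export
plsr_fit <- function(X, y, A, scale = FALSE) {
  if (inherits(X, "spectrum_set")) X <- X$X
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  A <- as.integer(A)
  if (A < 1L) stop("A must be >= 1")
  x_mean <- colMeans(X)
  x_scale <- rep(1, p)
  Xc <- sweep(X, 2, x_mean)
  if (scale) {
    x_scale <- apply(X, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
    Xc <- sweep(Xc, 2, x_scale, "/")
  }
  y_mean <- mean(y)
  yc <- y - y_mean
  rk <- qr(Xc)$rank
  if (A > rk) stop("A = ", A, " exceeds rank(X) = ", rk)
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  qv <- numeric(A)
  Xd <- Xc; yd <- yc
  for (a in seq_len(A)) {
    w <- as.numeric(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) stop("degenerate deflated covariance at component ", a)
    w <- w / nw
    tt <- as.numeric(Xd %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-14) stop("degenerate score vector at component ", a)
    pv <- as.numeric(crossprod(Xd, tt)) / t2
    qa <- sum(yd * tt) / t2
    Xd <- Xd - tcrossprod(tt, pv)
    yd <- yd - tt * qa
    W[, a] <- w; P[, a] <- pv; qv[a] <- qa
  }
  b <- pls_coef_from_wpq(W, P, qv, A)
  structure(list(coefficients = b, x_mean = x_mean, x_scale = x_scale,
                 y_mean = y_mean, weights = W, loadings = P, q = qv, A = A),
            class = "plsr_model")
}

# b_A = W_A (P_A' W_A)^-1 q_A for the first A components
pls_coef_from_wpq <- function(W, P, qv, A) {
  Wa <- W[, seq_len(A), drop = FALSE]
  Pa <- P[, seq_len(A), drop = FALSE]
  as.numeric(Wa %*% solve(crossprod(Pa, Wa), qv[seq_len(A)]))
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_set")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  Xc <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_scale, "/")
  as.numeric(Xc %*% object$coefficients) + object$y_mean
}

#' Choose the PLSR component count by cross-validation
#'
#' Seeded k-fold cross-validation over `A = 1..Amax`; returns the component
#' count with minimum RMSECV, ties broken toward the smallest A (the more
#' parsimonious model).
#'
#' @param X samples x bands matrix or `spectrum_set`.
#' @param y response vector.
#' @param Amax largest candidate component count (capped internally at the
#'   fold-wise training rank).
#' @param folds number of CV folds (default 5); must be `<=` samples.
#' @param seed integer seed for the fold assignment.
#' @return The chosen A, with attribute `rmsecv` (per-A vector).
#' @export
plsr_choose_components <- function(X, y, Amax = 10L, folds = 5L, seed = 1L) {
  if (inherits(X, "spectrum_set")) X <- X$X
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds > n) stop("folds (", folds, ") exceeds samples (", n, ")")
  if (Amax < 1L) stop("Amax must be >= 1")
  fold_id <- local({
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    sample(rep(seq_len(folds), length.out = n))
  })
  press <- numeric(Amax)
  counted <- 0L
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    Amax_f <- min(Amax, qr(scale(X[tr, , drop = FALSE], scale = FALSE))$rank)
    fit <- plsr_fit(X[tr, , drop = FALSE], y[tr], A = Amax_f)
    Xc <- sweep(X[te, , drop = FALSE], 2, fit$x_mean)
    for (A in seq_len(Amax)) {
      bA <- pls_coef_from_wpq(fit$weights, fit$loadings, fit$q, min(A, Amax_f))
      pred <- as.numeric(Xc %*% bA) + fit$y_mean
      press[A] <- press[A] + sum((y[te] - pred)^2)
    }
    counted <- counted + length(te)
  }
  rmsecv <- sqrt(press / counted)
  A_best <- which.min(rmsecv)  # which.min takes the first (smallest A) on ties
  structure(as.integer(A_best), rmsecv = rmsecv)
}

# RMSECV of a PLS model with fixed A on (X, y); used by CARS scoring.
pls_cv_rmse <- function(X, y, A, folds = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  fold_id <- local({
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    sample(rep(seq_len(folds), length.out = n))
  })
  press <- 0
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    A_f <- min(A, qr(scale(X[tr, , drop = FALSE], scale = FALSE))$rank,
               ncol(X), length(tr) - 1L)
    fit <- plsr_fit(X[tr, , drop = FALSE], y[tr], A = max(1L, A_f))
    pred <- predict(fit, X[te, , drop = FALSE])
    press <- press + sum((y[te] - pred)^2)
  }
  sqrt(press / n)
}

# Save/restore .Random.seed so seeded helpers don't perturb the caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
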