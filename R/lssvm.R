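#' Fit a least-squares support vector machine regressor
#'
#' Solves the LSSVM dual system in one shot:
#' \deqn{\begin{bmatrix} 0 & 1^\top \\ 1 & K + I/\gamma \end{bmatrix}
#'       \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ y \end{bmatrix}}
#' with RBF kernel \eqn{K_{ij} = \exp(-\|x_i - x_j\|^2 / \sigma^2)} (or a
#' linear kernel \eqn{K = X X^\top}). Prediction is
#' \eqn{f(x) = \sum_j \alpha_j K(x, x_j) + b}.
#'
#' @param X samples x bands matrix or `spectrum_set`.
#' @param y response vector.
#' @param gamma regularization parameter, > 0 (larger = less regularized).
#' @param sigma2 squared RBF width in band-space distance units, > 0.
#'   Ignored for the linear kernel.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @return An object of class `lssvm_model` with dual coefficients `alpha`,
#'   bias `b`, the stored training spectra and hyperparameters, plus
#'   `kkt_residual`, the max-norm residual of the solved system.
#' @export
lssvm_fit <- function(X, y, gamma, sigma2 = 1, kernel = c("rbf", "linear")) {
  if (inherits(X, "spectrum_set")) X <- X$X
  kernel <- match.arg(kernel)
  X <- as.matrix(X); y <- as.numeric(y)
  if (gamma <= 0) stop("gamma must be > 0")
  if (kernel == "rbf" && sigma2 <= 0) stop("sigma2 must be > 0")
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  K <- kernel_matrix(X, X, kernel, sigma2)
  M <- matrix(0, n + 1L, n + 1L)
  M[1, -1] <- 1
  M[-1, 1] <- 1
  M[-1, -1] <- K + diag(n) / gamma
  rhs <- c(0, y)
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    stop("LSSVM system is singular (", conditionMessage(e),
         "); try a smaller gamma (stronger regularization)")
  })
  kkt <- max(abs(M %*% sol - rhs))
  structure(list(alpha = sol[-1], b = sol[1], gamma = gamma, sigma2 = sigma2,
                 kernel = kernel, Xtrain = X, kkt_residual = kkt),
            class = "lssvm_model")
}

kernel_matrix <- function(A, B, kernel, sigma2) {
  if (kernel == "linear") return(tcrossprod(A, B))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma2)
}

#' @export
predict.lssvm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectrum_set")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  K <- kernel_matrix(newdata, object$Xtrain, object$kernel, object$sigma2)
  as.numeric(K %*% object$alpha) + object$b
}

#' Tune LSSVM hyperparameters by grid search
#'
#' Seeded k-fold cross-validation over the `(gamma, sigma2)` grid, minimizing
#' RMSECV. Ties are broken toward the smallest gamma, then smallest sigma2,
#' so the result is invariant to grid ordering.
#'
#' @param X samples x bands matrix or `spectrum_set`.
#' @param y response vector.
#' @param gamma_grid candidate regularization values (default `10^(0:5)`).
#' @param sigma2_grid candidate squared widths (default `10^(0:4)`).
#' @param folds CV folds (default 5).
#' @param seed fold-assignment seed.
#' @return List with `gamma`, `sigma2`, `rmsecv` (the winning score) and
#'   `grid` (a data.frame of all scores).
#' @export
lssvm_tune <- function(X, y, gamma_grid = 10^(0:5), sigma2_grid = 10^(0:4),
                       folds = 5L, seed = 1L) {
  if (inherits(X, "spectrum_set")) X <- X$X
  X <- as.matrix(X); y <- as.numeric(y)
  if (!length(gamma_grid) || !length(sigma2_grid)) stop("empty tuning grid")
  n <- nrow(X)
  fold_id <- local({
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    sample(rep(seq_len(folds), length.out = n))
  })
  gamma_grid <- sort(gamma_grid)
  sigma2_grid <- sort(sigma2_grid)
  grid <- expand.grid(sigma2 = sigma2_grid, gamma = gamma_grid)[, 2:1]
  grid$rmsecv <- NA_real_
  for (g in seq_len(nrow(grid))) {
    press <- 0
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      fit <- lssvm_fit(X[tr, , drop = FALSE], y[tr],
                       gamma = grid$gamma[g], sigma2 = grid$sigma2[g])
      pred <- predict(fit, X[te, , drop = FALSE])
      press <- press + sum((y[te] - pred)^2)
    }
    grid$rmsecv[g] <- sqrt(press / n)
  }
  best <- which.min(grid$rmsecv)  # grid sorted by gamma then sigma2: ties fall
  list(gamma = grid$gamma[best], sigma2 = grid$sigma2[best],
       rmsecv = grid$rmsecv[best], grid = grid)
}
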